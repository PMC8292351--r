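# The twelve canonical forward-simulation cases: parameter deltas around the
# base parameterization (Table-2-style constants, C = 200 ubar, O = 209
# mbar). Cases 1-4 probe the b6f-limited state alone (Rubisco effectively
# unlimited); 5-8 probe the regulatory modes across the light-saturation
# transition; 9-12 probe antenna connectivity, state transitions and the
# balance of the two V_max values.

#' Configuration fixture for a simulation case
#'
#' Returns the list of parameter variants that define one of the twelve
#' canonical simulation cases. Each variant holds a complete argument set
#' for [solve_steady_state()].
#'
#' @param case_id Integer 1-12.
#' @return List with `case_id`, `label`, `potential_only` (cases 1-4:
#'   b6f-limited chain without the Rubisco transition), and `variants`, a
#'   named list of argument sets (`leaf`, `env`, `k`, `coupling`).
#' @export
case_fixture <- function(case_id) {
  if (!case_id %in% 1:12) stop("unknown case id: ", case_id)
  base_leaf <- leaf_parameters   # Table defaults; R_d = 0.01 V_max_rubc
  base <- list(leaf = base_leaf(), env = leaf_env(),
               k = photo_constants(), coupling = coupling_efficiencies())
  variant <- function(label, ...) {
    v <- utils::modifyList(base, list(...))
    v$label <- label
    v
  }
  pot <- case_id %in% 1:4
  v <- switch(as.character(case_id),
    "1" = lapply(c(0.425, 0.6375, 0.85), function(at)
      variant(sprintf("alpha_total=%.3f", at),
              leaf = base_leaf(alpha_total = at))),
    "2" = lapply(c(175, 350, 700), function(vb)
      variant(sprintf("V_max_cb6f=%d", vb),
              leaf = base_leaf(V_max_cb6f = vb))),
    "3" = {
      sc <- list(
        reference = coupling_scenario(TRUE, TRUE, 4),
        no_ndh = coupling_scenario(TRUE, FALSE, 4),
        structural_atp = coupling_scenario(TRUE, TRUE, 14 / 3),
        no_q_cycle = coupling_scenario(FALSE, TRUE, 4),
        all_relaxed = coupling_scenario(FALSE, FALSE, 14 / 3))
      lapply(names(sc), function(nm)
        variant(nm, coupling = coupling_efficiencies(sc[[nm]])))
    },
    "4" = lapply(c(100, 200, 1000, 5000), function(C)
      variant(sprintf("C=%d", C), env = leaf_env(C = C))),
    "5" = list(variant("b6f_feedback_only",
                       leaf = base_leaf(npq_mode = "none"))),
    "6" = list(variant("npq_feedback_only",
                       leaf = base_leaf(b6f_control = FALSE))),
    "7" = list(variant("npq_plus_b6f",
                       leaf = base_leaf(cef_mode = "minimal"))),
    "8" = list(variant("npq_plus_regulatory_cef1",
                       leaf = base_leaf(cef_mode = "regulatory"))),
    "9" = lapply(c(0, 2, Inf), function(u)
      variant(sprintf("K_U2=%s", format(u)),
              k = photo_constants(K_U2 = u))),
    "10" = lapply(c(0, 2, Inf), function(u)
      variant(sprintf("K_U2=%s", format(u)),
              leaf = base_leaf(state_transitions = TRUE),
              k = photo_constants(K_U2 = u))),
    "11" = lapply(c(175, 350, 700), function(vb)
      variant(sprintf("V_max_cb6f=%d", vb),
              leaf = base_leaf(V_max_cb6f = vb,
                               state_transitions = TRUE),
              k = photo_constants(K_U2 = 2))),
    "12" = lapply(c(175, 350, 700), function(vb)
      variant(sprintf("V_max_cb6f=%d", vb),
              leaf = base_leaf(V_max_cb6f = vb,
                               V_max_rubc = vb / 3.5,
                               R_d = 0.01 * vb / 3.5,
                               state_transitions = TRUE),
              k = photo_constants(K_U2 = 2)))
  )
  labels <- c("absorptance sweep", "b6f Vmax sweep (potential)",
              "proton-coupling scenarios", "chloroplast CO2 sweep",
              "b6f feedback only (no NPQ)", "NPQ feedback only",
              "NPQ + b6f feedback (minimal CEF1)",
              "NPQ + regulatory CEF1",
              "PS II connectivity, fixed pigments",
              "PS II connectivity + state transitions",
              "b6f Vmax sweep, connected antenna",
              "joint Vmax sweep at fixed ratio")
  list(case_id = case_id, label = labels[case_id], potential_only = pot,
       variants = v)
}

#' Run a simulation case over a light grid
#'
#' Solves every variant of [case_fixture()] over the light grid and
#' assembles the observable columns: electron fluxes, CEF1 fraction, gross
#' assimilation and its absorbed quantum yield, K_N2, NPQ, open fractions,
#' the b6f turnover ratio and the PS II fluorescence yield. For the
#' potential-only cases (1-4) the Rubisco transition is lifted so the full
#' b6f-limited chain is reported at all light intensities.
#'
#' @param case_id Integer 1-12.
#' @param Q_grid Light grid (umol m^-2 s^-1).
#' @param detector A [detector_model()] for the NPQ column.
#' @return `data.frame`, one row per (variant, Q).
#' @export
simulate_case <- function(case_id, Q_grid = seq(0, 2400, by = 50),
                          detector = detector_model()) {
  fx <- case_fixture(case_id)
  out <- lapply(fx$variants, function(v) {
    leaf <- v$leaf
    if (fx$potential_only) {
      # lift the Rubisco cap but keep the base-case respiration
      leaf$V_max_rubc <- 1e9
    }
    st <- solve_steady_state(Q_grid, leaf, v$env, v$k, rubisco_kinetics(),
                             v$coupling)
    dark_ref <- c(st$alpha_1_eff[st$Q == 0][1],
                  st$alpha_2_eff[st$Q == 0][1])
    if (any(is.na(dark_ref)))
      dark_ref <- c(st$alpha_1_eff[1], st$alpha_2_eff[1])
    lv <- fluorescence_levels(st, v$k, detector, alpha_dark = dark_ref)
    data.frame(
      case = fx$case_id, variant = v$label, Q = st$Q,
      LEF = st$J_P680, CEF1 = st$CEF1,
      cef1_fraction = ifelse(st$J_P700 > 0, st$CEF1 / st$J_P700,
                             cef1_fraction(st$eta)),
      A_g = st$A_g,
      quantum_yield_co2 = ifelse(st$Q > 0,
                                 st$A_g / (st$Q * leaf$alpha_total),
                                 NA_real_),
      Phi_P2 = st$Phi_P2, Phi_P1 = st$Phi_P1,
      K_N2 = st$K_N2,
      NPQ = lv$F_m / lv$F_m_prime - 1,
      open_psii = 1 - st$f2, open_psi = 1 - st$f1,
      pq_reduction = st$fb,
      k_star_over_kq = st$k_star_over_kq,
      Phi_F2 = st$Phi_F2,
      A = st$A, regime = st$regime,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
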