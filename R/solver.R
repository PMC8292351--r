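# Steady-state solution under the minimum rule: the b6f-limited state
# (maximum b6f turnover, shared closure of PS II / b6f / PS I), the
# Rubisco-limited state (PS II flux pinned by carboxylation, photosynthetic
# control via the b6f turnover constant or a regulatory CEF1), and the
# back-solving of either the NPQ rate constant K_N2 or the PS II/PS I
# cross-section split.

# --- internal helpers -------------------------------------------------------

# Phi_P2 at K_N2 = N for closure f, vectorized; finite or infinite K_U2.
phi_p2_at <- function(f, k, N) {
  psii_yields(f, k, N)$Phi_P2
}

# Closed-form K_N2 solving Q * alpha_2 * Phi_P2(f2, K_N2) = target.
# Negative result means the target is infeasible at K_N2 = 0.
npq_closed_form <- function(target, Q, alpha_2, f2, k) {
  t <- ifelse(Q > 0, target / (Q * alpha_2), 0)
  c0 <- k$K_P2 + k$K_D2 + k$K_F2
  cm <- k$K_D2 + k$K_F2
  u <- k$K_U2
  if (is.infinite(u)) {
    N <- ifelse(t > 0, (1 - f2) * k$K_P2 / t - c0 + f2 * k$K_P2, 0)
  } else {
    m0 <- c0 + u
    mm <- cm + u
    aq <- t
    bq <- t * (m0 + mm - u) - (1 - f2) * k$K_P2
    cq <- t * (m0 * mm - (1 - f2) * u * mm - f2 * u * m0) -
      (1 - f2) * k$K_P2 * mm
    disc <- pmax(bq^2 - 4 * aq * cq, 0)
    N <- ifelse(t > 0, (-bq + sqrt(disc)) / (2 * aq), 0)
  }
  N[t <= 0] <- 0
  N
}

# Closed-form f2 solving Q * alpha_2 * Phi_P2(f2, 0) = target (K_N2 = 0).
# Phi_P2 is linear-fractional in f2, so the root is rational; clamped to
# [0, 1]. Used for the no-NPQ regulatory mode and the PS II-limited branch.
f2_closed_form <- function(target, Q, alpha_2, k) {
  t <- ifelse(Q > 0, target / (Q * alpha_2), 0)
  c0 <- k$K_P2 + k$K_D2 + k$K_F2
  cm <- k$K_D2 + k$K_F2
  u <- k$K_U2
  if (is.infinite(u)) {
    f <- (k$K_P2 - t * c0) / (k$K_P2 * (1 - t))
  } else {
    A <- k$K_P2 * (cm + u)
    f <- (A - t * c0 * (cm + u)) / (A - t * u * k$K_P2)
  }
  pmin(pmax(ifelse(t > 0, f, 0), 0), 1)
}

# --- exported operations ----------------------------------------------------

#' Back-solve the NPQ rate constant from a PS II flux target
#'
#' Finds the unique K_N2 >= 0 with
#' `Q * alpha_2 * Phi_P2(f2, K_N2) = J_P680_target` by bracketed
#' root-finding (Phi_P2 is strictly decreasing in K_N2). If the target
#' exceeds the supply at K_N2 = 0 the balance cannot be met by quenching;
#' K_N2 = 0 is returned with `psii_limited = TRUE`.
#'
#' @param J_P680_target Required PS II electron flux (umol e- m^-2 s^-1).
#' @param Q Incident PPFD (umol m^-2 s^-1).
#' @param alpha_2 PS II absorbance cross-section.
#' @param f2 Fraction of closed PS II centers.
#' @param k A [photo_constants()] object.
#' @param tol Absolute tolerance on K_N2 (ns^-1).
#' @return List with `K_N2` (ns^-1) and logical `psii_limited`.
#' @export
solve_npq <- function(J_P680_target, Q, alpha_2, f2, k = photo_constants(),
                      tol = 1e-10) {
  stopifnot(length(J_P680_target) == 1, J_P680_target >= 0)
  if (Q <= 0 || J_P680_target == 0)
    return(list(K_N2 = 0, psii_limited = FALSE))
  supply0 <- Q * alpha_2 * phi_p2_at(f2, k, 0)
  if (J_P680_target > supply0 * (1 + 1e-12))
    return(list(K_N2 = 0, psii_limited = TRUE))
  g <- function(N) Q * alpha_2 * phi_p2_at(f2, k, N) - J_P680_target
  hi <- 100
  while (g(hi) > 0 && hi < 1e6) hi <- hi * 2
  root <- stats::uniroot(g, c(0, hi), tol = tol)$root
  list(K_N2 = root, psii_limited = FALSE)
}

#' Balanced PS II / PS I cross-section split
#'
#' In the state-transition regime (K_N2 = 0) the pigment split that balances
#' PS II supply to PS I demand at shared closure `f` satisfies
#' `alpha_2/alpha_1 = [(1 - f) K_P1/SumK0_P700 / eta] / Phi_P2(f, K_N2 = 0)`
#' with `alpha_1 + alpha_2 = alpha_total`. With no exciton sharing the ratio
#' is independent of `f`.
#'
#' @param eta PS I : PS II flux ratio.
#' @param f Shared closure fraction; vectorized.
#' @param k A [photo_constants()] object.
#' @param alpha_total Total leaf absorbance.
#' @return List with vectors `alpha_1`, `alpha_2`.
#' @export
solve_cross_sections <- function(eta, f, k = photo_constants(),
                                 alpha_total = 0.85) {
  kp1n <- k$K_P1 / (k$K_P1 + k$K_D1 + k$K_F1)
  ratio <- ((1 - f) * kp1n / eta) / phi_p2_at(f, k, 0)
  alpha_1 <- alpha_total / (1 + ratio)
  list(alpha_1 = alpha_1, alpha_2 = alpha_total - alpha_1)
}

#' Potential assimilation under Cyt b6f limitation
#'
#' The b6f-limited chain: J'_P700 from the light hyperbola, J'_CB6F =
#' J'_P700, J'_P680 = J'_CB6F / eta, and
#' `A_j = J'_P680 (1 - G/C)/(4 + 8 G/C) - R_d`.
#'
#' @param Q Incident PPFD (umol m^-2 s^-1); vectorized.
#' @param leaf A [leaf_parameters()] object (its `alpha_1` is used; pass
#'   effective cross-sections for state-transition states).
#' @param env A [leaf_env()] object.
#' @param k A [photo_constants()] object.
#' @param kin A [rubisco_kinetics()] object.
#' @param coupling Output of [coupling_efficiencies()].
#' @return List with `A_j`, `J_prime_P700`, `J_prime_CB6F`, `J_prime_P680`.
#' @export
aj <- function(Q, leaf = leaf_parameters(), env = leaf_env(),
               k = photo_constants(), kin = rubisco_kinetics(),
               coupling = coupling_efficiencies()) {
  gs <- co2_compensation(rubisco_specificity(kin), env$O)
  if (any(env$C <= gs)) stop("C must exceed the compensation point")
  x <- gs / env$C
  eta <- eta_ratio(coupling$n_L, coupling$n_C, gs, env$C)
  Jp700 <- potential_psi_rate(Q, leaf$alpha_1, k, leaf$V_max_cb6f)
  Jp680 <- Jp700 / eta
  list(A_j = Jp680 * (1 - x) / (4 + 8 * x) - leaf$R_d,
       J_prime_P700 = Jp700, J_prime_CB6F = Jp700, J_prime_P680 = Jp680)
}

#' Potential assimilation under Rubisco limitation
#'
#' `A_c = V_max C / (K_c (1 + O/K_o) + C) * (1 - G/C) - R_d`; `V_c` is the
#' Michaelis factor before the photorespiration correction.
#'
#' @inheritParams aj
#' @return List with `A_c` and `V_c`.
#' @export
ac <- function(leaf = leaf_parameters(), env = leaf_env(),
               kin = rubisco_kinetics()) {
  gs <- co2_compensation(rubisco_specificity(kin), env$O)
  x <- gs / env$C
  V_c <- leaf$V_max_rubc * env$C /
    (kin$K_c * (1 + (env$O * 1000) / (kin$K_o * 1000)) + env$C)
  list(A_c = V_c * (1 - x) - leaf$R_d, V_c = V_c)
}

#' Light-saturation point
#'
#' The crossover of the b6f-limited and Rubisco-limited potential rates.
#' The required potential PS I flux at the crossover is
#' `J'_req = eta (A_c + R_d)(4 + 8 G/C)/(1 - G/C)`; since the hyperbola
#' satisfies J' = f V_max at closure f, the saturation closure is
#' `f_sat = J'_req / V_max` regardless of the cross-section split, and
#' `Q_sat = J'_req (V_max/a)/(V_max - J'_req)` with the initial slope a of
#' the (possibly re-balanced) PS I bed.
#'
#' @inheritParams aj
#' @return List with `Q_sat` (`Inf` when `A_c` exceeds the b6f asymptote),
#'   `f_sat`, the cross-sections `alpha_1`, `alpha_2` in force at
#'   saturation, and logical `never_saturates`.
#' @export
light_saturation_point <- function(leaf = leaf_parameters(),
                                   env = leaf_env(),
                                   k = photo_constants(),
                                   kin = rubisco_kinetics(),
                                   coupling = coupling_efficiencies()) {
  gs <- co2_compensation(rubisco_specificity(kin), env$O)
  x <- gs / env$C
  eta <- eta_ratio(coupling$n_L, coupling$n_C, gs, env$C)
  A_c <- ac(leaf, env, kin)$A_c
  J_req <- eta * (A_c + leaf$R_d) * (4 + 8 * x) / (1 - x)
  if (J_req >= leaf$V_max_cb6f) {
    return(list(Q_sat = Inf, f_sat = 1,
                alpha_1 = leaf$alpha_1, alpha_2 = leaf$alpha_2,
                never_saturates = TRUE))
  }
  f_sat <- J_req / leaf$V_max_cb6f
  if (leaf$state_transitions) {
    split <- solve_cross_sections(eta, f_sat, k, leaf$alpha_total)
    a1 <- split$alpha_1
    a2 <- split$alpha_2
  } else {
    a1 <- leaf$alpha_1
    a2 <- leaf$alpha_2
  }
  a <- psi_initial_slope(a1, k)
  list(Q_sat = J_req * (leaf$V_max_cb6f / a) / (leaf$V_max_cb6f - J_req),
       f_sat = f_sat, alpha_1 = a1, alpha_2 = a2, never_saturates = FALSE)
}

# Below-saturation closure with a free cross-section split: f satisfies
# f = Q a(f) / (V_max + Q a(f)) with a(f) the PS I initial slope of the
# balanced split at closure f. Damped fixed-point iteration, vectorized
# over Q; with no exciton sharing the split is closure-independent and the
# loop converges in one step.
closure_with_split <- function(Q, eta, k, alpha_total, V_max_cb6f,
                               tol = 1e-12, max_iter = 200) {
  kp1n <- k$K_P1 / (k$K_P1 + k$K_D1 + k$K_F1)
  a1 <- solve_cross_sections(eta, 0, k, alpha_total)$alpha_1
  f <- Q * a1 * kp1n / (V_max_cb6f + Q * a1 * kp1n)
  for (i in seq_len(max_iter)) {
    a1 <- solve_cross_sections(eta, f, k, alpha_total)$alpha_1
    f_new <- Q * a1 * kp1n / (V_max_cb6f + Q * a1 * kp1n)
    delta <- max(abs(f_new - f))
    f <- 0.5 * f + 0.5 * f_new
    if (delta < tol) break
  }
  if (delta >= tol) stop("cross-section split iteration did not converge")
  f
}

#' Solve the steady state of the leaf
#'
#' Applies the minimum rule `A = min(A_j, A_c)`. In the b6f-limited regime
#' the turnover constant is maximal (k* = k_q) and PS II closure, b6f
#' occupancy and PS I closure share the light-driven value
#' `f = Q/(V_max/a + Q)`; in the Rubisco-limited regime the PS II flux is
#' pinned by carboxylation and either the b6f turnover constant is derated
#' (`cef_mode = "minimal"`) or an uncoupled regulatory CEF1 keeps b6f at
#' maximum turnover (`cef_mode = "regulatory"`). The remaining degree of
#' freedom is closed by back-solving the NPQ constant K_N2
#' (`npq_mode = "kn2"`), by letting PS II closure float with K_N2 = 0
#' (`npq_mode = "none"`), or — with `state_transitions = TRUE` — by
#' re-balancing the cross-section split below the light-saturation point
#' and freezing it at its saturation value above.
#'
#' @param Q Incident PPFD (umol m^-2 s^-1); vectorized.
#' @param leaf A [leaf_parameters()] object.
#' @param env A [leaf_env()] object; `C` may be a vector recycled against
#'   `Q`.
#' @param k A [photo_constants()] object.
#' @param kin A [rubisco_kinetics()] object.
#' @param coupling Output of [coupling_efficiencies()].
#' @return A `data.frame` of class `steady_state`, one row per `Q`, with
#'   the regime label, assimilation rates, electron fluxes, closure
#'   fractions, turnover ratio, K_N2, effective cross-sections, yields of
#'   both photosystems and the light-saturation point.
#' @export
solve_steady_state <- function(Q, leaf = leaf_parameters(),
                               env = leaf_env(),
                               k = photo_constants(),
                               kin = rubisco_kinetics(),
                               coupling = coupling_efficiencies()) {
  stopifnot(all(Q >= 0))
  n <- max(length(Q), length(env$C), length(env$O))
  Q <- rep_len(Q, n)
  C <- rep_len(env$C, n)
  O <- rep_len(env$O, n)

  gs <- co2_compensation(rubisco_specificity(kin), O)
  if (any(C <= gs)) stop("C must exceed the compensation point")
  x <- gs / C
  eta <- eta_ratio(coupling$n_L, coupling$n_C, gs, C)
  V_c_mich <- leaf$V_max_rubc * C / (kin$K_c * (1 + O / kin$K_o) + C)
  A_c <- V_c_mich * (1 - x) - leaf$R_d

  # effective cross-sections and the saturation point
  J_req <- eta * (A_c + leaf$R_d) * (4 + 8 * x) / (1 - x)
  never_sat <- J_req >= leaf$V_max_cb6f
  f_sat <- ifelse(never_sat, 1, J_req / leaf$V_max_cb6f)
  if (leaf$state_transitions) {
    split_sat <- solve_cross_sections(eta, f_sat, k, leaf$alpha_total)
    a_sat <- psi_initial_slope(split_sat$alpha_1, k)
    Q_sat <- ifelse(never_sat, Inf,
                    J_req * (leaf$V_max_cb6f / a_sat) /
                      (leaf$V_max_cb6f - J_req))
    below <- Q < Q_sat
    f_light <- numeric(n)
    alpha_1_eff <- rep_len(split_sat$alpha_1, n)
    alpha_2_eff <- rep_len(split_sat$alpha_2, n)
    if (any(below)) {
      fb <- closure_with_split(Q[below], eta[below], k, leaf$alpha_total,
                               leaf$V_max_cb6f)
      f_light[below] <- fb
      sp <- solve_cross_sections(eta[below], fb, k, leaf$alpha_total)
      alpha_1_eff[below] <- sp$alpha_1
      alpha_2_eff[below] <- sp$alpha_2
    }
    if (any(!below)) {
      a_hi <- psi_initial_slope(alpha_1_eff[!below], k)
      f_light[!below] <- Q[!below] / (leaf$V_max_cb6f / a_hi + Q[!below])
    }
    # in darkness there is no flux to balance, so the split is the leaf's
    # own dark-adapted pigment state rather than the (indeterminate)
    # balance condition
    alpha_1_eff[Q == 0] <- leaf$alpha_1
    alpha_2_eff[Q == 0] <- leaf$alpha_2
  } else {
    alpha_1_eff <- rep_len(leaf$alpha_1, n)
    alpha_2_eff <- rep_len(leaf$alpha_2, n)
    a0 <- psi_initial_slope(leaf$alpha_1, k)
    Q_sat <- ifelse(never_sat, Inf,
                    J_req * (leaf$V_max_cb6f / a0) /
                      (leaf$V_max_cb6f - J_req))
    f_light <- Q / (leaf$V_max_cb6f / a0 + Q)
  }

  a_eff <- psi_initial_slope(alpha_1_eff, k)
  Jp700_prime <- f_light * leaf$V_max_cb6f
  Jp680_prime <- Jp700_prime / eta
  A_j <- Jp680_prime * (1 - x) / (4 + 8 * x) - leaf$R_d

  # ties (A_j = A_c at Q_sat, up to roundoff) classify as b6f-limited so
  # that k*/k_q is left-continuous
  b6f_lim <- A_j <= A_c + 1e-9 * (abs(A_c) + 1)
  regime <- ifelse(b6f_lim, "b6f_limited", "rubisco_limited")

  J_P680 <- ifelse(b6f_lim, Jp680_prime, V_c_mich * (4 + 8 * x))
  f2 <- f_light
  fb <- f_light
  k_ratio <- rep_len(1, n)
  if (leaf$cef_mode == "minimal") {
    J_CB6F <- ifelse(b6f_lim, Jp700_prime, eta * J_P680)
    if (leaf$b6f_control) {
      k_ratio <- ifelse(b6f_lim, 1,
                        ifelse(Jp700_prime > 0, J_CB6F / Jp700_prime, 1))
    } else {
      # no feedback on b6f: the PQ poise alone carries the restriction
      fb <- ifelse(b6f_lim, f_light,
                   pmin(J_CB6F / leaf$V_max_cb6f, 1))
      f2 <- fb
    }
  } else { # regulatory CEF1: b6f stays at maximum turnover and J'_CB6F
    J_CB6F <- Jp700_prime
  }
  J_P700 <- J_CB6F
  CEF1 <- J_P700 - J_P680

  # PS I closure from its rate law; equals f_light whenever J_P700 = J'_P700
  f1 <- ifelse(Q > 0, 1 - J_P700 / (Q * a_eff), 0)
  f1 <- pmin(pmax(f1, 0), 1)

  # close the PS II balance
  K_N2 <- numeric(n)
  psii_limited <- logical(n)
  if (leaf$npq_mode == "none") {
    f2 <- f2_closed_form(J_P680, Q, alpha_2_eff, k)
  } else {
    need <- Q > 0 & J_P680 > 0
    if (leaf$state_transitions) {
      # below saturation the split balances supply exactly (K_N2 = 0)
      need <- need & !(Q < Q_sat & b6f_lim)
    }
    if (any(need)) {
      N <- npq_closed_form(J_P680[need], Q[need], alpha_2_eff[need],
                           f2[need], k)
      bad <- N < 0
      if (any(bad)) {
        idx <- which(need)[bad]
        for (i in idx) {
          # PS II-limited corner: quenching cannot help; re-solve f2 = fb
          # from Q a2 Phi_P2(f2, 0) = f2 V_max / eta
          g <- function(f) Q[i] * alpha_2_eff[i] * phi_p2_at(f, k, 0) -
            f * leaf$V_max_cb6f / eta[i]
          f_root <- stats::uniroot(g, c(1e-12, 1 - 1e-12),
                                   tol = 1e-12)$root
          f2[i] <- f_root
          fb[i] <- f_root
          J_P680[i] <- f_root * leaf$V_max_cb6f / eta[i]
          J_CB6F[i] <- f_root * leaf$V_max_cb6f
          J_P700[i] <- J_CB6F[i]
          CEF1[i] <- J_P700[i] - J_P680[i]
          f1[i] <- min(max(1 - J_P700[i] / (Q[i] * a_eff[i]), 0), 1)
          psii_limited[i] <- TRUE
        }
        N[bad] <- 0
      }
      K_N2[need] <- pmax(N, 0)
    }
  }

  # realized carbon fluxes under the minimum rule
  A <- pmin(A_j, A_c)
  A[psii_limited] <- J_P680[psii_limited] * (1 - x[psii_limited]) /
    (4 + 8 * x[psii_limited]) - leaf$R_d
  A_g <- A + leaf$R_d
  V_c <- A_g / (1 - x)
  V_o <- 2 * x * V_c

  y2 <- psii_yields(f2, k, K_N2)
  y1 <- psi_yields(f1, k)

  out <- data.frame(
    Q = Q, C = C, O = O, regime = regime,
    A = A, A_j = A_j, A_c = A_c, A_g = A_g,
    V_c = V_c, V_o = V_o,
    J_P680 = J_P680, J_P700 = J_P700, J_CB6F = J_CB6F, CEF1 = CEF1,
    f1 = f1, f2 = f2, fb = fb,
    k_star_over_kq = k_ratio, K_N2 = K_N2,
    alpha_1_eff = alpha_1_eff, alpha_2_eff = alpha_2_eff,
    eta = eta, gamma_star = gs,
    Phi_P2 = y2$Phi_P2, Phi_N2 = y2$Phi_N2, Phi_D2 = y2$Phi_D2,
    Phi_F2 = y2$Phi_F2,
    Phi_P1 = y1$Phi_P1, Phi_F1 = y1$Phi_F1,
    Q_sat = Q_sat, psii_limited = psii_limited,
    stringsAsFactors = FALSE
  )
  class(out) <- c("steady_state", class(out))
  out
}
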