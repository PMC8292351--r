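# Forward operator from a solved steady state to detector-space PAM
# fluorescence levels, and the quenching indices an experimenter derives
# from them. The detector sums PS II and PS I emission; the extreme levels
# (Fm, Fm', Fo, Fo') use the open/closed rate-constant sums without the
# exciton-sharing term, matching the convention of the coupling expressions.

# detector-space fluorescence from cross-sections and fluorescence yields
detector_level <- function(alpha_2, Phi_F2, alpha_1, Phi_F1, detector) {
  detector$S_det * (alpha_2 * Phi_F2 * detector$eps_F2 +
                      alpha_1 * Phi_F1 * detector$eps_F1)
}

#' Fluorescence levels of a solved state
#'
#' Computes the steady-state level `F_s` from the state's own yields (with
#' exciton sharing), and the four extreme levels from the rate-constant
#' sums: `F_m` (dark-adapted, all PS II centers closed, K_N2 = 0), `F_m'`
#' (light-adapted K_N2, all closed), `F_o` (dark-adapted, all open) and
#' `F_o'` (light-adapted K_N2, all open). PS I emission contributes via
#' `K_F1` over the open- or closed-state PS I sums; PS I has no regulated
#' quenching, so its open/closed yields are the same in dark and light.
#'
#' Dark levels use the dark-adapted cross-sections: for a state-transition
#' leaf this is the balanced split at closure 0, otherwise the cross
#' sections in force.
#'
#' @param state One row (or a vectorized set of rows) of
#'   [solve_steady_state()] output.
#' @param k A [photo_constants()] object.
#' @param detector A [detector_model()].
#' @param alpha_dark Optional numeric vector `c(alpha_1, alpha_2)` of
#'   dark-adapted cross-sections for the `F_m`/`F_o` reference; defaults to
#'   the state's effective cross-sections (correct for fixed-pigment
#'   leaves).
#' @return `data.frame` with columns `F_s`, `F_m`, `F_m_prime`, `F_o`,
#'   `F_o_prime`.
#' @export
fluorescence_levels <- function(state, k = photo_constants(),
                                detector = detector_model(),
                                alpha_dark = NULL) {
  if (is.null(alpha_dark)) {
    a1_dark <- state$alpha_1_eff
    a2_dark <- state$alpha_2_eff
  } else {
    a1_dark <- alpha_dark[1]
    a2_dark <- alpha_dark[2]
  }
  s1_open <- k$K_P1 + k$K_D1 + k$K_F1
  s1_closed <- k$K_X1 + k$K_D1 + k$K_F1
  psi_open <- k$K_F1 / s1_open
  psi_closed <- k$K_F1 / s1_closed

  # PS II extreme-state sums (sharing term omitted at the extremes)
  f2_closed_dark <- k$K_F2 / (k$K_D2 + k$K_F2)
  f2_closed_light <- k$K_F2 / (state$K_N2 + k$K_D2 + k$K_F2)
  f2_open_dark <- k$K_F2 / (k$K_P2 + k$K_D2 + k$K_F2)
  f2_open_light <- k$K_F2 / (k$K_P2 + state$K_N2 + k$K_D2 + k$K_F2)

  data.frame(
    F_s = detector_level(state$alpha_2_eff, state$Phi_F2,
                         state$alpha_1_eff, state$Phi_F1, detector),
    F_m = detector_level(a2_dark, f2_closed_dark, a1_dark, psi_closed,
                         detector),
    F_m_prime = detector_level(state$alpha_2_eff, f2_closed_light,
                               state$alpha_1_eff, psi_closed, detector),
    F_o = detector_level(a2_dark, f2_open_dark, a1_dark, psi_open,
                         detector),
    F_o_prime = detector_level(state$alpha_2_eff, f2_open_light,
                               state$alpha_1_eff, psi_open, detector)
  )
}

#' PAM quenching analysis
#'
#' Derives the standard PAM indices from fluorescence levels, exactly as an
#' experimenter would: the Genty yield `Phi_P2_app = 1 - Fs/Fm'`, the
#' Hendrickson partition (`Phi_N2_app`, `Phi_DF2_app`), `NPQ = Fm/Fm' - 1`,
#' the puddle and lake openness indices `qP`, `qL`, the apparent linear
#' electron flux `LEF_app = Q * alpha_2_assumed * Phi_P2_app`, and the
#' apparent b6f conductances `k_Lake = LEF/(1 - qL)` and
#' `k_Puddle = LEF/(1 - qP)`.
#'
#' `alpha_2_assumed` defaults to the field convention 0.85 * 0.5 = 0.425 —
#' the diagnostic mimics what an experimenter computes, independent of the
#' model's actual cross-section.
#'
#' @param levels A `data.frame` as returned by [fluorescence_levels()] (or
#'   measured levels with the same columns).
#' @param Q Incident PPFD (umol m^-2 s^-1).
#' @param alpha_2_assumed Assumed PS II cross-section for `LEF_app`.
#' @return `data.frame` with the indices; degenerate denominators give
#'   `NA` rather than an error.
#' @export
pam_indices <- function(levels, Q, alpha_2_assumed = 0.85 * 0.5) {
  safe_div <- function(a, b) ifelse(abs(b) > 0, a / b, NA_real_)
  Phi_P2_app <- 1 - safe_div(levels$F_s, levels$F_m_prime)
  Phi_N2_app <- levels$F_s * (safe_div(1, levels$F_m_prime) -
                                safe_div(1, levels$F_m))
  Phi_DF2_app <- safe_div(levels$F_s, levels$F_m)
  NPQ <- safe_div(levels$F_m, levels$F_m_prime) - 1
  qP <- safe_div(levels$F_m_prime - levels$F_s,
                 levels$F_m_prime - levels$F_o_prime)
  qL <- qP * safe_div(levels$F_o_prime, levels$F_s)
  LEF_app <- Q * alpha_2_assumed * Phi_P2_app
  data.frame(
    Phi_P2_app = Phi_P2_app, Phi_N2_app = Phi_N2_app,
    Phi_DF2_app = Phi_DF2_app, NPQ = NPQ, qP = qP, qL = qL,
    LEF_app = LEF_app,
    k_Lake = safe_div(LEF_app, 1 - qL),
    k_Puddle = safe_div(LEF_app, 1 - qP)
  )
}

#' Estimate the maximum Cyt b6f activity from PAM records
#'
#' Under limiting light the apparent b6f conductance is maximal, so each
#' record's `k_Lake = LEF/(1 - qL)` extrapolates the linear electron flux
#' to a fully reduced plastoquinone pool. The estimate is the median of
#' `k_Lake` over the records flagged as light-limited.
#'
#' @param indices A `data.frame` from [pam_indices()] over a series of
#'   records.
#' @param limiting_light_mask Logical vector selecting records taken under
#'   limiting light (with `qL < 1`).
#' @return The `V_max` estimate (umol e- m^-2 s^-1).
#' @export
estimate_vmax_b6f <- function(indices, limiting_light_mask) {
  m <- limiting_light_mask & is.finite(indices$k_Lake) & indices$qL < 1
  if (!any(m)) stop("no usable light-limited records under the mask")
  stats::median(indices$k_Lake[m])
}
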