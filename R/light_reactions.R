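# Yield algebra and rate laws for PS I, PS II and Cyt b6f. All rate laws are
# written in ratio (concentration-free) form: closure fractions f in [0,1]
# replace absolute complex concentrations, and V_max(CB6F) carries the only
# absolute scale in the electron transport chain.

#' PS I de-excitation yields at a given closure fraction
#'
#' Open centers (weight 1-f1) quench via photochemistry K_P1; closed
#' (oxidized) centers (weight f1) via K_X1. Heat loss K_D1 and fluorescence
#' K_F1 act in both states.
#'
#' @param f1 Fraction of closed PS I centers, in `[0, 1]`; vectorized.
#' @param k A [photo_constants()] object.
#' @return List of vectors `Phi_P1`, `Phi_X1`, `Phi_D1`, `Phi_F1`
#'   (mol dissipated mol^-1 absorbed; sum to 1).
#' @export
psi_yields <- function(f1, k = photo_constants()) {
  stopifnot(all(f1 >= 0 & f1 <= 1))
  s0 <- k$K_P1 + k$K_D1 + k$K_F1
  sp <- k$K_X1 + k$K_D1 + k$K_F1
  list(Phi_P1 = (1 - f1) * k$K_P1 / s0,
       Phi_X1 = f1 * k$K_X1 / sp,
       Phi_D1 = (1 - f1) * k$K_D1 / s0 + f1 * k$K_D1 / sp,
       Phi_F1 = (1 - f1) * k$K_F1 / s0 + f1 * k$K_F1 / sp)
}

#' PS II de-excitation yields with exciton sharing
#'
#' Internal yields describe the fate of excitation leaving a single unit
#' (photochemistry, regulated heat loss K_N2, constitutive heat loss,
#' fluorescence, transfer to a neighboring unit K_U2); overall yields follow
#' from the geometric series over repeated transfers,
#' Phi_X = phi_X / (1 - phi_U2).
#'
#' `K_U2 = Inf` (pure lake connectivity) is evaluated in its analytic limit:
#' Phi_P2 = (1-f2) K_P2 / (SK0 - f2 K_P2) with SK0 = K_P2+K_N2+K_D2+K_F2,
#' and the non-photochemical yields split the remainder in proportion to
#' their rate constants.
#'
#' @param f2 Fraction of closed PS II centers, in `[0, 1]`; vectorized.
#' @param k A [photo_constants()] object (supplies `K_U2`).
#' @param K_N2 Regulated heat-loss rate constant (ns^-1); vectorized.
#' @return List with internal yields `phi_*`, overall yields `Phi_*`, and
#'   `phi_U2`.
#' @export
psii_yields <- function(f2, k = photo_constants(), K_N2 = 0) {
  stopifnot(all(f2 >= 0 & f2 <= 1), all(K_N2 >= 0))
  u <- k$K_U2
  c0 <- k$K_P2 + K_N2 + k$K_D2 + k$K_F2   # open-state sum minus sharing
  cm <- K_N2 + k$K_D2 + k$K_F2            # closed-state sum minus sharing
  if (is.infinite(u)) {
    den <- c0 - f2 * k$K_P2
    Phi_P2 <- (1 - f2) * k$K_P2 / den
    z <- rep_len(0, length(Phi_P2))
    return(list(phi_P2 = z, phi_N2 = z, phi_D2 = z, phi_F2 = z,
                phi_U2 = rep_len(1, length(Phi_P2)),
                Phi_P2 = Phi_P2,
                Phi_N2 = K_N2 / den,
                Phi_D2 = k$K_D2 / den,
                Phi_F2 = k$K_F2 / den))
  }
  s0 <- c0 + u
  sm <- cm + u
  w_open <- (1 - f2) / s0
  w_closed <- f2 / sm
  phi_P2 <- (1 - f2) * k$K_P2 / s0
  phi_N2 <- K_N2 * (w_open + w_closed)
  phi_D2 <- k$K_D2 * (w_open + w_closed)
  phi_F2 <- k$K_F2 * (w_open + w_closed)
  phi_U2 <- u * (w_open + w_closed)
  if (any(phi_U2 >= 1)) stop("phi_U2 >= 1: exciton sharing diverges")
  g <- 1 / (1 - phi_U2)
  list(phi_P2 = phi_P2, phi_N2 = phi_N2, phi_D2 = phi_D2,
       phi_F2 = phi_F2, phi_U2 = phi_U2,
       Phi_P2 = phi_P2 * g, Phi_N2 = phi_N2 * g,
       Phi_D2 = phi_D2 * g, Phi_F2 = phi_F2 * g)
}

#' Electron flux through Cyt b6f
#'
#' J_CB6F = f_b V_max (k*/k_q): occupancy of the Qp site by plastoquinol
#' times the maximum activity, derated by the current turnover ratio.
#'
#' @param fb Fraction of b6f sites occupied by PQH2, in `[0, 1]`.
#' @param V_max_cb6f Maximum b6f activity (umol e- m^-2 s^-1).
#' @param k_star_over_kq Current over maximum turnover constant, in
#'   `(0, 1]`.
#' @return J_CB6F (umol e- m^-2 s^-1).
#' @export
cytb6f_flux <- function(fb, V_max_cb6f, k_star_over_kq = 1) {
  stopifnot(all(fb >= 0 & fb <= 1),
            all(k_star_over_kq >= 0 & k_star_over_kq <= 1))
  fb * V_max_cb6f * k_star_over_kq
}

# Initial slope of the PS I light response: alpha_1 * K_P1 / (sum of open
# PS I rate constants). Every hyperbola in the solver is parameterized by it.
psi_initial_slope <- function(alpha_1, k) {
  alpha_1 * k$K_P1 / (k$K_P1 + k$K_D1 + k$K_F1)
}

#' Potential (b6f-limited) PS I electron flux
#'
#' The rectangular hyperbola J'_P700 = V_max Q / (V_max/a + Q) with initial
#' slope a = alpha_1 K_P1 / (K_P1 + K_D1 + K_F1); asymptote V_max(CB6F).
#'
#' @param Q Incident PPFD (umol m^-2 s^-1); vectorized.
#' @param alpha_1 PS I absorbance cross-section.
#' @param k A [photo_constants()] object.
#' @param V_max_cb6f Maximum b6f activity (umol e- m^-2 s^-1).
#' @return J'_P700 (umol e- m^-2 s^-1).
#' @export
potential_psi_rate <- function(Q, alpha_1, k = photo_constants(),
                               V_max_cb6f = 350) {
  stopifnot(all(Q >= 0))
  a <- psi_initial_slope(alpha_1, k)
  V_max_cb6f * Q / (V_max_cb6f / a + Q)
}

#' Shared closure fraction at a given light intensity
#'
#' In any state poised per the donor-side balance, the closed fractions of
#' PS II, the PQH2 occupancy of b6f and the oxidized fraction of PS I share
#' the value f = Q / (V_max/a + Q), the closure at which the potential PS I
#' flux f V_max equals light capture by open centers.
#'
#' @inheritParams potential_psi_rate
#' @return Closure fraction in `[0, 1)`.
#' @export
closure_at_light <- function(Q, alpha_1, k = photo_constants(),
                             V_max_cb6f = 350) {
  stopifnot(all(Q >= 0))
  a <- psi_initial_slope(alpha_1, k)
  Q / (V_max_cb6f / a + Q)
}

#' Realized PS II and PS I electron fluxes
#'
#' J_P680 = Q alpha_2 Phi_P2(f2) and J_P700 = Q alpha_1 Phi_P1(f1): light
#' capture by each bed times the overall photochemical yield at the current
#' closure.
#'
#' @param f2,f1 Closure fractions.
#' @param Q Incident PPFD (umol m^-2 s^-1).
#' @param alpha_2,alpha_1 Absorbance cross-sections.
#' @param k A [photo_constants()] object.
#' @param K_N2 Regulated heat-loss constant for PS II (ns^-1).
#' @return The flux in umol e- m^-2 s^-1.
#' @export
psii_flux <- function(f2, Q, alpha_2, k = photo_constants(), K_N2 = 0) {
  Q * alpha_2 * psii_yields(f2, k, K_N2)$Phi_P2
}

#' @rdname psii_flux
#' @export
psi_flux <- function(f1, Q, alpha_1, k = photo_constants()) {
  Q * alpha_1 * psi_yields(f1, k)$Phi_P1
}
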