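#' Photochemical rate constants for PS I and PS II
#'
#' Exciton de-excitation rate constants for the two photosystems, in ns^-1.
#' Open PS I centers dissipate via photochemistry (`K_P1`), constitutive heat
#' loss (`K_D1`) and fluorescence (`K_F1`); closed (oxidized) PS I centers
#' quench via `K_X1`, which is parameterized as numerically equal to `K_P1`
#' so that closed centers quench to heat as efficiently as open centers
#' quench photochemically. PS II adds inter-unit exciton sharing (`K_U2`) and
#' a regulated heat-loss constant (`K_N2`) which is a state variable of the
#' solved leaf, not a constant, and is therefore not stored here.
#'
#' Defaults give a maximum PS I photochemical yield of 14.5/15.1 (96%), a
#' maximum PS II photochemical yield of 4.5/5.1 (88%), and a closed-state
#' PS II fluorescence yield of 0.05/0.6 (8%).
#'
#' @param K_P1,K_D1,K_F1 PS I rate constants (ns^-1).
#' @param K_X1 Heat-loss constant of closed PS I centers (ns^-1); defaults to
#'   `K_P1`.
#' @param K_P2,K_D2,K_F2 PS II rate constants (ns^-1).
#' @param K_U2 PS II inter-unit exciton sharing constant (ns^-1). May be
#'   `Inf` for pure lake-type connectivity (handled analytically).
#' @return An object of class `photo_constants` (named list).
#' @export
photo_constants <- function(K_P1 = 14.5, K_D1 = 0.55, K_F1 = 0.05,
                            K_X1 = K_P1,
                            K_P2 = 4.5, K_D2 = 0.55, K_F2 = 0.05,
                            K_U2 = 0) {
  stopifnot(K_P1 >= 0, K_D1 >= 0, K_F1 >= 0, K_X1 >= 0,
            K_P2 >= 0, K_D2 >= 0, K_F2 >= 0, K_U2 >= 0)
  structure(list(K_P1 = K_P1, K_D1 = K_D1, K_F1 = K_F1, K_X1 = K_X1,
                 K_P2 = K_P2, K_D2 = K_D2, K_F2 = K_F2, K_U2 = K_U2),
            class = "photo_constants")
}

#' Rubisco kinetic constants at 25 degrees C
#'
#' @param k_c Catalytic constant for CO2 (mol CO2 mol^-1 sites s^-1).
#' @param K_c Michaelis constant for CO2 (ubar).
#' @param k_o Catalytic constant for O2 (mol O2 mol^-1 sites s^-1).
#' @param K_o Michaelis constant for O2 (mbar).
#' @return An object of class `rubisco_kinetics`.
#' @export
rubisco_kinetics <- function(k_c = 3.6, K_c = 260, k_o = 0.9, K_o = 179) {
  if (any(c(k_c, K_c, k_o, K_o) <= 0))
    stop("Rubisco kinetic constants must be strictly positive")
  structure(list(k_c = k_c, K_c = K_c, k_o = k_o, K_o = K_o),
            class = "rubisco_kinetics")
}

#' Driving environment of a leaf
#'
#' @param Q Incident photosynthetically active radiation
#'   (umol PPFD m^-2 s^-1); may be a vector.
#' @param T_leaf Leaf temperature (degrees C). The model is parameterized at
#'   25 C; other temperatures are carried through but do not rescale the
#'   kinetic constants.
#' @param C Chloroplast CO2 partial pressure (ubar); recycled against `Q`.
#' @param O Chloroplast O2 partial pressure (mbar).
#' @param P Air pressure (bar).
#' @return An object of class `leaf_env`.
#' @export
leaf_env <- function(Q = 0, T_leaf = 25, C = 200, O = 209, P = 1) {
  stopifnot(all(Q >= 0), all(C > 0), all(O >= 0), all(P > 0))
  structure(list(Q = Q, T_leaf = T_leaf, C = C, O = O, P = P),
            class = "leaf_env")
}

#' Leaf biochemical parameters
#'
#' Absorbance partitioning, maximum enzyme activities, respiration and the
#' regulatory mode switches of the solver.
#'
#' `alpha_1 + alpha_2 = alpha_total` is enforced: when only `alpha_total`
#' is supplied the default Table split 0.41/0.44 is rescaled to it.
#'
#' @param alpha_total Total leaf absorbance to PAR (mol mol^-1).
#' @param alpha_1,alpha_2 PS I and PS II absorbance cross-sections
#'   (mol absorbed mol^-1 incident). Must sum to `alpha_total`.
#' @param V_max_cb6f Maximum Cyt b6f activity (umol e- m^-2 s^-1).
#' @param V_max_rubc Maximum Rubisco carboxylase activity
#'   (umol CO2 m^-2 s^-1).
#' @param R_d Day respiration (umol CO2 m^-2 s^-1). Default reads the
#'   tabulated "0.01" as a fraction of `V_max_rubc`.
#' @param g_m Mesophyll conductance (mol CO2 m^-2 s^-1 bar^-1).
#' @param state_transitions Logical; permit pigment redistribution between
#'   the photosystem beds (qT) under limiting light. When `TRUE`, `alpha_1`
#'   and `alpha_2` are re-solved by the balance condition and the supplied
#'   values are ignored below light saturation.
#' @param cef_mode `"minimal"` (CEF1 only balances the ATP budget;
#'   photosynthetic control acts through the b6f turnover constant) or
#'   `"regulatory"` (an uncoupled CEF1 keeps b6f at maximum turnover above
#'   saturation).
#' @param npq_mode `"kn2"` (regulated heat loss K_N2 is back-solved to
#'   balance PS II supply) or `"none"` (K_N2 pinned at 0; PS II closure
#'   floats instead).
#' @param b6f_control Logical; when `FALSE`, feedback on the b6f turnover
#'   constant is disabled and balance above saturation is reached through
#'   the plastoquinone poise alone.
#' @param k_q Maximum b6f turnover constant (mol PQH2 mol^-1 sites s^-1).
#'   Enters only through the ratio k*/k_q; the electron-basis scale is
#'   carried by `V_max_cb6f`.
#' @return An object of class `leaf_parameters`.
#' @export
leaf_parameters <- function(alpha_total = 0.85,
                            alpha_1 = alpha_total * 0.41 / 0.85,
                            alpha_2 = alpha_total - alpha_1,
                            V_max_cb6f = 350, V_max_rubc = 100,
                            R_d = 0.01 * V_max_rubc,
                            g_m = 0.084,
                            state_transitions = FALSE,
                            cef_mode = c("minimal", "regulatory"),
                            npq_mode = c("kn2", "none"),
                            b6f_control = TRUE,
                            k_q = 300) {
  cef_mode <- match.arg(cef_mode)
  npq_mode <- match.arg(npq_mode)
  if (abs(alpha_1 + alpha_2 - alpha_total) > 1e-9)
    stop("alpha_1 + alpha_2 must equal alpha_total")
  stopifnot(alpha_total > 0, alpha_1 > 0, alpha_2 > 0,
            V_max_cb6f > 0, V_max_rubc > 0, R_d >= 0, g_m > 0, k_q > 0)
  structure(list(alpha_total = alpha_total, alpha_1 = alpha_1,
                 alpha_2 = alpha_2, V_max_cb6f = V_max_cb6f,
                 V_max_rubc = V_max_rubc, R_d = R_d, g_m = g_m,
                 state_transitions = state_transitions,
                 cef_mode = cef_mode, npq_mode = npq_mode,
                 b6f_control = b6f_control, k_q = k_q),
            class = "leaf_parameters")
}

#' PAM detector model
#'
#' Fluorescence reaching a PAM detector is a weighted sum of PS II and PS I
#' emission. The absolute detector scale `S_det` and the PS II weighting
#' `eps_F2` only ever occur as the product `S_det * eps_F2`, so all derived
#' PAM indices are invariant to it; the physically meaningful free quantity
#' is the ratio `eps_F1/eps_F2`.
#'
#' @param S_det Arbitrary detector sensitivity (> 0).
#' @param eps_F2,eps_F1 Emission-to-detector weighting factors for PS II and
#'   PS I (mol photons at detector mol^-1 emitted).
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(S_det = 1, eps_F2 = 1, eps_F1 = 0) {
  stopifnot(S_det > 0, eps_F2 >= 0, eps_F1 >= 0)
  structure(list(S_det = S_det, eps_F2 = eps_F2, eps_F1 = eps_F1,
                 eps_ratio = if (eps_F2 > 0) eps_F1 / eps_F2 else NA_real_),
            class = "detector_model")
}
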