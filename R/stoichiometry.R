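#' Rubisco specificity for CO2 relative to O2
#'
#' S = (k_c/K_c) / (k_o/K_o), with both Michaelis constants expressed in a
#' common pressure unit (ubar) before the ratio is taken.
#'
#' @param kin A [rubisco_kinetics()] object.
#' @return Dimensionless specificity (mol CO2 mol^-1 O2).
#' @export
rubisco_specificity <- function(kin = rubisco_kinetics()) {
  if (any(unlist(kin) <= 0))
    stop("Rubisco kinetics must be strictly positive")
  # K_o arrives in mbar; 1 mbar = 1000 ubar
  (kin$k_c / kin$K_c) * (kin$K_o * 1000 / kin$k_o)
}

#' CO2 compensation point in the absence of day respiration
#'
#' Gamma* = O / (2 S): the chloroplast pCO2 at which carboxylase CO2 uptake
#' balances photorespiratory CO2 release.
#'
#' @param S_spec Rubisco specificity (dimensionless).
#' @param O Chloroplast O2 partial pressure (mbar).
#' @return Gamma* in ubar.
#' @export
co2_compensation <- function(S_spec, O) {
  if (any(S_spec <= 0)) stop("S_spec must be > 0")
  0.5 * (O * 1000) / S_spec
}

#' Coupling scenario for the thylakoid proton circuit
#'
#' @param q_cycle_on Logical; constitutive Q-cycle at Cyt b6f
#'   (2 H+ per electron when on, 1 when off).
#' @param ndh_pump_on Logical; NDH-mediated Fd->PQ transfer pumping
#'   2 H+ per electron in cyclic flow.
#' @param h_per_atp Protons per ATP at the ATP synthase: 4 (thermodynamic)
#'   or 14/3 (structural, 14 c-subunits per 3 ATP).
#' @return An object of class `coupling_scenario`.
#' @export
coupling_scenario <- function(q_cycle_on = TRUE, ndh_pump_on = TRUE,
                              h_per_atp = 4) {
  if (!isTRUE(all.equal(h_per_atp, 4)) && !isTRUE(all.equal(h_per_atp, 14 / 3)))
    stop("h_per_atp must be 4 or 14/3")
  structure(list(q_cycle_on = isTRUE(q_cycle_on),
                 ndh_pump_on = isTRUE(ndh_pump_on),
                 h_per_atp = h_per_atp),
            class = "coupling_scenario")
}

#' ATP coupling efficiencies of linear and cyclic electron flow
#'
#' Proton bookkeeping per electron. Linear flow deposits 1 H+ in the lumen
#' at water oxidation plus 2 (Q-cycle) or 1 (no Q-cycle) at plastoquinol
#' oxidation by b6f. Cyclic flow deposits the b6f contribution plus 2 per
#' electron when the NDH pump mediates Fd->PQ transfer (0 otherwise). Each
#' ATP costs `h_per_atp` lumen protons at the synthase.
#'
#' The reference scenario (Q-cycle on, NDH on, 4 H+/ATP) gives
#' n_L = 3/4 = 0.75 and n_C = 4/4 = 1.00.
#'
#' @param scenario A [coupling_scenario()].
#' @return List with `n_L`, `n_C` (mol ATP mol^-1 e-) and the underlying
#'   lumen-proton counts `H_LEF`, `H_CEF`.
#' @export
coupling_efficiencies <- function(scenario = coupling_scenario()) {
  h_b6f <- if (scenario$q_cycle_on) 2 else 1
  H_LEF <- 1 + h_b6f
  H_CEF <- h_b6f + if (scenario$ndh_pump_on) 2 else 0
  list(n_L = H_LEF / scenario$h_per_atp,
       n_C = H_CEF / scenario$h_per_atp,
       H_LEF = H_LEF, H_CEF = H_CEF)
}

#' Required ratio of PS I to PS II electron flow
#'
#' eta = 1 - n_L/n_C + (3 + 7 G/C) / ((4 + 8 G/C) n_C), the PS I:PS II flux
#' ratio that simultaneously balances the Fd, NADPH and ATP budgets. The
#' cyclic fraction of total PS I electron flow is 1 - 1/eta.
#'
#' @param n_L,n_C ATP per electron in linear and cyclic flow.
#' @param gamma_star CO2 compensation point (ubar).
#' @param C Chloroplast CO2 partial pressure (ubar); may be a vector.
#' @return eta (mol e- PS I per mol e- PS II).
#' @export
eta_ratio <- function(n_L, n_C, gamma_star, C) {
  if (any(n_C <= 0)) stop("n_C must be > 0")
  if (any(C <= 0)) stop("C must be > 0")
  x <- gamma_star / C
  1 - n_L / n_C + (3 + 7 * x) / ((4 + 8 * x) * n_C)
}

#' Cyclic fraction of PS I electron flow
#'
#' @param eta PS I : PS II flux ratio, see [eta_ratio()].
#' @return CEF1 / J_P700 = 1 - 1/eta.
#' @export
cef1_fraction <- function(eta) 1 - 1 / eta

#' Electron-transport requirements of a given assimilation rate
#'
#' J_P680 = (A + R_d) (4 + 8 G/C) / (1 - G/C) and J_P700 = eta J_P680.
#'
#' @param A Net CO2 assimilation (umol m^-2 s^-1).
#' @param R_d Day respiration (umol m^-2 s^-1).
#' @param C Chloroplast CO2 (ubar).
#' @param gamma_star CO2 compensation point (ubar).
#' @param eta PS I : PS II flux ratio.
#' @return List with `J_P680` and `J_P700` (umol e- m^-2 s^-1).
#' @export
electron_requirements <- function(A, R_d, C, gamma_star, eta) {
  if (any(C <= gamma_star)) stop("C must exceed the compensation point")
  x <- gamma_star / C
  J_P680 <- (A + R_d) * (4 + 8 * x) / (1 - x)
  list(J_P680 = J_P680, J_P700 = eta * J_P680)
}

#' Metabolic demand for NADPH, Fd and ATP
#'
#' PCR/PCO stoichiometry per carboxylation and oxygenation:
#' J_NADPH = 2 V_c + 1.5 V_o, J_Fd = V_o, J_ATP = 3 V_c + 3.5 V_o.
#'
#' @param V_c Carboxylation rate (umol CO2 m^-2 s^-1).
#' @param V_o Oxygenation rate (umol O2 m^-2 s^-1).
#' @return List with `V_c`, `V_o`, `J_NADPH`, `J_Fd`, `J_ATP`.
#' @export
demand_fluxes <- function(V_c, V_o) {
  if (any(V_c < 0) || any(V_o < 0)) stop("rates must be non-negative")
  list(V_c = V_c, V_o = V_o,
       J_NADPH = 2 * V_c + 1.5 * V_o,
       J_Fd = V_o,
       J_ATP = 3 * V_c + 3.5 * V_o)
}

#' Reductant and ATP supply of the electron transport chain
#'
#' Linear flow provides all reductant (J_P680 = J_Fd + 2 J_NADPH);
#' ATP supply is J_P680 n_L + (J_P700 - J_P680) n_C.
#'
#' @param J_P680,J_P700 PS II and PS I electron fluxes (umol e- m^-2 s^-1);
#'   `J_P700 >= J_P680` (the excess is cyclic flow).
#' @param n A list with `n_L`, `n_C`, as from [coupling_efficiencies()].
#' @return List with `reductant_e` (= J_P680) and `J_ATP_supply`.
#' @export
supply_fluxes <- function(J_P680, J_P700, n) {
  if (any(J_P680 < 0)) stop("J_P680 must be non-negative")
  if (any(J_P700 - J_P680 < -1e-9 * pmax(1, J_P700)))
    stop("J_P700 < J_P680 implies negative cyclic flow")
  list(reductant_e = J_P680,
       J_ATP_supply = J_P680 * n$n_L + (J_P700 - J_P680) * n$n_C)
}

#' Gross and net CO2 assimilation from Rubisco rates
#'
#' A_g = V_c - 0.5 V_o (0.5 mol CO2 released per mol O2 fixed in
#' photorespiration); A = A_g - R_d.
#'
#' @param V_c,V_o Carboxylation and oxygenation rates (umol m^-2 s^-1).
#' @param R_d Day respiration (umol CO2 m^-2 s^-1).
#' @return List with `A_g` and `A`.
#' @export
assimilation <- function(V_c, V_o, R_d = 0) {
  if (any(V_c < 0) || any(V_o < 0)) stop("rates must be non-negative")
  A_g <- V_c - 0.5 * V_o
  list(A_g = A_g, A = A_g - R_d)
}

#' Oxygenation : carboxylation ratio at given gas pressures
#'
#' V_o / V_c = (1/S) O/C = 2 Gamma*/C.
#'
#' @param S_spec Rubisco specificity.
#' @param C Chloroplast CO2 (ubar).
#' @param O Chloroplast O2 (mbar).
#' @return The ratio V_o/V_c.
#' @export
vo_vc_ratio <- function(S_spec, C, O) {
  (O * 1000) / (S_spec * C)
}
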