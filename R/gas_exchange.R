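# CO2 diffusion path from cuvette air to the chloroplast stroma: the
# ternary-corrected boundary-layer/stomatal step and a single lumped
# mesophyll conductance.

#' Intercellular CO2 from a gas-exchange record
#'
#' The standard ternary-corrected relation
#' `C_i = ((g_tc - E/2) C_a - A) / (g_tc + E/2)`, with the transpiration
#' flux converted from mmol to mol m^-2 s^-1.
#'
#' @param A Net CO2 assimilation (umol m^-2 s^-1); vectorized.
#' @param g_tc Total (boundary-layer + stomatal) conductance to CO2
#'   (mol m^-2 s^-1).
#' @param C_a Cuvette CO2 partial pressure (ubar).
#' @param E_mmol Transpiration rate (mmol H2O m^-2 s^-1).
#' @return `C_i` in ubar; `NA` with a warning for non-physical records
#'   (`C_i < 0`).
#' @export
intercellular_co2 <- function(A, g_tc, C_a, E_mmol = 0) {
  E <- E_mmol / 1000
  if (any(g_tc <= E / 2)) stop("g_tc must exceed E/2")
  C_i <- ((g_tc - E / 2) * C_a - A) / (g_tc + E / 2)
  if (any(C_i < 0, na.rm = TRUE)) {
    warning("non-physical record(s): C_i < 0 flagged as NA")
    C_i[C_i < 0] <- NA_real_
  }
  C_i
}

#' Chloroplast CO2 from intercellular CO2
#'
#' `C_c = C_i - A/g_m`; with `g_m` in mol m^-2 s^-1 bar^-1 and `A` in
#' umol m^-2 s^-1, `A/g_m` is in ubar.
#'
#' @param C_i Intercellular CO2 (ubar).
#' @param A Net CO2 assimilation (umol m^-2 s^-1).
#' @param g_m Mesophyll conductance (mol CO2 m^-2 s^-1 bar^-1).
#' @return `C_c` in ubar; `NA` with a warning where `C_c <= 0`.
#' @export
chloroplast_co2 <- function(C_i, A, g_m) {
  if (any(g_m <= 0)) stop("g_m must be positive")
  C_c <- C_i - A / g_m
  if (any(C_c <= 0, na.rm = TRUE)) {
    warning("non-physical record(s): C_c <= 0 flagged as NA")
    C_c[C_c <= 0] <- NA_real_
  }
  C_c
}

#' Cuvette CO2 consistent with a chloroplast CO2 (inverse path)
#'
#' Inverts [intercellular_co2()] and [chloroplast_co2()]; used by the
#' synthetic-data generator to emit gas-exchange records whose diffusion
#' path reproduces a prescribed `C_c`.
#'
#' @inheritParams intercellular_co2
#' @param C_c Chloroplast CO2 (ubar).
#' @param g_m Mesophyll conductance (mol m^-2 s^-1 bar^-1).
#' @return `C_a` in ubar.
#' @export
cuvette_co2_from_chloroplast <- function(C_c, A, g_m, g_tc, E_mmol = 0) {
  E <- E_mmol / 1000
  C_i <- C_c + A / g_m
  (C_i * (g_tc + E / 2) + A) / (g_tc - E / 2)
}
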