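# Protocol-faithful synthetic datasets: a light sine-wave schedule, the
# forward model run at each sample, and multiplicative measurement noise —
# so the inversion machinery can be exercised end-to-end with no external
# data.

#' Light sine-wave protocol
#'
#' Q(t) = peak_Q * sin(pi t / duration), sampled every `interval_min`
#' minutes and clipped at zero; the first and last samples fall in
#' darkness.
#'
#' @param peak_Q Peak PPFD (umol m^-2 s^-1).
#' @param duration_h Protocol length (hours).
#' @param interval_min Sampling interval (minutes); must divide the
#'   duration.
#' @return `data.frame` with `time_s` and `Q`.
#' @export
sine_wave_protocol <- function(peak_Q, duration_h = 8, interval_min = 8) {
  stopifnot(peak_Q >= 0, duration_h > 0, interval_min > 0)
  n_steps <- duration_h * 60 / interval_min
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("interval must divide the duration")
  t_h <- seq(0, duration_h, by = interval_min / 60)
  Q <- pmax(peak_Q * sin(pi * t_h / duration_h), 0)
  Q[Q < peak_Q * 1e-9] <- 0   # zap the floating-point residue of sin(pi)
  data.frame(time_s = t_h * 3600, Q = Q)
}

#' Multiplicative measurement-noise model
#'
#' Mean-one lognormal noise: a draw with coefficient of variation `cv`
#' multiplies each observation.
#'
#' @param cv_fluor CV of the fluorescence channels.
#' @param cv_gas CV of the gas-exchange channels.
#' @param seed RNG seed applied by [generate_dataset()].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_fluor = 0, cv_gas = 0, seed = 1L) {
  stopifnot(cv_fluor >= 0, cv_gas >= 0)
  structure(list(cv_fluor = cv_fluor, cv_gas = cv_gas, seed = seed),
            class = "noise_model")
}

# mean-one lognormal factors with coefficient of variation cv
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a paired PAM + gas-exchange dataset
#'
#' Runs the steady-state solver at every protocol sample (chloroplast CO2
#' held at `env_base$C`, the simulations' convention), forwards each state
#' through the fluorescence operator, emits gas-exchange records whose
#' diffusion path (fixed `g_tc`, `E`) reproduces the prescribed chloroplast
#' CO2, and applies seeded multiplicative noise. Samples at Q = 0 become
#' dark records carrying `F_m`/`F_o`; lit samples carry `F_m'`/`F_o'`.
#'
#' @param leaf A [leaf_parameters()] object (the truth).
#' @param env_base A [leaf_env()] giving C, O, P and temperature.
#' @param protocol Output of [sine_wave_protocol()] (or any `data.frame`
#'   with `time_s`, `Q`).
#' @param noise A [noise_model()].
#' @param detector A [detector_model()].
#' @param k,kin,coupling Model constants as in [solve_steady_state()].
#' @param g_tc Total conductance to CO2 written into the records
#'   (mol m^-2 s^-1).
#' @param E_mmol Transpiration written into the records (mmol m^-2 s^-1).
#' @return A `data.frame` of class `pam_dataset` in the standard column
#'   layout: `time_s`, `record_type`, `Q`, `T_leaf`, `C_a`, `O_mbar`,
#'   `P_bar`, `A`, `E_mmol`, `g_tc`, `F_s`, `F_m_or_Fm_prime`,
#'   `F_o_or_Fo_prime`.
#' @export
generate_dataset <- function(leaf, env_base = leaf_env(),
                             protocol = sine_wave_protocol(2400),
                             noise = noise_model(),
                             detector = detector_model(),
                             k = photo_constants(),
                             kin = rubisco_kinetics(),
                             coupling = coupling_efficiencies(),
                             g_tc = 0.2, E_mmol = 1.5) {
  set.seed(noise$seed)
  Q <- protocol$Q
  env <- leaf_env(Q = Q, T_leaf = env_base$T_leaf, C = env_base$C,
                  O = env_base$O, P = env_base$P)
  st <- solve_steady_state(Q, leaf, env, k, kin, coupling)
  dark_ref <- c(st$alpha_1_eff[st$Q == 0][1], st$alpha_2_eff[st$Q == 0][1])
  if (any(is.na(dark_ref))) {
    st0 <- solve_steady_state(0, leaf, env, k, kin, coupling)
    dark_ref <- c(st0$alpha_1_eff, st0$alpha_2_eff)
  }
  lv <- fluorescence_levels(st, k, detector, alpha_dark = dark_ref)

  dark <- Q <= 0
  A_true <- st$A
  C_a <- cuvette_co2_from_chloroplast(st$C, A_true, leaf$g_m, g_tc, E_mmol)

  A_obs <- A_true * lognormal_factors(length(Q), noise$cv_gas)
  nf <- function(v) v * lognormal_factors(length(v), noise$cv_fluor)

  out <- data.frame(
    time_s = protocol$time_s,
    record_type = ifelse(dark, "dark", "light"),
    Q = Q,
    T_leaf = env_base$T_leaf,
    C_a = C_a,
    O_mbar = st$O,
    P_bar = env_base$P,
    A = A_obs,
    E_mmol = E_mmol,
    g_tc = g_tc,
    F_s = nf(lv$F_s),
    F_m_or_Fm_prime = nf(ifelse(dark, lv$F_m, lv$F_m_prime)),
    F_o_or_Fo_prime = nf(ifelse(dark, lv$F_o, lv$F_o_prime)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pam_dataset", class(out))
  out
}
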