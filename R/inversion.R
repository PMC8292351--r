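# Multiobjective inversion: fit the six free leaf parameters to a paired
# PAM + gas-exchange series by simultaneously minimizing a fluorescence
# misfit and a gas-exchange misfit with an elitist NSGA-II, and summarize
# the resulting Pareto population.

#' Free parameters of the inversion
#'
#' @param alpha_2 PS II absorbance cross-section (dark-adapted;
#'   `alpha_1 = alpha_total - alpha_2`).
#' @param K_U2 PS II exciton-sharing rate constant (ns^-1).
#' @param V_max_cb6f Maximum Cyt b6f activity (umol e- m^-2 s^-1).
#' @param V_max_rubc Maximum Rubisco activity (umol CO2 m^-2 s^-1).
#' @param g_m Mesophyll conductance (mol m^-2 s^-1 bar^-1).
#' @param eps_ratio PS I : PS II fluorescence detector weighting.
#' @return Named numeric vector of class `free_parameters`.
#' @export
free_parameters <- function(alpha_2 = 0.44, K_U2 = 0, V_max_cb6f = 350,
                            V_max_rubc = 100, g_m = 0.084,
                            eps_ratio = 0) {
  structure(c(alpha_2 = alpha_2, K_U2 = K_U2, V_max_cb6f = V_max_cb6f,
              V_max_rubc = V_max_rubc, g_m = g_m, eps_ratio = eps_ratio),
            class = "free_parameters")
}

#' Default search bounds for the inversion
#'
#' @param alpha_total Total leaf absorbance (bounds on `alpha_2` are
#'   0.2–0.7 of it).
#' @return List with `lower` and `upper` named vectors.
#' @export
default_bounds <- function(alpha_total = 0.85) {
  list(lower = c(alpha_2 = 0.2 * alpha_total, K_U2 = 0, V_max_cb6f = 50,
                 V_max_rubc = 20, g_m = 0.01, eps_ratio = 0),
       upper = c(alpha_2 = 0.7 * alpha_total, K_U2 = 10, V_max_cb6f = 1000,
                 V_max_rubc = 300, g_m = 0.5, eps_ratio = 10))
}

# Forward-model a dataset at one candidate parameter vector. Returns modeled
# A for light rows and modeled fluorescence levels for all rows, aligned
# with the dataset rows, or NULL on solver failure.
model_dataset <- function(params, dataset, fixed) {
  p <- as.list(params)
  leaf <- try(leaf_parameters(
    alpha_total = fixed$alpha_total,
    alpha_1 = fixed$alpha_total - p$alpha_2,
    alpha_2 = p$alpha_2,
    V_max_cb6f = p$V_max_cb6f, V_max_rubc = p$V_max_rubc,
    R_d = fixed$R_d, g_m = p$g_m,
    state_transitions = TRUE, cef_mode = fixed$cef_mode
  ), silent = TRUE)
  if (inherits(leaf, "try-error")) return(NULL)
  k <- photo_constants(K_U2 = p$K_U2)
  det <- detector_model(eps_F1 = p$eps_ratio)

  light <- dataset$record_type == "light"
  C_i <- suppressWarnings(
    intercellular_co2(dataset$A[light], dataset$g_tc[light],
                      dataset$C_a[light], dataset$E_mmol[light]))
  C_c <- suppressWarnings(chloroplast_co2(C_i, dataset$A[light], p$g_m))
  if (any(!is.finite(C_c))) return(NULL)
  gs <- co2_compensation(rubisco_specificity(fixed$kin),
                         dataset$O_mbar[light])
  if (any(C_c <= gs)) return(NULL)

  st <- try(solve_steady_state(
    dataset$Q[light], leaf,
    leaf_env(C = C_c, O = dataset$O_mbar[light]),
    k, fixed$kin, fixed$coupling), silent = TRUE)
  if (inherits(st, "try-error")) return(NULL)

  # dark reference state at the mean chloroplast CO2 of the lit records
  st0 <- try(solve_steady_state(
    0, leaf, leaf_env(C = mean(C_c), O = mean(dataset$O_mbar[light])),
    k, fixed$kin, fixed$coupling), silent = TRUE)
  if (inherits(st0, "try-error")) return(NULL)
  dark_ref <- c(st0$alpha_1_eff, st0$alpha_2_eff)

  lv_light <- fluorescence_levels(st, k, det, alpha_dark = dark_ref)
  lv_dark <- fluorescence_levels(st0, k, det, alpha_dark = dark_ref)

  n <- nrow(dataset)
  out <- data.frame(A = rep(NA_real_, n), F_s = NA_real_,
                    F_max = NA_real_, F_min = NA_real_)
  out$A[light] <- st$A
  out$F_s[light] <- lv_light$F_s
  out$F_max[light] <- lv_light$F_m_prime
  out$F_min[light] <- lv_light$F_o_prime
  out$F_s[!light] <- lv_dark$F_s
  out$F_max[!light] <- lv_dark$F_m
  out$F_min[!light] <- lv_dark$F_o
  out
}

# sigma normalizers: a fraction of each observable's measured dynamic range
sigma_normalizers <- function(dataset, frac = 0.02) {
  light <- dataset$record_type == "light"
  rng <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(1)
    r <- max(v) - min(v)
    if (r <= 0) r <- max(abs(v))   # single-valued channel (e.g. dark Fm)
    if (r <= 0) r <- 1
    r
  }
  list(A = frac * rng(dataset$A[light]),
       F_s = frac * rng(dataset$F_s[light]),
       F_max_light = frac * rng(dataset$F_m_or_Fm_prime[light]),
       F_min_light = frac * rng(dataset$F_o_or_Fo_prime[light]),
       F_max_dark = frac * rng(dataset$F_m_or_Fm_prime[!light]),
       F_min_dark = frac * rng(dataset$F_o_or_Fo_prime[!light]))
}

#' Inversion objectives
#'
#' Two sum-of-squares misfits: `loss_gas` over net assimilation and
#' `loss_fluor` over the fluorescence channels (steady-state F_s, light
#' maxima/minima Fm'/Fo', dark Fm/Fo), each scaled by a sigma equal to 2%
#' of the observable's measured dynamic range. The arbitrary detector scale
#' is eliminated by a weighted least-squares factor fitted across all
#' fluorescence observations, so the objectives are invariant to rescaling
#' all measured fluorescence by a common constant. Solver failures return a
#' large finite penalty.
#'
#' @param params A [free_parameters()] vector (or any named numeric with
#'   the same elements).
#' @param dataset A `pam_dataset`.
#' @param fixed List of fixed constants: `alpha_total`, `R_d`, `kin`,
#'   `coupling`, `cef_mode`; see [fit_fixed_constants()].
#' @param sigmas Optional precomputed [sigma_normalizers()].
#' @return Numeric `c(loss_fluor, loss_gas)`.
#' @export
objectives <- function(params, dataset, fixed = fit_fixed_constants(),
                       sigmas = NULL) {
  if (is.null(sigmas)) sigmas <- sigma_normalizers(dataset)
  mod <- model_dataset(params, dataset, fixed)
  if (is.null(mod)) return(c(loss_fluor = 1e12, loss_gas = 1e12))
  light <- dataset$record_type == "light"

  obs_f <- c(dataset$F_s[light],
             dataset$F_m_or_Fm_prime[light],
             dataset$F_o_or_Fo_prime[light],
             dataset$F_m_or_Fm_prime[!light],
             dataset$F_o_or_Fo_prime[!light])
  mod_f <- c(mod$F_s[light], mod$F_max[light], mod$F_min[light],
             mod$F_max[!light], mod$F_min[!light])
  sig_f <- c(rep(sigmas$F_s, sum(light)),
             rep(sigmas$F_max_light, sum(light)),
             rep(sigmas$F_min_light, sum(light)),
             rep(sigmas$F_max_dark, sum(!light)),
             rep(sigmas$F_min_dark, sum(!light)))
  ok <- is.finite(obs_f) & is.finite(mod_f)
  obs_f <- obs_f[ok]; mod_f <- mod_f[ok]; sig_f <- sig_f[ok]
  denom <- sum(mod_f^2 / sig_f^2)
  scale <- if (denom > 0) sum(mod_f * obs_f / sig_f^2) / denom else 1
  loss_fluor <- sum(((scale * mod_f - obs_f) / sig_f)^2)

  loss_gas <- sum(((mod$A[light] - dataset$A[light]) / sigmas$A)^2)
  if (!is.finite(loss_fluor)) loss_fluor <- 1e12
  if (!is.finite(loss_gas)) loss_gas <- 1e12
  c(loss_fluor = loss_fluor, loss_gas = loss_gas)
}

#' Fixed constants for the inversion
#'
#' @param alpha_total Total leaf absorbance.
#' @param R_d Day respiration (umol m^-2 s^-1).
#' @param kin A [rubisco_kinetics()].
#' @param coupling Output of [coupling_efficiencies()].
#' @param cef_mode Photosynthetic-control mode passed to the solver.
#' @return List used as `fixed` by [objectives()] and [fit()].
#' @export
fit_fixed_constants <- function(alpha_total = 0.85, R_d = 1,
                                kin = rubisco_kinetics(),
                                coupling = coupling_efficiencies(),
                                cef_mode = "minimal") {
  list(alpha_total = alpha_total, R_d = R_d, kin = kin,
       coupling = coupling, cef_mode = cef_mode)
}

# ---- NSGA-II machinery (2 objectives) --------------------------------------

# Pareto ranks by iterative peeling of nondominated points.
pareto_ranks <- function(F) {
  n <- nrow(F)
  f1 <- F[, 1]; f2 <- F[, 2]
  dom <- outer(f1, f1, "<=") & outer(f2, f2, "<=") &
    (outer(f1, f1, "<") | outer(f2, f2, "<"))
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    cnt <- colSums(dom[remaining, remaining, drop = FALSE])
    front <- which(remaining)[cnt == 0]
    rank[front] <- r
    remaining[front] <- FALSE
  }
  rank
}

crowding_distance <- function(F, front_idx) {
  d <- rep(0, length(front_idx))
  for (m in 1:2) {
    o <- order(F[front_idx, m])
    fmin <- F[front_idx[o[1]], m]
    fmax <- F[front_idx[o[length(o)]], m]
    d[o[1]] <- Inf
    d[o[length(o)]] <- Inf
    if (length(o) > 2 && fmax > fmin) {
      d[o[2:(length(o) - 1)]] <- d[o[2:(length(o) - 1)]] +
        (F[front_idx[o[3:length(o)]], m] -
           F[front_idx[o[1:(length(o) - 2)]], m]) / (fmax - fmin)
    }
  }
  d
}

sbx_crossover <- function(p1, p2, eta_c, p_cross) {
  if (stats::runif(1) > p_cross) return(rbind(p1, p2))
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta_c + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
  cross <- stats::runif(length(p1)) < 0.5
  beta[!cross] <- 1
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  rbind(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

poly_mutation <- function(x, eta_m, p_mut) {
  mut <- stats::runif(length(x)) < p_mut
  if (any(mut)) {
    u <- stats::runif(sum(mut))
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta_m + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta_m + 1)))
    x[mut] <- pmin(pmax(x[mut] + delta, 0), 1)
  }
  x
}

#' Fit the model to a dataset with an elitist multiobjective GA
#'
#' NSGA-II over the six free parameters: Latin-hypercube initialization,
#' binary tournament on (rank, crowding), simulated binary crossover and
#' polynomial mutation, elitist environmental selection. Deterministic for
#' a fixed seed.
#'
#' @param dataset A `pam_dataset`.
#' @param bounds As from [default_bounds()].
#' @param ga_config List with `population`, `generations`, `seed`, and
#'   optionally `p_crossover`, `eta_c`, `eta_m`.
#' @param fixed Fixed constants, see [fit_fixed_constants()].
#' @return An object of class `pareto_front`: list with `params` (decoded
#'   nondominated solutions), `objectives`, and `summary` (per-parameter
#'   50th (25th, 75th) percentiles).
#' @export
fit <- function(dataset, bounds = default_bounds(),
                ga_config = list(population = 200, generations = 300,
                                 seed = 1L),
                fixed = fit_fixed_constants()) {
  pop_n <- ga_config$population
  gens <- ga_config$generations
  p_cross <- if (is.null(ga_config$p_crossover)) 0.9 else
    ga_config$p_crossover
  # wide SBX (small distribution index) markedly improves traversal of the
  # sloppy (V_max_rubc, g_m) valley of this problem
  eta_c <- if (is.null(ga_config$eta_c)) 2 else ga_config$eta_c
  eta_m <- if (is.null(ga_config$eta_m)) 20 else ga_config$eta_m
  lo <- bounds$lower
  hi <- bounds$upper
  if (any(hi < lo)) stop("invalid bounds")
  npar <- length(lo)
  p_mut <- 1 / npar
  sigmas <- sigma_normalizers(dataset)

  decode <- function(U) sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  evaluate <- function(U) {
    X <- decode(U)
    t(apply(X, 1, function(row) {
      names(row) <- names(lo)
      objectives(row, dataset, fixed, sigmas)
    }))
  }

  set.seed(ga_config$seed)
  P <- as.matrix(lhs::randomLHS(pop_n, npar))
  FP <- evaluate(P)
  rank <- pareto_ranks(FP)
  crowd <- rep(0, pop_n)
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(FP, idx)
  }

  for (gen in seq_len(gens)) {
    # binary tournaments
    pick <- function() {
      ij <- sample.int(pop_n, 2)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] >= crowd[j]) i else j
    }
    offspring <- matrix(0, pop_n, npar)
    m <- 1
    while (m <= pop_n) {
      ch <- sbx_crossover(P[pick(), ], P[pick(), ], eta_c, p_cross)
      ch[1, ] <- poly_mutation(ch[1, ], eta_m, p_mut)
      ch[2, ] <- poly_mutation(ch[2, ], eta_m, p_mut)
      offspring[m, ] <- ch[1, ]
      if (m + 1 <= pop_n) offspring[m + 1, ] <- ch[2, ]
      m <- m + 2
    }
    FO <- evaluate(offspring)
    R <- rbind(P, offspring)
    FR <- rbind(FP, FO)
    rr <- pareto_ranks(FR)
    sel <- integer(0)
    r <- 1L
    while (length(sel) < pop_n) {
      idx <- which(rr == r)
      if (length(sel) + length(idx) <= pop_n) {
        sel <- c(sel, idx)
      } else {
        cd <- crowding_distance(FR, idx)
        sel <- c(sel, idx[order(cd, decreasing = TRUE)][
          seq_len(pop_n - length(sel))])
      }
      r <- r + 1L
    }
    P <- R[sel, , drop = FALSE]
    FP <- FR[sel, , drop = FALSE]
    rank <- pareto_ranks(FP)
    crowd <- rep(0, pop_n)
    for (r2 in unique(rank)) {
      idx <- which(rank == r2)
      crowd[idx] <- crowding_distance(FP, idx)
    }
  }

  front_idx <- which(rank == 1)
  X <- decode(P[front_idx, , drop = FALSE])
  colnames(X) <- names(lo)
  Fb <- FP[front_idx, , drop = FALSE]
  colnames(Fb) <- c("loss_fluor", "loss_gas")
  qs <- apply(X, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  summary <- data.frame(parameter = names(lo), q25 = qs[1, ],
                        median = qs[2, ], q75 = qs[3, ],
                        row.names = NULL)
  structure(list(params = as.data.frame(X), objectives = as.data.frame(Fb),
                 summary = summary),
            class = "pareto_front")
}

#' Synthetic parameter-recovery test
#'
#' Generates a dataset from known truth via [generate_dataset()], runs
#' [fit()], and reports the maximum relative error of the Pareto-front
#' medians against the truth across the six free parameters.
#'
#' @param true_params A [free_parameters()] vector.
#' @param protocol A light protocol, see [sine_wave_protocol()].
#' @param noise_level Common CV applied to fluorescence and gas channels.
#' @param ga_config GA settings as in [fit()].
#' @param env_base Environment for the generator.
#' @param fixed Fixed constants for generator and fit.
#' @return List with `max_rel_error_pct`, the per-parameter relative
#'   errors (%), the `front`, and the generated `dataset`.
#' @export
recovery_test <- function(true_params = free_parameters(K_U2 = 2),
                          protocol = sine_wave_protocol(2400),
                          noise_level = 0,
                          ga_config = list(population = 200,
                                           generations = 300, seed = 1L),
                          env_base = leaf_env(),
                          fixed = fit_fixed_constants()) {
  p <- as.list(true_params)
  leaf <- leaf_parameters(alpha_total = fixed$alpha_total,
                          alpha_1 = fixed$alpha_total - p$alpha_2,
                          alpha_2 = p$alpha_2,
                          V_max_cb6f = p$V_max_cb6f,
                          V_max_rubc = p$V_max_rubc,
                          R_d = fixed$R_d, g_m = p$g_m,
                          state_transitions = TRUE,
                          cef_mode = fixed$cef_mode)
  ds <- generate_dataset(leaf, env_base, protocol,
                         noise = noise_model(noise_level, noise_level,
                                             seed = ga_config$seed),
                         detector = detector_model(eps_F1 = p$eps_ratio),
                         k = photo_constants(K_U2 = p$K_U2),
                         kin = fixed$kin, coupling = fixed$coupling)
  front <- fit(ds, ga_config = ga_config, fixed = fixed)
  truth <- unlist(p)[front$summary$parameter]
  denom <- ifelse(abs(truth) > 0, abs(truth), 1)
  rel <- 100 * abs(front$summary$median - truth) / denom
  names(rel) <- front$summary$parameter
  list(max_rel_error_pct = max(rel), rel_errors_pct = rel,
       front = front, dataset = ds)
}

#' Quality-of-fit report
#'
#' Type I (ordinary least squares) regressions of the median-model
#' predictions on the measurements, per observable, with R^2, RMSE,
#' intercept and slope. An optional logical mask excludes outlier records
#' from the statistics.
#'
#' @param front A `pareto_front` from [fit()].
#' @param dataset The fitted `pam_dataset`.
#' @param fixed Fixed constants used in the fit.
#' @param mask Optional logical vector over dataset rows; `FALSE` rows are
#'   excluded.
#' @return `data.frame` with one row per observable: `R2`, `RMSE`,
#'   `beta0`, `beta1`.
#' @export
fit_report <- function(front, dataset, fixed = fit_fixed_constants(),
                       mask = NULL) {
  med <- front$summary$median
  names(med) <- front$summary$parameter
  mod <- model_dataset(med, dataset, fixed)
  if (is.null(mod)) stop("median parameters fail to forward-model")
  if (is.null(mask)) mask <- rep(TRUE, nrow(dataset))
  light <- dataset$record_type == "light"

  # match the arbitrary detector scale before regressing
  obs_f <- c(dataset$F_s[light], dataset$F_m_or_Fm_prime[light],
             dataset$F_o_or_Fo_prime[light])
  mod_f <- c(mod$F_s[light], mod$F_max[light], mod$F_min[light])
  scale <- sum(mod_f * obs_f) / sum(mod_f^2)

  one <- function(name, obs, pred, use) {
    use <- use & is.finite(obs) & is.finite(pred)
    obs <- obs[use]; pred <- pred[use]
    if (length(obs) < 3 || stats::var(obs) == 0)
      return(data.frame(observable = name, R2 = NA_real_, RMSE = NA_real_,
                        beta0 = NA_real_, beta1 = NA_real_))
    co <- stats::coef(stats::lm(pred ~ obs))
    ss_res <- sum((pred - obs)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    data.frame(observable = name, R2 = 1 - ss_res / ss_tot,
               RMSE = sqrt(mean((pred - obs)^2)),
               beta0 = unname(co[1]), beta1 = unname(co[2]))
  }
  rbind(
    one("A", dataset$A[light], mod$A[light], mask[light]),
    one("F_s", dataset$F_s[light], scale * mod$F_s[light], mask[light]),
    one("F_m_prime", dataset$F_m_or_Fm_prime[light],
        scale * mod$F_max[light], mask[light]),
    one("F_o_prime", dataset$F_o_or_Fo_prime[light],
        scale * mod$F_min[light], mask[light])
  )
}
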