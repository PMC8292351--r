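# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: yields by explicit geometric-series summation,
# steady states by nested grid refinement on the kinetic balance equations.

# Reference conditions used repeatedly (chloroplast CO2 200 ubar, O2
# 209 mbar, Rubisco constants at 25 C).
ref <- local({
  S <- (3.6 * 179000) / (260 * 0.9)        # 2753.846...
  gs <- 0.5 * 209000 / S                   # 37.9469... ubar
  x <- gs / 200
  list(S = S, gamma_star = gs, x = x,
       eta = 1 - 0.75 + (3 + 7 * x) / (4 + 8 * x))
})

# PS II overall yields by truncated geometric-series summation over exciton
# transfers (independent of the closed-form 1/(1 - phi_U2) route).
psii_yields_series <- function(f2, k, K_N2 = 0, n_terms = 400) {
  s0 <- k$K_P2 + K_N2 + k$K_D2 + k$K_F2 + k$K_U2
  sm <- K_N2 + k$K_D2 + k$K_F2 + k$K_U2
  phi <- function(K_open, K_closed) {
    (1 - f2) * K_open / s0 + f2 * K_closed / sm
  }
  phi_U2 <- phi(k$K_U2, k$K_U2)
  mult <- sum(phi_U2^(0:n_terms))
  list(Phi_P2 = (1 - f2) * k$K_P2 / s0 * mult,
       Phi_N2 = phi(K_N2, K_N2) * mult,
       Phi_D2 = phi(k$K_D2, k$K_D2) * mult,
       Phi_F2 = phi(k$K_F2, k$K_F2) * mult)
}

# b6f-limited steady state by brute-force grid refinement over the shared
# closure f and the NPQ constant K_N2, minimizing the squared relative
# residuals of the two kinetic balance equations:
#   (1) PS I light capture equals b6f throughput:
#         Q alpha_1 (1 - f) K_P1/SumK0 = f V_max
#   (2) PS II supply matches its share of b6f throughput:
#         Q alpha_2 Phi_P2(f, K_N2) = f V_max / eta
grid_oracle_b6f_state <- function(Q, alpha_1, alpha_2, V_max, eta, k,
                                  levels = 16, width_f = c(0, 1),
                                  width_N = c(0, 60)) {
  kp1n <- k$K_P1 / (k$K_P1 + k$K_D1 + k$K_F1)
  resid <- function(f, N) {
    supply1 <- Q * alpha_1 * (1 - f) * kp1n
    drain1 <- f * V_max
    supply2 <- Q * alpha_2 * psii_yields(f, k, N)$Phi_P2
    drain2 <- f * V_max / eta
    ((supply1 - drain1) / pmax(drain1, 1e-8))^2 +
      ((supply2 - drain2) / pmax(drain2, 1e-8))^2
  }
  fr <- width_f
  Nr <- width_N
  for (lev in seq_len(levels)) {
    fg <- seq(fr[1], fr[2], length.out = 41)
    Ng <- seq(Nr[1], Nr[2], length.out = 41)
    gr <- expand.grid(f = fg, N = Ng)
    r <- resid(gr$f, gr$N)
    best <- gr[which.min(r), ]
    # keep a generous window (+/- 4 grid steps) so the refinement cannot
    # cut off the minimum of the correlated (f, K_N2) valley
    df <- 4 * diff(fr) / 40
    dN <- 4 * diff(Nr) / 40
    fr <- c(max(best$f - df, 0), min(best$f + df, 1))
    Nr <- c(max(best$N - dN, 0), best$N + dN)
  }
  list(f = best$f, K_N2 = best$N)
}

# random leaf/environment draws for property tests
random_case <- function() {
  alpha_total <- stats::runif(1, 0.6, 0.9)
  a1 <- alpha_total * stats::runif(1, 0.4, 0.6)
  list(leaf = leaf_parameters(alpha_total = alpha_total, alpha_1 = a1,
                              alpha_2 = alpha_total - a1,
                              V_max_cb6f = stats::runif(1, 150, 600),
                              V_max_rubc = stats::runif(1, 50, 150)),
       env = leaf_env(C = stats::runif(1, 150, 400),
                      O = stats::runif(1, 150, 250)),
       k = photo_constants(K_U2 = sample(c(0, stats::runif(1, 0.5, 5)), 1)))
}
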