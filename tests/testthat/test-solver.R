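# Minimum-rule solver: limiting rates, regulatory back-solves, saturation.

tbl_leaf <- function(...) leaf_parameters(...)

test_that("potential rates match the worked chains", {
  r <- aj(2400, tbl_leaf(), leaf_env())
  expect_equal(r$J_prime_P700, 255.398, tolerance = 1e-4)
  expect_equal(r$J_prime_P680, 246.908, tolerance = 1e-4)
  expect_equal(r$A_j, 35.26, tolerance = 1e-3)
  expect_equal(aj(0, tbl_leaf(), leaf_env())$A_j, -1)
  # hyperbola asymptote
  A_inf <- (350 / ref$eta) * (1 - ref$x) / (4 + 8 * ref$x) - 1
  expect_equal(aj(1e9, tbl_leaf(), leaf_env())$A_j, A_inf,
               tolerance = 1e-4)

  rc <- ac(tbl_leaf(), leaf_env())
  expect_equal(rc$V_c, 26.1926, tolerance = 1e-4)
  expect_equal(rc$A_c, 20.2229, tolerance = 1e-4)
  expect_equal(ac(tbl_leaf(), leaf_env(C = 1e9))$A_c, 99,
               tolerance = 1e-3)
  gs <- ref$gamma_star
  expect_equal(ac(tbl_leaf(), leaf_env(C = gs))$A_c, -1, tolerance = 1e-9)
})

test_that("NPQ back-solve agrees with its closed form and flags infeasibility", {
  k <- photo_constants()
  # no quenching needed when the target equals the unquenched supply
  f2 <- 0.3
  s0 <- psii_flux(f2, 800, 0.44, k, 0)
  expect_equal(solve_npq(s0, 800, 0.44, f2, k)$K_N2, 0, tolerance = 1e-9)

  # closed form when K_U2 = 0
  target <- 144.527
  r <- solve_npq(target, 2400, 0.44, 0.729709, k)
  closed <- 2400 * 0.44 * (1 - 0.729709) * 4.5 / target - 5.1
  expect_equal(r$K_N2, closed, tolerance = 1e-7)
  expect_equal(r$K_N2, 3.787, tolerance = 1e-3)
  expect_false(r$psii_limited)

  # root reproduces the target flux also with exciton sharing
  set.seed(23)
  for (i in 1:20) {
    kk <- photo_constants(K_U2 = stats::runif(1, 0, 6))
    f <- stats::runif(1, 0.05, 0.9)
    Q <- stats::runif(1, 100, 2400)
    tgt <- stats::runif(1, 0.2, 0.95) * psii_flux(f, Q, 0.44, kk, 0)
    rr <- solve_npq(tgt, Q, 0.44, f, kk)
    expect_equal(psii_flux(f, Q, 0.44, kk, rr$K_N2), tgt,
                 tolerance = 1e-8)
  }

  inf <- solve_npq(2 * s0, 800, 0.44, f2, k)
  expect_true(inf$psii_limited)
  expect_equal(inf$K_N2, 0)
})

test_that("cross-section split balances the photosystems", {
  k0 <- photo_constants()
  sp <- solve_cross_sections(ref$eta, 0, k0, 0.85)
  expect_equal(sp$alpha_2, 0.4358, tolerance = 1e-4)
  expect_equal(sp$alpha_1, 0.4142, tolerance = 1e-4)
  # without sharing the split is closure-independent
  sp2 <- solve_cross_sections(ref$eta, 0.6, k0, 0.85)
  expect_equal(sp$alpha_2, sp2$alpha_2, tolerance = 1e-12)

  # connected antenna shifts pigment to PS I as closure builds
  k2 <- photo_constants(K_U2 = 2)
  f_sat <- light_saturation_point(tbl_leaf(state_transitions = TRUE),
                                  leaf_env(), k2)$f_sat
  expect_equal(f_sat, 0.4271, tolerance = 1e-4)
  dark <- solve_cross_sections(ref$eta, 0, k2, 0.85)$alpha_2
  sat <- solve_cross_sections(ref$eta, f_sat, k2, 0.85)$alpha_2
  expect_equal(sat, 0.3635, tolerance = 1e-3)
  expect_equal(100 * (1 - sat / dark), 16.6, tolerance = 1e-2)
  lake <- solve_cross_sections(
    ref$eta, f_sat, photo_constants(K_U2 = Inf), 0.85)
  expect_equal(100 * (1 - lake$alpha_2 / dark), 22.8, tolerance = 0.1)
})

test_that("light-saturation point and continuity of the minimum rule", {
  lsp <- light_saturation_point(tbl_leaf(), leaf_env())
  expect_equal(lsp$Q_sat, 662.834, tolerance = 1e-3)
  expect_false(lsp$never_saturates)
  lsp2 <- light_saturation_point(tbl_leaf(V_max_rubc = 1e6, R_d = 1),
                                 leaf_env())
  expect_true(lsp2$never_saturates)
  expect_equal(lsp2$Q_sat, Inf)

  eps <- 1e-6
  st <- solve_steady_state(lsp$Q_sat + c(-eps, 0, eps), tbl_leaf(),
                           leaf_env())
  expect_lt(abs(st$A[3] - st$A[1]), 1e-6)
  # the tie itself is classified b6f-limited, keeping k* left-continuous
  expect_equal(st$regime[2], "b6f_limited")
  expect_equal(st$k_star_over_kq[2], 1)
})

test_that("steady state reproduces the frozen worked chains", {
  st <- solve_steady_state(c(0, 300, 2400), tbl_leaf(), leaf_env())
  # dark
  expect_equal(st$A[1], -1)
  expect_equal(st$f2[1], 0)
  expect_equal(st$K_N2[1], 0)
  # limiting light
  expect_equal(st$regime[2], "b6f_limited")
  expect_equal(st$k_star_over_kq[2], 1)
  expect_equal(st$f2[2], 0.252317, tolerance = 1e-5)
  expect_equal(st$f1[2], st$f2[2], tolerance = 1e-12)
  expect_equal(st$fb[2], st$f2[2], tolerance = 1e-12)
  # saturating light
  expect_equal(st$regime[3], "rubisco_limited")
  expect_equal(st$J_P680[3], 144.527, tolerance = 1e-3)
  expect_equal(st$J_P700[3], 149.497, tolerance = 1e-3)
  expect_equal(st$f2[3], 0.729709, tolerance = 1e-5)
  expect_equal(st$k_star_over_kq[3], 0.58535, tolerance = 1e-4)
  expect_equal(st$K_N2[3], 3.78706, tolerance = 1e-4)
})

test_that("minimum rule, photosynthetic control bounds and the flux bracket hold on a grid", {
  Q <- seq(0, 2400, by = 50)
  for (mode in c("minimal", "regulatory")) {
    st <- solve_steady_state(Q, tbl_leaf(cef_mode = mode), leaf_env())
    expect_equal(st$A, pmin(st$A_j, st$A_c), tolerance = 1e-12)
    expect_true(all(diff(st$A) > -1e-9))
    expect_true(all(st$k_star_over_kq > 0 & st$k_star_over_kq <= 1))
    below <- st$Q < st$Q_sat
    expect_true(all(st$k_star_over_kq[below] == 1))
    if (mode == "minimal") {
      above <- st$k_star_over_kq[!below]
      expect_true(all(diff(above) < 0))
    } else {
      expect_true(all(st$k_star_over_kq == 1))
    }
    # eta J_P680 <= J_CB6F <= J'_CB6F
    Jp <- potential_psi_rate(Q, 0.41, photo_constants(), 350)
    expect_true(all(st$J_P680 * st$eta <= st$J_CB6F + 1e-9))
    expect_true(all(st$J_CB6F <= Jp + 1e-9))
  }
})

test_that("ATP/NADPH/Fd budgets close at every solved state", {
  set.seed(31)
  Q <- seq(0, 2400, by = 100)
  for (i in 1:5) {
    cs <- random_case()
    st <- solve_steady_state(Q, cs$leaf, cs$env, cs$k)
    d <- demand_fluxes(st$V_c, st$V_o)
    s <- supply_fluxes(st$J_P680, st$J_P700, coupling_efficiencies())
    rel <- abs(s$J_ATP_supply - d$J_ATP) / pmax(d$J_ATP, 1e-8)
    expect_true(all(rel[st$Q > 0] < 1e-10))
    expect_equal(st$J_P680, d$J_Fd + 2 * d$J_NADPH, tolerance = 1e-8)
  }
})

test_that("joint V_max scaling leaves the transition poise invariant", {
  f_sats <- vapply(c(0.5, 1, 2, 4), function(s) {
    light_saturation_point(
      tbl_leaf(V_max_cb6f = 350 * s, V_max_rubc = 100 * s,
               R_d = 0.01 * 100 * s),
      leaf_env())$f_sat
  }, 0)
  expect_true(max(abs(f_sats - f_sats[1])) < 1e-8)
})

test_that("PS II-limited corner engages at high CO2 and satisfies its balance", {
  st <- solve_steady_state(100, tbl_leaf(V_max_rubc = 1e6, R_d = 1),
                           leaf_env(C = 5000))
  expect_true(st$psii_limited)
  expect_equal(st$K_N2, 0)
  expect_equal(st$f2, st$fb, tolerance = 1e-12)
  expect_equal(psii_flux(st$f2, 100, 0.44, photo_constants(), 0),
               st$f2 * 350 / st$eta, tolerance = 1e-8)
  # assimilation reflects the reduced PS II flux
  expect_equal(st$A_g, st$J_P680 * (1 - st$gamma_star / 5000) /
                 (4 + 8 * st$gamma_star / 5000), tolerance = 1e-10)
})

test_that("state transitions: exact balance below saturation, frozen split above", {
  k2 <- photo_constants(K_U2 = 2)
  leaf <- tbl_leaf(state_transitions = TRUE)
  st <- solve_steady_state(c(0, 150, 400, 1200, 2400), leaf, leaf_env(),
                           k2)
  # dark state keeps the leaf's own pigment split
  expect_equal(st$alpha_2_eff[1], 0.44)
  below <- st$Q > 0 & st$Q < st$Q_sat
  expect_true(all(st$K_N2[below] == 0))
  # the split balances PS II supply exactly (no NPQ needed)
  expect_equal(psii_flux(st$f2[below], st$Q[below],
                         st$alpha_2_eff[below], k2, 0),
               st$J_P680[below], tolerance = 1e-8)
  above <- st$Q >= st$Q_sat
  expect_true(all(abs(st$alpha_2_eff[above] - st$alpha_2_eff[above][1])
                  < 1e-12))
  expect_true(all(st$K_N2[above] > 0))
  expect_equal(st$alpha_1_eff + st$alpha_2_eff, rep(0.85, 5),
               tolerance = 1e-12)
})
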