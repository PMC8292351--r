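# Forward operator to detector space and the PAM indices derived from it.

test_that("extreme levels follow the rate-constant sums", {
  k <- photo_constants()
  st <- solve_steady_state(c(0, 800), leaf_parameters(), leaf_env())
  det <- detector_model(eps_F1 = 0)
  lv <- fluorescence_levels(st, k, det)
  # dark-adapted maximum: alpha_2 K_F2/(K_D2 + K_F2)
  expect_equal(lv$F_m[1], 0.44 * 0.05 / 0.6, tolerance = 1e-12)
  expect_equal(lv$F_o[1], 0.44 * 0.05 / 5.1, tolerance = 1e-12)
  # light-adapted maximum is quenched by K_N2
  expect_equal(lv$F_m_prime[2],
               0.44 * 0.05 / (st$K_N2[2] + 0.6), tolerance = 1e-12)
  # PS I contribution enters Fo more strongly than Fm
  det2 <- detector_model(eps_F1 = 2)
  lv2 <- fluorescence_levels(st, k, det2)
  psi_share_fo <- (lv2$F_o[1] - lv$F_o[1]) / lv2$F_o[1]
  psi_share_fm <- (lv2$F_m[1] - lv$F_m[1]) / lv2$F_m[1]
  expect_gt(psi_share_fo, psi_share_fm)
  expect_equal(psi_share_fo,
               (0.41 * (0.05 / 15.1) * 2) / lv2$F_o[1], tolerance = 1e-12)
})

test_that("Genty identity and openness indices are exact without PS I light and sharing", {
  k <- photo_constants()
  det <- detector_model(eps_F1 = 0)
  set.seed(41)
  for (i in 1:20) {
    cs <- random_case()
    kk <- photo_constants(K_U2 = 0)
    st <- solve_steady_state(stats::runif(1, 50, 2400), cs$leaf, cs$env,
                             kk)
    lv <- fluorescence_levels(st, kk, det)
    expect_equal(1 - lv$F_s / lv$F_m_prime, st$Phi_P2, tolerance = 1e-12)
    pm <- pam_indices(lv, st$Q)
    expect_equal(pm$qP, 1 - st$f2, tolerance = 1e-12)
    expect_lte(pm$qL, pm$qP + 1e-12)
  }
  # PS I contamination biases the apparent yield downward
  st <- solve_steady_state(800, leaf_parameters(), leaf_env())
  lv1 <- fluorescence_levels(st, k, detector_model(eps_F1 = 1.5))
  expect_lt(1 - lv1$F_s / lv1$F_m_prime, st$Phi_P2)
})

test_that("PAM indices match the caption arithmetic and partition to one", {
  lv <- data.frame(F_s = 800, F_m = 3905, F_m_prime = 1600, F_o = 600,
                   F_o_prime = 600)
  pm <- pam_indices(lv, Q = 1000)
  expect_equal(pm$Phi_P2_app, 0.5)
  expect_equal(pm$NPQ, 3905 / 1600 - 1, tolerance = 1e-12)
  expect_equal(pm$NPQ, 1.4406, tolerance = 1e-4)
  expect_equal(pm$qP, 0.8)
  expect_equal(pm$qL, 0.6)
  expect_equal(pm$LEF_app, 212.5)
  expect_equal(pm$k_Lake, 531.25)
  expect_equal(pm$k_Puddle, 1062.5)
  expect_equal(pm$Phi_P2_app + pm$Phi_N2_app + pm$Phi_DF2_app, 1,
               tolerance = 1e-12)
  # degenerate levels flag rather than throw
  lv2 <- data.frame(F_s = 800, F_m = 800, F_m_prime = 800, F_o = 800,
                    F_o_prime = 800)
  pm2 <- pam_indices(lv2, 1000)
  expect_equal(pm2$NPQ, 0)
  expect_true(is.na(pm2$qP))
})

test_that("all indices are invariant to the detector scale", {
  st <- solve_steady_state(c(400, 1500), leaf_parameters(), leaf_env())
  k <- photo_constants()
  for (c_scale in c(0.1, 7)) {
    a <- pam_indices(fluorescence_levels(st, k,
                                         detector_model(S_det = 1,
                                                        eps_F1 = 1)),
                     st$Q)
    b <- pam_indices(fluorescence_levels(st, k,
                                         detector_model(S_det = c_scale,
                                                        eps_F1 = 1)),
                     st$Q)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("level ordering holds for solver-produced states", {
  Q <- seq(0, 2400, by = 200)
  for (u in c(0, 2)) {
    kk <- photo_constants(K_U2 = u)
    st <- solve_steady_state(Q, leaf_parameters(), leaf_env(), kk)
    lv <- fluorescence_levels(st, kk, detector_model(eps_F1 = 1))
    expect_true(all(lv$F_o_prime <= lv$F_s + 1e-12))
    expect_true(all(lv$F_s <= lv$F_m_prime + 1e-12))
    expect_true(all(lv$F_m_prime <= lv$F_m + 1e-12))
  }
})

test_that("the lake openness index reads the PQ pool poise exactly for a lake leaf", {
  kk <- photo_constants(K_U2 = Inf)
  st <- solve_steady_state(seq(100, 2400, by = 300), leaf_parameters(),
                           leaf_env(), kk)
  lv <- fluorescence_levels(st, kk, detector_model(eps_F1 = 0))
  pm <- pam_indices(lv, st$Q)
  expect_equal(1 - pm$qL, st$fb, tolerance = 1e-10)
})

test_that("kLake diagnostic recovers V_max under its own assumptions", {
  # one-point extrapolation
  single <- data.frame(qP = 0.7, qL = 0.6, LEF_app = 100,
                       k_Lake = 100 / 0.4, k_Puddle = 100 / 0.3)
  expect_equal(estimate_vmax_b6f(single, TRUE), 250)
  expect_error(estimate_vmax_b6f(single, FALSE), "mask")

  # lake-connected leaf, photorespiration suppressed: CEF1 ~ 0 and
  # 1 - qL reads the PQH2 occupancy, so the extrapolation hits V_max
  kk <- photo_constants(K_U2 = Inf)
  leaf <- leaf_parameters(V_max_rubc = 1e6, R_d = 1)
  env <- leaf_env(C = 5000)
  st <- solve_steady_state(seq(50, 600, by = 50), leaf, env, kk)
  lv <- fluorescence_levels(st, kk, detector_model(eps_F1 = 0))
  pm <- pam_indices(lv, st$Q, alpha_2_assumed = st$alpha_2_eff)
  est <- estimate_vmax_b6f(pm, st$regime == "b6f_limited")
  expect_lt(abs(est - 350) / 350, 0.02)

  # photosynthetic control pulls records at saturating light below V_max
  leaf2 <- leaf_parameters(V_max_rubc = 60)
  st2 <- solve_steady_state(c(300, 500, 1200, 2400), leaf2,
                            leaf_env(C = 5000), kk)
  lv2 <- fluorescence_levels(st2, kk, detector_model(eps_F1 = 0))
  pm2 <- pam_indices(lv2, st2$Q, alpha_2_assumed = st2$alpha_2_eff)
  sat <- st2$regime == "rubisco_limited"
  expect_true(any(sat))
  expect_lt(estimate_vmax_b6f(pm2, rep(TRUE, nrow(pm2))),
            estimate_vmax_b6f(pm2, !sat))
  expect_true(all(pm2$k_Lake[sat] < 350))
})
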