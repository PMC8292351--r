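# Energy/mass budgets linking electron transport to carbon metabolism.

test_that("Rubisco specificity and CO2 compensation point follow the kinetic constants", {
  kin <- rubisco_kinetics()
  S <- rubisco_specificity(kin)
  expect_equal(S, (3.6 * 179000) / (260 * 0.9), tolerance = 1e-12)
  expect_equal(S, 2753.846, tolerance = 1e-6)

  # symmetric kinetics give S = 1 once units are common
  expect_equal(rubisco_specificity(
    rubisco_kinetics(k_c = 1, K_c = 1000, k_o = 1, K_o = 1)), 1)
  # linear in k_c
  S2 <- rubisco_specificity(rubisco_kinetics(k_c = 7.2))
  expect_equal(S2 / S, 2)
  expect_error(rubisco_specificity(
    rubisco_kinetics(k_c = -1)), "positive")

  expect_equal(co2_compensation(S, 209), 104500 / S, tolerance = 1e-12)
  expect_equal(co2_compensation(S, 209), 37.9469, tolerance = 1e-5)
  expect_equal(co2_compensation(S, 0), 0)
  expect_lt(co2_compensation(1e9, 209), 1e-3)
})

test_that("proton bookkeeping reproduces the tabulated coupling efficiencies", {
  n_ref <- coupling_efficiencies(coupling_scenario(TRUE, TRUE, 4))
  expect_equal(n_ref$n_L, 0.75)
  expect_equal(n_ref$n_C, 1.00)

  expect_equal(coupling_efficiencies(
    coupling_scenario(TRUE, FALSE, 4))$n_C, 0.5)
  n_struct <- coupling_efficiencies(coupling_scenario(TRUE, TRUE, 14 / 3))
  expect_equal(n_struct$n_L, 9 / 14)
  expect_equal(n_struct$n_C, 12 / 14)
  n_noq <- coupling_efficiencies(coupling_scenario(FALSE, TRUE, 4))
  expect_equal(n_noq$n_L, 0.5)
  expect_equal(n_noq$n_C, 0.75)
  n_all <- coupling_efficiencies(coupling_scenario(FALSE, FALSE, 14 / 3))
  expect_equal(n_all$n_L, 3 / 7)
  expect_equal(n_all$n_C, 3 / 14)
  expect_error(coupling_scenario(h_per_atp = 5), "14/3")
})

test_that("eta balances the three budgets and degenerates correctly", {
  # no photorespiration and reference coupling: no cyclic flow at all
  expect_equal(eta_ratio(0.75, 1, 0, 200), 1.0)
  e <- eta_ratio(0.75, 1, ref$gamma_star, 200)
  expect_equal(e, ref$eta, tolerance = 1e-12)
  expect_equal(e, 1.034385, tolerance = 1e-6)
  expect_equal(100 * cef1_fraction(e), 3.324, tolerance = 1e-3)

  # structural ATP synthase raises the cyclic share to ~14%
  e_s <- eta_ratio(9 / 14, 12 / 14, ref$gamma_star, 200)
  expect_equal(round(100 * cef1_fraction(e_s)), 14)

  # cyclic fraction increases monotonically with photorespiratory pressure
  xs <- seq(0, 0.5, by = 0.05)
  fr <- cef1_fraction(eta_ratio(0.75, 1, xs * 200, 200))
  expect_true(all(diff(fr) > 0))
  expect_error(eta_ratio(0.75, 0, 10, 200), "n_C")
})

test_that("electron requirements follow the gas-exchange linkage", {
  r <- electron_requirements(10, 1, 200, ref$gamma_star, ref$eta)
  expect_equal(r$J_P680, 11 * (4 + 8 * ref$x) / (1 - ref$x),
               tolerance = 1e-12)
  expect_equal(r$J_P680, 74.910, tolerance = 1e-4)
  expect_equal(r$J_P700, 77.485, tolerance = 1e-4)
  # no photorespiration: 4 electrons per net CO2
  expect_equal(electron_requirements(10, 1, 200, 0, 1)$J_P680, 44)
  expect_equal(electron_requirements(-1, 1, 200, ref$gamma_star,
                                     ref$eta)$J_P680, 0)
  expect_error(electron_requirements(10, 1, 30, ref$gamma_star, ref$eta),
               "compensation")
})

test_that("demand stoichiometry matches the PCR and PCO cycle coefficients", {
  d <- demand_fluxes(3, 0)
  expect_equal(c(d$J_NADPH, d$J_Fd, d$J_ATP), c(6, 0, 9))
  d2 <- demand_fluxes(0, 6)
  expect_equal(c(d2$J_NADPH, d2$J_Fd, d2$J_ATP), c(9, 6, 21))
  d0 <- demand_fluxes(0, 0)
  expect_equal(c(d0$J_NADPH, d0$J_Fd, d0$J_ATP), c(0, 0, 0))
  expect_error(demand_fluxes(-1, 0), "non-negative")
})

test_that("supply equals demand when the budgets close", {
  n <- coupling_efficiencies()
  s <- supply_fluxes(100, 100, n)
  expect_equal(s$J_ATP_supply, 75)
  expect_equal(supply_fluxes(100, 103.44, n)$J_ATP_supply, 78.44)
  expect_error(supply_fluxes(100, 90, n), "negative cyclic")

  set.seed(42)
  for (i in 1:200) {
    V_c <- stats::runif(1, 0, 60)
    V_o <- stats::runif(1, 0, 30)
    sc <- coupling_scenario(sample(c(TRUE, FALSE), 1),
                            sample(c(TRUE, FALSE), 1),
                            sample(c(4, 14 / 3), 1))
    nn <- coupling_efficiencies(sc)
    d <- demand_fluxes(V_c, V_o)
    J_P680 <- 4 * V_c + 4 * V_o
    J_P700 <- (d$J_ATP - J_P680 * nn$n_L) / nn$n_C + J_P680
    if (J_P700 < J_P680) next   # scenario cannot run without extra ATP sinks
    s <- supply_fluxes(J_P680, J_P700, nn)
    expect_equal(s$J_ATP_supply, d$J_ATP, tolerance = 1e-12)
    expect_equal(s$reductant_e, d$J_Fd + 2 * d$J_NADPH, tolerance = 1e-12)
    # 1:1 CO2:O2 exchange: gross O2 evolution minus PCO uptake equals A_g
    expect_equal(J_P680 / 4 - 1.5 * V_o, assimilation(V_c, V_o)$A_g,
                 tolerance = 1e-12)
  }
})

test_that("assimilation combines carboxylation, photorespiration and respiration", {
  expect_equal(assimilation(10, 0, 0)$A, 10)
  a <- assimilation(26.193, 26.193 * 2 * ref$x, 1)
  expect_equal(a$A_g, 26.193 * (1 - ref$x), tolerance = 1e-12)
  expect_equal(a$A, 20.22, tolerance = 1e-3)
  # Vo from the specificity relation reproduces the same gross rate
  vo <- 26.193 * vo_vc_ratio(ref$S, 200, 209)
  expect_equal(assimilation(26.193, vo)$A_g, 26.193 * (1 - ref$x),
               tolerance = 1e-12)
})
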