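test_that("dose amount conversion gives ~3900 pmol for the study dose", {
  expect_equal(signif(dose_amount_pmol(dose_event(0.1, 28)), 3), 3900)
  expect_equal(dose_amount_pmol(dose_event(0, 28)), 0)
  expect_error(dose_event(-1, 28), "dose_per_bw")
})

test_that("a zero dose yields identically zero trajectories", {
  sim <- simulate_pbpk(dose_event(0, 28), system = fx_system(),
                       times = c(1, 24))
  expect_true(all(sim$states == 0))
  expect_true(all(sim$obs_nM == 0))
})

test_that("mass is conserved over 168 h", {
  dose_pmol <- dose_amount_pmol(dose_event(0.1, 28))
  # closed system: CL_int = 0
  sys0 <- build_pbpk_system(fx_phys(), drug_params(CL_int = 0), fx_tum())
  sim0 <- simulate_pbpk(dose_event(0.1, 28), system = sys0)
  amt0 <- total_amount(sim0, include_eliminated = FALSE)
  expect_lt(max(abs(amt0 - dose_pmol)) / dose_pmol, 0.001)
  expect_equal(max(sim0$eliminated_pmol), 0)

  # eliminating system: remaining + eliminated = dose
  sim <- fx_sim()
  amt <- total_amount(sim)
  expect_lt(max(abs(amt - dose_pmol)) / dose_pmol, 0.001)
  expect_gt(max(sim$eliminated_pmol), 0.9 * dose_pmol)  # mostly cleared
})

test_that("observable mapping matches the mixture formulas", {
  sys <- fx_system()
  # all sub-compartments at the same concentration read back unchanged
  y <- setNames(rep(7.5, 81), mmaepbpk:::.state_names)
  for (m in c("lung", "muscle", "spleen"))
    expect_equal(observable_concentration(y, sys, m), 7.5,
                 tolerance = 1e-12)
  # whole blood is the hematocrit-weighted plasma/BC mixture
  y2 <- numeric(81); y2[1] <- 10; y2[2] <- 54.6
  expect_equal(observable_concentration(y2, sys, "blood"),
               0.55 * 10 + 0.45 * 54.6, tolerance = 1e-12)
  # empty tumor reads zero
  y3 <- setNames(rep(1, 81), mmaepbpk:::.state_names)
  y3[c(78, 79, 80)] <- 0
  expect_equal(observable_concentration(y3, sys, "tumor"), 0)
  # aliases and validation
  expect_equal(observable_concentration(y, sys, "fat"),
               observable_concentration(y, sys, "adipose"))
  expect_error(observable_concentration(y, sys, "gizzard"), "unknown matrix")
})

test_that("unit conversion is consistent with the published plasma AUC", {
  # 54.3 ng*h/mL converts to 75.6 h*nM, within 0.4% of the printed 75.4
  expect_equal(convert_units(54.3, "ng_per_mL_to_nM"), 75.6,
               tolerance = 5e-4)
  expect_lt(abs(convert_units(54.3, "ng_per_mL_to_nM") - 75.4) / 75.4,
            0.004)
  # round trip and zero
  x <- c(0, 0.2, 54.3, 1e4)
  expect_equal(convert_units(convert_units(x, "ng_per_mL_to_nM"),
                             "nM_to_ng_per_mL"), x, tolerance = 1e-12)
  expect_error(convert_units(1, MW = 0), "MW")
})

test_that("reported observables are grid-independent", {
  s1 <- simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                      rtol = 1e-8, atol = 1e-10)
  s2 <- simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                      rtol = 5e-9, atol = 5e-11)
  keep <- s1$obs_nM > 1e-8
  expect_lt(max(abs(s2$obs_nM[keep] - s1$obs_nM[keep]) / s1$obs_nM[keep]),
            1e-4)
})

test_that("compiled and pure-R integration paths agree", {
  tt <- c(0.5, 6, 72)
  sc <- simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                      times = tt, compiled = TRUE)
  sr <- simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                      times = tt, compiled = FALSE)
  keep <- sc$obs_nM > 1e-8
  expect_lt(max(abs(sr$obs_nM[keep] - sc$obs_nM[keep]) / sc$obs_nM[keep]),
            1e-5)
})

test_that("out-of-horizon output times are rejected", {
  expect_error(simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                             times = c(1, 500)), "200")
})
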