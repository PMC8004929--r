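test_that("lin/log trapezoid handles flat, rising and falling segments", {
  # constant segment: plain rectangle
  expect_equal(auc_linlog(c(0, 1), c(10, 10)), 10)
  # a falling segment's log value is below its linear value
  log_seg <- auc_linlog(c(0, 1), c(10, 2))
  expect_lt(log_seg, (10 + 2) / 2)
  expect_equal(log_seg, (10 - 2) / log(10 / 2), tolerance = 1e-12)
  # input validation
  expect_error(auc_linlog(1, 5), "2 points")
  expect_error(auc_linlog(c(0, 0), c(1, 1)), "increasing")
  expect_error(auc_linlog(c(0, 1), c(-1, 1)), ">= 0")
})

test_that("AUC matches the closed-form mono-exponential integral", {
  c0 <- 120; k <- 0.3
  tmax <- 5 * log(2) / k
  tt <- seq(0, tmax, length.out = 50)
  cc <- c0 * exp(-k * tt)
  truth_t <- c0 / k * (1 - exp(-k * tmax))
  expect_lt(abs(auc_linlog(tt, cc) - truth_t) / truth_t, 0.005)
  # with extrapolation the full integral c0/k is recovered
  ext <- auc_linlog(tt, cc, extrapolate = TRUE)
  expect_lt(abs(ext$AUC_0_inf - c0 / k) / (c0 / k), 0.005)
  expect_equal(ext$lambda_z, k, tolerance = 1e-6)
})

test_that("AUC agrees with a high-resolution quadrature oracle on model output", {
  # log-spaced grid resolves the minutes-scale initial decline, plus the
  # study sampling times
  tt <- sort(unique(c(exp(seq(log(0.02), log(24), length.out = 250)),
                      c(5 / 60, 1, 6, 12, 24))))
  sim <- simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                       times = tt)
  auc <- auc_linlog(sim$times, sim$obs_nM[, "plasma"])
  # oracle: plain linear trapezoid on a 6000-point grid
  td <- exp(seq(log(0.02), log(24), length.out = 6000))
  dense <- simulate_pbpk(dose_event(0.1, 28), system = fx_system(),
                         times = td)
  dc <- dense$obs_nM[, "plasma"]
  oracle <- sum(diff(td) * (dc[-1] + dc[-length(dc)]) / 2)
  expect_lt(abs(auc - oracle) / oracle, 0.005)
})

test_that("moment analysis recovers the closed-form CL, Vss and half-life", {
  v <- 40; k <- 0.28; dose <- 3900
  tmax <- 5 * log(2) / k
  tt <- seq(0, tmax, length.out = 50)
  cc <- dose / v * exp(-k * tt)
  res <- moment_analysis(tt, cc, dose)
  expect_lt(abs(res$CL - v * k) / (v * k), 0.01)        # 11.2 mL/h
  expect_equal(res$t_half, log(2) / 0.28, tolerance = 1e-4)  # 2.476 h
  expect_lt(abs(res$Vss - v) / v, 0.01)
  # linearity: doubling the dose doubles AUC and leaves CL unchanged
  res2 <- moment_analysis(tt, 2 * cc, 2 * dose)
  expect_equal(res2$AUC_0_inf, 2 * res$AUC_0_inf, tolerance = 1e-10)
  expect_equal(res2$CL, res$CL, tolerance = 1e-10)
  # no estimable terminal slope -> flagged partial result
  res3 <- moment_analysis(c(0, 1, 2), c(1, 2, 3), dose)
  expect_true(res3$partial)
  expect_true(is.na(res3$CL))
  expect_gt(res3$AUC_0_t, 0)
})

test_that("partition coefficients reproduce the reference AUC ratios", {
  expect_equal(signif(kp(94.6, 75.4), 3), 1.25)          # muscle
  expect_lt(abs(kp(2396, 75.4) - 31.6) / 31.6, 0.01)     # kidney
  expect_equal(kp(75.4, 75.4), 1)
  expect_error(kp(10, 0), "AUC_plasma")
})

test_that("cellular-space adjustment divides by the cellular fraction", {
  expect_equal(adjust_kp(35.3, 0.5439), 64.9, tolerance = 1e-3)  # lung
  expect_equal(adjust_kp(2.5, 1), 2.5)
  f <- runif(20, 0.05, 1)
  expect_true(all(adjust_kp(2.5, f) >= 2.5))
  expect_error(adjust_kp(1, 0), "f_cellular")
  expect_error(adjust_kp(1, 1.2), "f_cellular")
})

test_that("percent predictive error follows the absolute-value convention", {
  expect_equal(percent_pe(75.4, 75.4), 0)
  expect_equal(percent_pe(81.59, 75.4), 8.21, tolerance = 1e-3)
  expect_equal(percent_pe(69.21, 75.4), percent_pe(81.59, 75.4),
               tolerance = 1e-12)
  expect_equal(percent_pe(69.21, 75.4, signed = TRUE),
               -percent_pe(69.21, 75.4), tolerance = 1e-12)
  expect_error(percent_pe(1, 0), "AUC_obs")
})

test_that("IVIVE scales in vitro clearance to whole-liver mL/h", {
  hep <- ivive(3, 135, 1.0, f_metabolic = 0.4, basis = "hepatocyte")
  expect_equal(hep$CL_metabolic, 24.3, tolerance = 1e-12)
  expect_equal(hep$CL_total, 24.3 / 0.4, tolerance = 1e-12)
  mic <- ivive(24, 41.9, 1.0, basis = "microsome", sf_basis = "microsome")
  expect_equal(mic$CL_metabolic, 24 * 41.9 * 60 / 1000, tolerance = 1e-12)
  # f_metabolic = 1: total equals metabolic
  expect_equal(ivive(3, 135, 1, f_metabolic = 1)$CL_total, 24.3,
               tolerance = 1e-12)
  expect_error(ivive(3, 41.9, 1, basis = "hepatocyte",
                     sf_basis = "microsome"), "do not match")
  expect_error(ivive(-3, 135, 1), "positive")
})

test_that("allometric PS scaling uses the body-surface exponent", {
  expect_equal(scale_ps(2.5, 28, 28), 2.5)
  expect_equal(scale_ps(1.0, 28, 28000), 1000^0.67, tolerance = 1e-12)
  bw <- c(30, 300, 3000, 30000)
  expect_true(all(diff(scale_ps(1, 28, bw)) > 0))
  expect_error(scale_ps(1, 0, 28), "positive")
})

test_that("kp_table pools replicates and adjusts by cellular fraction", {
  des <- study_design(sigma1 = 0, sigma2 = 0)
  ds <- generate_study(des, fx_phys(), fx_drug(), fx_tum())
  kt <- kp_table(ds, fx_phys())
  expect_true(all(c("plasma", "blood", "tumor") %in% kt$matrix))
  expect_true(is.na(kt$Kp[kt$matrix == "plasma"]))
  # adjusted Kp >= apparent Kp for tissues
  tis <- kt$matrix %in% mmaepbpk:::.tissues
  expect_true(all(kt$Kp_adj[tis] >= kt$Kp[tis]))
  # blood Kp not adjusted
  expect_equal(kt$Kp_adj[kt$matrix == "blood"],
               kt$Kp[kt$matrix == "blood"])
  # the CLint-accounted liver constant rides along as metadata
  expect_equal(attr(kt, "liver_kp_clint"), 25.3)
  # highly perfused tissues show the strong partitioning of the payload
  expect_gt(kt$Kp[kt$matrix == "lung"], 20)
  expect_lt(kt$Kp[kt$matrix == "brain"], 1)
})
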