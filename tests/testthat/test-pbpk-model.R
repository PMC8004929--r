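# Construct the closed-form distributional equilibrium for a uniform plasma
# concentration cp: every exchange flux cancels by the partitioning algebra.
.analytic_equilibrium <- function(system, cp) {
  drug <- system$drug; tum <- system$tum
  y <- setNames(numeric(length(system$state_names)), system$state_names)
  y["plasma"] <- cp
  y["bc"] <- drug$Kp_BC * cp
  for (t in mmaepbpk:::.tissues) {
    y[paste0(t, ".plasma")] <- cp
    y[paste0(t, ".bc")] <- drug$Kp_BC * cp
    y[paste0(t, ".endo")] <- drug$fu_p * cp
    y[paste0(t, ".is")] <- drug$fu_p * cp
    y[paste0(t, ".cell")] <- drug$Kp[[t]] * cp
  }
  y["tumor.extra"] <- tum$epsilon * cp
  y["tumor.free"] <- tum$k_in / tum$k_out * tum$epsilon * cp
  kd <- tum$k_off / tum$k_on
  y["tumor.bound"] <- tum$C_tubulin * y["tumor.free"] /
    (kd + y["tumor.free"])
  y
}

test_that("the system is homogeneous: zero state has zero derivative", {
  dy <- pbpk_rhs(0, numeric(81), fx_system())
  expect_equal(dy, setNames(numeric(81), mmaepbpk:::.state_names))
})

test_that("amount-weighted fluxes conserve mass in the coefficient matrix", {
  # with the elimination bookkeeping state included, w'A = 0 identically,
  # with and without hepatic clearance
  for (cl in c(0, 137)) {
    sys <- build_pbpk_system(fx_phys(), drug_params(CL_int = cl), fx_tum())
    resid <- drop(sys$w %*% sys$A)
    scale <- max(abs(sys$A %*% diag(sys$w)))
    expect_lt(max(abs(resid)) / scale, 1e-12)
  }
})

test_that("rhs vanishes at the analytic equilibrium with CL_int = 0", {
  sys0 <- build_pbpk_system(fx_phys(), drug_params(CL_int = 0), fx_tum())
  y <- .analytic_equilibrium(sys0, cp = 12.5)
  dy <- pbpk_rhs(0, y, sys0)
  # relative to the largest individual flux term feeding any state
  flux_scale <- max(abs(sys0$A) %*% y)
  expect_lt(max(abs(dy)) / flux_scale, 1e-8)
})

test_that("rhs rejects malformed states", {
  expect_error(pbpk_rhs(0, numeric(10), fx_system()), "length")
  y <- numeric(81); y[5] <- NaN
  expect_error(pbpk_rhs(0, y, fx_system()), "finite")
})

test_that("stationary distribution satisfies the PS flux balance", {
  sys0 <- build_pbpk_system(fx_phys(), drug_params(CL_int = 0), fx_tum())
  eq <- equilibrium_state(sys0, total_amount = 3900)
  drug <- sys0$drug
  for (t in mmaepbpk:::.tissues) {
    cis <- eq[paste0(t, ".is")]
    ccell <- eq[paste0(t, ".cell")]
    expect_lt(abs(cis - drug$fu_p / drug$Kp[[t]] * ccell) / cis, 1e-6)
  }
  # blood-cell and cellular partitioning recover the Kp values
  expect_equal(unname(eq["bc"] / eq["plasma"]), drug$Kp_BC,
               tolerance = 1e-8)
  for (t in c("lung", "kidney", "brain"))
    expect_equal(unname(eq[paste0(t, ".cell")] / eq[paste0(t, ".plasma")]),
                 unname(drug$Kp[[t]]), tolerance = 1e-6)
  # the stationary state is an actual fixed point of the nonlinear system
  dy <- pbpk_rhs(0, eq, sys0)
  expect_lt(max(abs(dy)) / max(abs(sys0$A) %*% eq), 1e-8)
  # amount constraint honored
  expect_equal(sum(sys0$w * eq), 3900, tolerance = 1e-9)
  # closed-system requirement
  expect_error(equilibrium_state(fx_system(), 100), "CL_int")
})

test_that("trajectories are dose-linear when tubulin is far from saturation", {
  tum_lin <- tumor_params(C_tubulin = 2e6)
  sys_a <- build_pbpk_system(fx_phys(), fx_drug(), tum_lin)
  tt <- c(1, 6, 24, 168)
  s1 <- simulate_pbpk(dose_event(0.1, 28), system = sys_a, times = tt)
  s2 <- simulate_pbpk(dose_event(0.2, 28), system = sys_a, times = tt)
  r1 <- s1$obs_nM; r2 <- s2$obs_nM
  keep <- r1 > 1e-6
  expect_lt(max(abs(r2[keep] / r1[keep] - 2) / 2), 0.005)
})
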