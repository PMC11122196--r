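test_that("RIF values and Poisson-propagated uncertainties follow the counting formula", {
  r <- rif_from_counts(1, 64, 100, 0, 100)
  expect_equal(r$N, 0.64)
  expect_equal(r$sigma, sqrt(65) / 100)  # 1-count floor on the zero baseline

  r2 <- rif_from_counts(1, 30, 100, 30, 100)
  expect_equal(r2$N, 0)

  expect_error(rif_from_counts(1, 10, 0, 5, 100), "cells")
  # negative RIF is legal and not clipped
  r3 <- rif_from_counts(1, 5, 100, 20, 100)
  expect_lt(r3$N, 0)
})

test_that("reported sigma calibrates against the empirical SD of replicate counts", {
  set.seed(3)
  reps <- replicate(10000, {
    s <- rpois(1, 100 * 0.5)
    b <- rpois(1, 100 * 0.1)
    r <- rif_from_counts(1, s, 100, b, 100)
    c(r$N, r$sigma)
  })
  expect_lt(abs(sd(reps[1, ]) - mean(reps[2, ])) / sd(reps[1, ]), 0.05)
})

test_that("model reduces to the intercept with no induction and at t = 0", {
  pd <- std_patient()
  p0 <- kinetic_params(0, 0.9, 0.5, 0.01, N0 = 0.07)
  expect_equal(model_rif(c(0, 1, 24, 500), p0, pd), rep(0.07, 4))
  p1 <- kinetic_params(0.03, 0.95, 0.4, 0.01, N0 = -0.02)
  expect_equal(model_rif(0, p1, pd), -0.02)
})

test_that("closed form agrees with the ODE oracle over random draws", {
  set.seed(42)
  grid <- seq(0, 500, by = 10)
  for (i in 1:30) {
    pd <- random_patient()
    kp <- kinetic_params(runif(1, 0.01, 0.11), runif(1, 0, 1),
                         runif(1, 0.01, 3), runif(1, 0, 0.05))
    ode <- model_rif_ode(grid, kp, function(s) dose_rate(pd, s))
    expect_lt(max(abs(model_rif(grid, kp, pd) - ode$N)), 1e-6)
  }
})

test_that("degenerate repair rates (k ~ lambda, k = 0) are handled smoothly", {
  pd <- std_patient()
  lam1 <- pd$blood$l[1] + pd$coefficients$l_phys
  grid <- seq(0, 400, by = 5)
  # k1 exactly at the blood clearance rate
  kp <- kinetic_params(0.03, 0.95, lam1, 1e-9)
  ode <- model_rif_ode(grid, kp, function(s) dose_rate(pd, s))
  expect_lt(max(abs(model_rif(grid, kp, pd) - ode$N)), 1e-6)
  # continuity at k2 = 0 over the study window
  win <- seq(0, 168, by = 2)
  a <- model_rif(win, kinetic_params(0.03, 0.95, 0.4, 0), pd)
  b <- model_rif(win, kinetic_params(0.03, 0.95, 0.4, 1e-6), pd)
  expect_lt(max(abs(a - b)), 1e-4)
  # k2 = 0: slow pool accumulates (1-alpha) c D(t) -> total dose
  kp0 <- kinetic_params(0.03, 0.8, 0.4, 0, N0 = 0.01)
  n_inf <- model_rif(5e4, kp0, pd)
  expect_lt(abs(n_inf - (0.01 + 0.2 * 0.03 * total_dose(pd))) /
              (0.2 * 0.03 * total_dose(pd)), 1e-4)
})

test_that("model is linear in c and reduces to the single-rate model at alpha = 1", {
  pd <- std_patient()
  grid <- c(1, 4, 24, 168)
  base <- model_rif(grid, kinetic_params(0.02, 0.9, 0.5, 0.01), pd)
  twice <- model_rif(grid, kinetic_params(0.04, 0.9, 0.5, 0.01), pd)
  expect_equal(twice, 2 * base, tolerance = 1e-12)
  one_a <- model_rif(grid, kinetic_params(0.02, 1, 0.5, 0.007), pd)
  one_b <- model_rif(grid, kinetic_params(0.02, 1, 0.5, 0.04, canonicalize = FALSE), pd)
  expect_equal(one_a, one_b, tolerance = 1e-12)
})

test_that("ODE solution honours trivial limits", {
  p <- kinetic_params(0.05, 1, 0.5, 0.01, N0 = 0.03)
  flat <- model_rif_ode(seq(0, 100, by = 10), p, function(s) 0 * s)
  expect_equal(flat$N, rep(0.03, nrow(flat)), tolerance = 1e-9)
  # constant dose rate r, alpha = 1: steady state N0 + c r / k1
  cr <- model_rif_ode(seq(0, 2000, by = 100), p, function(s) rep(2, length(s)))
  expect_equal(tail(cr$N, 1), 0.03 + 0.05 * 2 / 0.5, tolerance = 1e-6)
})

test_that("time of maximum matches the analytic two-exponential formula", {
  # single blood exponential, no photon term, alpha = 1
  bl <- biexp_clearance(c(1.5e-5, 0), c(0.10, 0))
  pd <- patient_dosimetry(3.5, 75, bl, std_wholebody(),
                          dose_coefficients(108, 1e-12), check_wb_norm = TRUE)
  k1 <- 0.5
  lam <- 0.10 + 0.0036
  kp <- kinetic_params(0.03, 1, k1, 0.01)
  tm <- time_of_max(kp, pd)
  expect_equal(tm$t_max, log(k1 / lam) / (k1 - lam), tolerance = 1e-6)
})

test_that("faster repair peaks earlier and peak time is invariant in c", {
  pd <- std_patient()
  k1s <- c(0.2, 0.5, 1.0, 2.0)
  tmax <- vapply(k1s, function(k)
    time_of_max(kinetic_params(0.03, 1, k, 0.01), pd)$t_max, 1)
  expect_true(all(diff(tmax) < 0))
  t_a <- time_of_max(kinetic_params(0.01, 0.95, 0.4, 0.01), pd)$t_max
  t_b <- time_of_max(kinetic_params(0.10, 0.95, 0.4, 0.01), pd)$t_max
  expect_equal(t_a, t_b, tolerance = 1e-6)
  expect_error(time_of_max(kinetic_params(0, 1, 0.5, 0.01), pd), "no maximum")
})

test_that("canonical ordering keeps k1 >= k2 with relabelled alpha", {
  p <- kinetic_params(0.03, 0.2, 0.01, 0.8)
  expect_equal(p$k1, 0.8)
  expect_equal(p$k2, 0.01)
  expect_equal(p$alpha, 0.8)
})
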