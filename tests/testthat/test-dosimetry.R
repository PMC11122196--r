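test_that("bi-exponential fit recovers exact parameters from noise-free data", {
  tt <- c(1, 2, 4, 8, 24, 48, 96, 168)
  a <- c(8e-5, 2e-5)
  l <- c(0.15, 0.01)
  lp <- 0.0036
  y <- (a[1] * exp(-(l[1] + lp) * tt) + a[2] * exp(-(l[2] + lp) * tt)) * 3.5
  fit <- fit_biexponential(tt, y, A0 = 3.5, l_phys = lp)
  expect_lt(max(abs(c(fit$a - a, fit$l - l)) / c(a, l)), 1e-6)
  expect_gt(attr(fit, "r2"), 1 - 1e-10)

  expect_error(fit_biexponential(tt[1:4], y[1:4]), "at least 5")
  expect_error(fit_biexponential(rev(tt), y), "strictly increasing")
})

test_that("single-exponential data yield a degenerate second component without changing doses", {
  tt <- c(1, 2, 4, 8, 24, 48, 96, 168)
  lp <- 0.0036
  y <- 8e-5 * exp(-(0.15 + lp) * tt)
  fit <- expect_silent(fit_biexponential(tt, y, l_phys = lp))
  expect_lt(abs(fit$a[2]), 1e-10)
  wb <- std_wholebody()
  pd_fit <- patient_dosimetry(3.5, 75, fit, wb, ref_coeffs())
  pd_one <- patient_dosimetry(3.5, 75, biexp_clearance(c(8e-5, 0), c(0.15, 0)),
                              wb, ref_coeffs())
  probe <- c(1, 24, 168, 1000)
  expect_lt(max(abs(cumulative_dose(pd_fit, probe) - cumulative_dose(pd_one, probe)) /
                  cumulative_dose(pd_one, probe)), 1e-6)
})

test_that("TIAC from noisy bi-exponential fits is accurate at the percent level", {
  tt <- c(1, 2, 4, 8, 24, 48, 96, 168)
  a <- c(8e-5, 2e-5)
  l <- c(0.15, 0.01)
  lp <- 0.0036
  tau_true <- sum(a / (l + lp))
  set.seed(5)
  errs <- replicate(50, {
    y <- (a[1] * exp(-(l[1] + lp) * tt) + a[2] * exp(-(l[2] + lp) * tt)) *
      exp(rnorm(length(tt), 0, 0.01))
    f <- fit_biexponential(tt, y, l_phys = lp)
    abs(sum(f$a / (f$l + lp)) - tau_true) / tau_true
  })
  expect_lt(median(errs), 0.02)
})

test_that("dose rate is the derivative of the cumulative dose", {
  pd <- std_patient()
  grid <- c(0.5, 1, 4, 24, 100, 400)
  h <- 1e-5
  num <- (cumulative_dose(pd, grid + h) - cumulative_dose(pd, grid - h)) / (2 * h)
  expect_lt(max(abs(num - dose_rate(pd, grid)) / dose_rate(pd, grid)), 1e-6)
  expect_error(dose_rate(pd, -1), ">= 0")
})

test_that("closed-form cumulative dose matches adaptive quadrature of the dose rate", {
  set.seed(101)
  for (i in 1:20) {
    pd <- random_patient()
    tend <- runif(1, 10, 800)
    q <- integrate(function(s) dose_rate(pd, s), 0, tend, rel.tol = 1e-12,
                   abs.tol = 0)$value
    expect_lt(abs(cumulative_dose(pd, tend) - q) / q, 1e-8)
  }
})

test_that("cumulative dose is zero at t=0, non-decreasing, and bounded by the total dose", {
  set.seed(202)
  for (i in 1:20) {
    pd <- random_patient()
    expect_identical(cumulative_dose(pd, 0), 0)
    d <- cumulative_dose(pd, seq(0, 2000, length.out = 80))
    expect_true(all(diff(d) >= 0))
    expect_true(all(d <= total_dose(pd) + 1e-9))
  }
})

test_that("total dose equals the large-t limit and scales linearly in A0", {
  pd <- std_patient()
  expect_lt(abs(total_dose(pd) - cumulative_dose(pd, 1e5)) / total_dose(pd), 1e-6)
  pd2 <- std_patient(A0 = 7.0)
  expect_equal(total_dose(pd2), total_dose(pd) * 2)
  expect_equal(dose_rate(pd2, 5), dose_rate(pd, 5) * 2)
})

test_that("dose functions scale linearly in the dose coefficients", {
  bl <- std_blood()
  wb <- std_wholebody()
  pd1 <- patient_dosimetry(3.5, 75, bl, wb, dose_coefficients(108, 0.0188))
  pd2 <- patient_dosimetry(3.5, 75, bl, wb, dose_coefficients(216, 0.0376))
  expect_equal(cumulative_dose(pd2, c(4, 48, 500)),
               2 * cumulative_dose(pd1, c(4, 48, 500)))
})

test_that("whole-body retention must start near 1 unless overridden", {
  wb_bad <- biexp_clearance(c(0.4, 0.1), c(0.07, 0.006))
  expect_error(patient_dosimetry(3.5, 75, std_blood(), wb_bad, ref_coeffs()),
               "retention at t=0")
  expect_s3_class(patient_dosimetry(3.5, 75, std_blood(), wb_bad, ref_coeffs(),
                                    check_wb_norm = FALSE),
                  "patient_dosimetry")
})

test_that("piecewise evaluator reproduces the closed form on model-true data", {
  pd <- std_patient()
  ts <- c(1, 2, 3, 4, 8, 16, 24, 36, 48, 72, 96, 120, 168, 240, 400, 700, 1100)
  vals <- clearance_value(pd$blood, ts) * pd$A0
  for (bp in c(24, 48, 96)) {
    pw <- piecewise_tiac(pd, ts, vals, bp)
    expect_lt(abs(total_dose(pw) - total_dose(pd)) / total_dose(pd), 0.02)
    # cumulative dose continuous at the breakpoint
    expect_lt(abs(cumulative_dose(pw, bp - 1e-6) - cumulative_dose(pw, bp + 1e-6)),
              1e-4)
  }
})

test_that("piecewise evaluator adds re-uptake dose and drops to zero correctly", {
  pd <- std_patient()
  ts <- c(1, 2, 3, 4, 24, 48, 96, 168)
  vals <- clearance_value(pd$blood, ts) * pd$A0
  reup <- vals
  reup[ts >= 96] <- reup[ts >= 96] * 3   # renewed uptake after 96 h
  pw_re <- piecewise_tiac(pd, ts, reup, 48)
  expect_gt(total_dose(pw_re), total_dose(pd))

  # zero activity from the breakpoint on: no beta dose beyond it
  co0 <- dose_coefficients(108, 1e-12)
  pd0 <- patient_dosimetry(3.5, 75, pd$blood, pd$wholebody, co0)
  zero <- vals
  zero[ts >= 48] <- 0
  pw0 <- piecewise_tiac(pd0, ts, zero, 48)
  expect_equal(total_dose(pw0), cumulative_dose(pd0, 48), tolerance = 1e-6)

  expect_error(piecewise_tiac(pd, ts, vals, 168), "beyond last sample")
  expect_error(piecewise_tiac(pd, ts, vals, 50), "one of the sample times")
})
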