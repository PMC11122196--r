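test_that("noise-free data identify all five parameters", {
  pd <- std_patient()
  truth <- kinetic_params(0.03, 0.95, 0.4, 0.01, N0 = 0)
  fit <- fit_patient(exact_rif(truth, pd), pd)
  expect_false(fit$excluded)
  expect_true(fit$converged)
  est <- unlist(fit$params[c("c", "alpha", "k1", "k2")])
  tru <- c(0.03, 0.95, 0.4, 0.01)
  expect_lt(max(abs(est - tru) / tru), 1e-4)
  expect_equal(fit$n_points, 9L)  # 8 samples + the baseline anchor
  expect_gt(fit$r2, 1 - 1e-8)
})

test_that("patients with seven data points are excluded as too-few-points", {
  pd <- std_patient()
  truth <- kinetic_params(0.03, 0.95, 0.4, 0.01)
  rif <- exact_rif(truth, pd, times = c(1, 2, 3, 4, 24, 48))  # 6 + baseline = 7
  fit <- fit_patient(rif, pd)
  expect_true(fit$excluded)
  expect_equal(fit$reason, "too-few-points")
  expect_null(fit$params)
})

test_that("the intercept stays inside the experimental-uncertainty bound", {
  pd <- std_patient()
  truth <- kinetic_params(0.03, 0.95, 0.4, 0.01, N0 = 0)
  rif <- exact_rif(truth, pd)
  rif$N <- rif$N + 0.3          # gross offset the bound must not absorb
  fit <- fit_patient(rif, pd)
  expect_lte(abs(fit$params$N0), attr(rif, "sigma0") + 1e-9)
})

test_that("simplified single-rate fit nests correctly", {
  pd <- std_patient()
  set.seed(7)
  # truth with a single fast rate: both models equivalent
  t1 <- kinetic_params(0.03, 1, 0.4, 0)
  rif1 <- exact_rif(t1, pd)
  rif1$N <- rif1$N + rnorm(nrow(rif1), 0, 0.01)
  fs <- fit_simplified(rif1, pd)
  ff <- fit_patient(rif1, pd)
  expect_equal(fs$params$alpha, 1)
  expect_lt(abs(fs$r2 - ff$r2), 0.01)

  # genuine slow component: the full model fits visibly better
  t2 <- kinetic_params(0.03, 0.9, 0.6, 0.005)
  rif2 <- exact_rif(t2, pd)
  rif2$N <- rif2$N + rnorm(nrow(rif2), 0, 0.005)
  fs2 <- fit_simplified(rif2, pd)
  ff2 <- fit_patient(rif2, pd)
  expect_lt(fs2$r2, ff2$r2)

  one <- rif2[1, , drop = FALSE]
  attr(one, "sigma0") <- 0.04
  expect_true(fit_simplified(one, pd)$excluded)
})

test_that("pooling identical copies of one patient reproduces the single fit", {
  pd <- std_patient()
  truth <- kinetic_params(0.022, 0.954, 0.362, 0.006)
  rif <- exact_rif(truth, pd)
  single <- fit_patient(rif, pd)
  pooled <- fit_pooled(list(list(rif = rif, pd = pd), list(rif = rif, pd = pd)))
  expect_equal(unlist(pooled$params), unlist(single$params), tolerance = 1e-6)
})

test_that("pooled r2 does not exceed the best individual r2 on a heterogeneous group", {
  set.seed(21)
  data <- lapply(1:4, function(i) {
    pd <- random_patient()
    truth <- kinetic_params(runif(1, 0.015, 0.03), 0.95,
                            runif(1, 0.25, 0.55), 0.006)
    list(rif = noisy_rif(truth, pd), pd = pd)
  })
  r2i <- vapply(data, function(d) fit_patient(d$rif, d$pd)$r2, 1)
  pooled <- fit_pooled(data)
  expect_lte(pooled$r2, max(r2i, na.rm = TRUE) + 1e-9)
})

test_that("weighted chi-square is invariant under the fast/slow label swap", {
  pd <- std_patient()
  grid <- c(1, 4, 24, 96)
  a <- model_rif(grid, kinetic_params(0.03, 0.9, 0.7, 0.02, canonicalize = FALSE), pd)
  b <- model_rif(grid, kinetic_params(0.03, 0.1, 0.02, 0.7, canonicalize = FALSE), pd)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("robustness check reports near-zero variation on noise-free data", {
  pd <- std_patient()
  truth <- kinetic_params(0.03, 0.95, 0.4, 0.01)
  rb <- robustness_check(exact_rif(truth, pd), pd)
  expect_lt(max(rb$perturbed, na.rm = TRUE), 1e-4)
  expect_lt(max(rb$drop_one, na.rm = TRUE), 1e-4)
})

test_that("linear fits reproduce exact lines and handle degenerate input", {
  D <- seq(10, 100, length.out = 10)
  lf <- linear_fit_induction(D, 0.01 * D + 0.1)
  expect_equal(lf$slope, 0.010, tolerance = 1e-10)
  expect_equal(lf$intercept, 0.100, tolerance = 1e-10)
  expect_equal(lf$r2, 1)

  flat <- linear_fit_induction(D, rep(0.4, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  expect_error(linear_fit_induction(D[1:2], D[1:2]), "at least 3")
  expect_error(linear_fit_doserate(rep(1, 5), rnorm(5)), "degenerate")

  r <- seq(0.5, 15, length.out = 12)
  lr <- linear_fit_doserate(r, 0.097 * r + 0.085)
  expect_equal(lr$slope, 0.097, tolerance = 1e-10)
})
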