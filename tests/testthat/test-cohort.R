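ref <- reference_fit_params()
clin <- reference_clinical()

test_that("k1 thresholds reproduce the published group assignment", {
  labels <- group_by_k1(ref$k1)
  expect_equal(labels, as.character(ref$group))
  expect_equal(sum(labels == "1"), 8L)
  expect_equal(sum(labels == "2"), 6L)
  expect_equal(ref$patient_id[labels == "1"],
               c("IP1", "IP2", "IP3", "IP5", "IP7", "IP15", "IP16", "IP18"))
  expect_equal(ref$patient_id[labels == "2"],
               c("IP4", "IP6", "IP9", "IP13", "IP14", "IP17"))

  expect_equal(group_by_k1(0.8), "unassigned")
  expect_error(group_by_k1(0.8, low = 1.1, high = 0.6), "low threshold")
})

test_that("k-means on the 12 complete patients reproduces the published centroids", {
  km <- kmeans_params(ref, k = 2, exclude = "IP6")
  expect_equal(length(km$assignments), 12L)
  expect_equal(unname(km$centers[1, c("k1", "c", "k2")]),
               c(0.37429, 0.02143, 0.00657), tolerance = 5e-4)
  expect_equal(unname(km$centers[2, c("k1", "c", "k2")]),
               c(1.3208, 0.052, 0.0276), tolerance = 5e-4)
  # centroids are the within-cluster means of the raw variables
  for (g in 1:2) {
    ids <- names(km$assignments)[km$assignments == g]
    sub <- ref[ref$patient_id %in% ids, c("k1", "k2", "c")]
    expect_equal(unname(km$centers[g, c("k1", "k2", "c")]),
                 unname(colMeans(sub)), tolerance = 1e-12)
  }
  # k-means assignment coincides with the threshold grouping
  expect_equal(unname(as.character(km$assignments)),
               as.character(ref$group[match(names(km$assignments), ref$patient_id)]))
  # stable across repeated runs
  km2 <- kmeans_params(ref, k = 2, exclude = "IP6")
  expect_identical(km$assignments, km2$assignments)
})

test_that("well-separated blobs give centroids equal to blob means", {
  blob <- data.frame(
    patient_id = sprintf("S%02d", 1:10),
    k1 = c(rep(0.3, 5), rep(2, 5)) + (1:10) * 1e-3,
    k2 = 0.01, c = c(rep(0.02, 5), rep(0.06, 5)))
  km <- kmeans_params(blob)
  expect_equal(unname(km$centers[1, "k1"]), mean(blob$k1[1:5]))
  expect_equal(unname(km$centers[2, "k1"]), mean(blob$k1[6:10]))
  expect_error(kmeans_params(blob[1, ]), "fewer")
})

test_that("the IQR rule flags the published outlier and nothing in a homogeneous cohort", {
  expect_equal(detect_outliers(ref), "IP6")
  homog <- data.frame(patient_id = sprintf("S%02d", 1:12),
                      k1 = seq(0.3, 0.5, length.out = 12),
                      k2 = seq(0.005, 0.01, length.out = 12),
                      c = seq(0.02, 0.03, length.out = 12))
  expect_length(detect_outliers(homog), 0)
  expect_equal(detect_outliers(ref, explicit = "IP6"), "IP6")
})

test_that("correlation routing follows the normality gate and handles edge cases", {
  r <- correlate(ref$k1, ref$c, labels = c("k1", "c"))
  expect_equal(r$method, "spearman")  # k1 and c are both non-normal here
  expect_equal(r$estimate, 0.947, tolerance = 5e-4)

  x <- seq(1, 14)
  ident <- correlate(x, x)
  expect_equal(ident$estimate, 1)

  expect_error(correlate(rep(1, 8), rnorm(8)), "constant")
  expect_error(correlate(1:3, 3:1), "at least 4")

  set.seed(31)
  # Spearman is invariant under monotone transforms
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    r1 <- correlate(a, b, method = "spearman")$estimate
    r2 <- correlate(exp(a), b, method = "spearman")$estimate
    r3 <- correlate(a, qlogis(plogis(b)), method = "spearman")$estimate
    expect_equal(r1, r2, tolerance = 1e-12)
    expect_equal(r1, r3, tolerance = 1e-12)
  }
})

test_that("group comparison routes by normality and detects shifts monotonically", {
  g <- rep(c("a", "b"), each = 8)
  v <- rep(c(1.2, 0.8, 1.1, 0.9, 1.05, 0.95, 1.0, 1.0), 2)
  same <- compare_groups(v, g)
  expect_gt(same$p, 0.99)

  k2v <- ref$k2
  cmp <- compare_groups(k2v, ref$group, method = "mann-whitney")
  expect_lt(abs(cmp$p - 0.017), 5e-4)
  expect_lt(cmp$p, 0.05)

  set.seed(17)
  rates <- vapply(c(0, 0.8, 1.6), function(shift) {
    mean(replicate(120, {
      x <- rnorm(10); y <- rnorm(10) + shift
      compare_groups(c(x, y), rep(1:2, each = 10))$p < 0.05
    }))
  }, 1)
  expect_true(all(diff(rates) > 0))
})

test_that("cohort summary reproduces the published aggregates", {
  sm <- summarize_cohort(ref)
  expect_equal(unname(sm$c["median"]), 0.026)
  expect_equal(unname(sm$alpha_percent["mean"]), 96, tolerance = 0.5)
  expect_lt(abs(unname(sm$N0["mean"]) + 0.018), 5e-4)
  expect_equal(unname(sm$k1[c("min", "max")]), c(0.193, 3.028))

  one <- summarize_cohort(ref[1, ])
  expect_equal(unname(one$c["median"]), ref$c[1])
})

test_that("the correlation battery covers the panel and is calibrated under the null", {
  cohort <- ref
  cohort$age <- clin$age_y[match(cohort$patient_id, clin$patient_id)]
  bat <- correlation_battery(cohort)
  pick <- function(a, b) bat[bat$var1 == a & bat$var2 == b, ]
  expect_gt(pick("k1", "R")$p, 0.05)   # in vivo vs ex vivo repair: no correlation
  expect_lt(pick("k1", "c")$p, 0.001)
  expect_equal(pick("age", "k1")$n, 14)

  set.seed(53)
  null_p <- replicate(400, correlate(rnorm(14), rnorm(14))$p)
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)
})
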