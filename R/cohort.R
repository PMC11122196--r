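#' Group patients by fast repair rate
#'
#' The fast repair rates observed across patients split into a slow-repair
#' mode and a fast-repair mode with an empty gap between them; patients are
#' labelled Group 1 (`k1 < low`) or Group 2 (`k1 > high`). Values inside the
#' gap are labelled `"unassigned"`.
#'
#' @param k1 Vector of fitted fast repair rates (h^-1); `NA` allowed.
#' @param low,high Gap boundaries (defaults 0.6 and 1.1 h^-1).
#' @return Character vector of labels `"1"`, `"2"`, `"unassigned"` or `NA`.
#' @export
group_by_k1 <- function(k1, low = 0.6, high = 1.1) {
  if (low >= high) stop_rifkin("low threshold must be < high threshold")
  out <- rep(NA_character_, length(k1))
  out[!is.na(k1) & k1 < low] <- "1"
  out[!is.na(k1) & k1 > high] <- "2"
  out[!is.na(k1) & k1 >= low & k1 <= high] <- "unassigned"
  out
}

#' K-means clustering of kinetic parameters
#'
#' Clusters patients on the *unstandardised* triple `(k1, k2, c)` — the raw
#' parameter scales are retained deliberately so that the centroids are
#' directly interpretable as group means of the physical parameters (and `k1`,
#' the dominant scale, drives the partition). Patients with any missing value
#' and patients on the exclusion list are removed first. The cluster whose
#' centroid has the smaller `k1` is labelled 1.
#'
#' Restarts use an internally seeded RNG (restored afterwards) so the result
#' is reproducible regardless of the caller's seed.
#'
#' @param fits data.frame with columns `patient_id`, `k1`, `k2`, `c`.
#' @param k Number of clusters (default 2).
#' @param exclude Character vector of patient ids excluded before clustering.
#' @param nstart Random restarts (default 20).
#' @return List with `assignments` (named by patient id), `centers` (one row
#'   per cluster, ordered by `k1`), `sizes` and the ids used.
#' @export
kmeans_params <- function(fits, k = 2L, exclude = character(), nstart = 20L) {
  stopifnot(all(c("patient_id", "k1", "k2", "c") %in% names(fits)))
  use <- stats::complete.cases(fits[, c("k1", "k2", "c")]) &
    !(fits$patient_id %in% exclude)
  d <- fits[use, , drop = FALSE]
  if (nrow(d) < k) stop_rifkin("fewer complete patients than clusters")
  m <- as.matrix(d[, c("k1", "k2", "c")])
  km <- with_local_seed(20240501L,
                        stats::kmeans(m, centers = k, nstart = nstart,
                                      iter.max = 100))
  ord <- order(km$centers[, "k1"])
  relabel <- match(seq_len(k), ord)
  assignments <- stats::setNames(relabel[km$cluster], d$patient_id)
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(assignments = assignments, centers = centers,
       sizes = as.integer(table(assignments)), patient_id = d$patient_id)
}

#' Flag outlying kinetic parameter vectors
#'
#' Default rule: a patient is flagged when any of `k1`, `k2`, `c` lies above
#' `Q3 + 1.5 * IQR` of the respective column (computed over the non-missing
#' fits). An explicit list can be supplied instead for exact reproduction of a
#' given analysis.
#'
#' @param fits data.frame with `patient_id`, `k1`, `k2`, `c`.
#' @param explicit Optional character vector of patient ids; if given, exactly
#'   these are flagged.
#' @param factor IQR multiplier (default 1.5).
#' @return Character vector of flagged patient ids.
#' @export
detect_outliers <- function(fits, explicit = NULL, factor = 1.5) {
  if (!is.null(explicit)) return(intersect(fits$patient_id, explicit))
  flagged <- character()
  for (v in c("k1", "k2", "c")) {
    x <- fits[[v]]
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    hi <- q[2] + factor * (q[2] - q[1])
    flagged <- union(flagged, fits$patient_id[!is.na(x) & x > hi])
  }
  flagged[order(match(flagged, fits$patient_id))]
}

.shapiro_normal <- function(x, level = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(list(normal = FALSE, p = NA_real_))
  p <- stats::shapiro.test(x)$p.value
  list(normal = p >= level, p = p)
}

.stat_result <- function(var1, var2, method, estimate, statistic, p, n,
                         normal = NA) {
  data.frame(var1 = var1, var2 = var2, method = method,
             estimate = estimate, statistic = statistic, p = p, n = n,
             normal_routing = normal, stringsAsFactors = FALSE)
}

#' Normality-routed correlation
#'
#' Tests each variable for normality (Shapiro-Wilk at the 5% level) and
#' applies Pearson's method when both pass, Spearman's otherwise. Spearman
#' uses average ranks for ties. The routing can be overridden with `method`.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @param method `"auto"` (normality-routed), `"pearson"` or `"spearman"`.
#' @param labels Length-2 character vector naming the variables.
#' @param level Significance level of the normality gate.
#' @return One-row data.frame: variables, method, correlation estimate,
#'   statistic, p-value, n.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      labels = c("x", "y"), level = 0.05) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop_rifkin("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_rifkin("constant vector: correlation undefined")
  routed <- NA
  if (method == "auto") {
    nx <- .shapiro_normal(x, level); ny <- .shapiro_normal(y, level)
    routed <- nx$normal && ny$normal
    method <- if (routed) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = method == "spearman" &&
                                           length(x) < 10))
  .stat_result(labels[1], labels[2], method,
               unname(ct$estimate), unname(ct$statistic), ct$p.value,
               length(x), routed)
}

#' Normality-routed two-sample comparison
#'
#' Shapiro-Wilk on each group at the 5% level; Welch's t-test when both pass,
#' Mann-Whitney U (Wilcoxon rank-sum) otherwise. Override with `method`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector with exactly two levels among the non-missing
#'   values.
#' @param method `"auto"`, `"t-test"` or `"mann-whitney"`.
#' @param label Name of the compared variable.
#' @param level Significance level of the normality gate.
#' @return One-row data.frame with method, statistic, p-value and n.
#' @export
compare_groups <- function(values, groups,
                           method = c("auto", "t-test", "mann-whitney"),
                           label = "value", level = 0.05) {
  method <- match.arg(method)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(droplevels(groups)) != 2L) stop_rifkin("need exactly two groups")
  groups <- droplevels(groups)
  g <- split(values, groups)
  routed <- NA
  if (method == "auto") {
    n1 <- .shapiro_normal(g[[1]], level); n2 <- .shapiro_normal(g[[2]], level)
    routed <- isTRUE(n1$normal) && isTRUE(n2$normal)
    method <- if (routed) "t-test" else "mann-whitney"
  }
  if (method == "t-test") {
    tt <- stats::t.test(g[[1]], g[[2]])
    est <- diff(rev(tt$estimate))
    res <- .stat_result(label, paste(levels(groups), collapse = " vs "),
                        "t-test", unname(est), unname(tt$statistic),
                        tt$p.value, length(values), routed)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]]))
    res <- .stat_result(label, paste(levels(groups), collapse = " vs "),
                        "mann-whitney", NA_real_, unname(wt$statistic),
                        wt$p.value, length(values), routed)
  }
  res
}

#' Cohort summary of fitted kinetic parameters
#'
#' @param fits data.frame with columns `c`, `alpha`, `k1`, `k2`, `N0` and
#'   optionally `excluded`/`reason`.
#' @return List with median/min/max of `c`, `k1`, `k2`, mean and SD of
#'   `alpha` (also as percent) and `N0`, and exclusion counts.
#' @export
summarize_cohort <- function(fits) {
  rng <- function(x) {
    x <- x[is.finite(x)]
    c(median = stats::median(x), min = min(x), max = max(x))
  }
  ms <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), sd = stats::sd(x))
  }
  excl <- if ("excluded" %in% names(fits)) sum(fits$excluded, na.rm = TRUE) else 0L
  reasons <- if ("reason" %in% names(fits))
    table(fits$reason[!is.na(fits$reason) & fits$reason != ""]) else table(character())
  n0 <- if ("N0" %in% names(fits)) fits$N0 else fits$n0
  list(c = rng(fits$c), k1 = rng(fits$k1), k2 = rng(fits$k2),
       alpha = ms(fits$alpha), alpha_percent = 100 * ms(fits$alpha),
       N0 = ms(n0), n = nrow(fits), n_excluded = excl,
       exclusion_reasons = reasons)
}

#' Correlation battery over kinetic parameters and covariates
#'
#' Runs the standard panel: pairwise correlations among `(k1, k2, c)`, each
#' against the ex vivo repair rate `R` (when present), patient age against
#' each parameter (and against RIF at 1 h and 48 h when those columns are
#' present), age against `R`, and each parameter against every additional
#' clinical covariate column supplied. Each pair uses all patients with
#' complete data for that pair; `n` is recorded per test. P-values are
#' unadjusted by default (two-sided, 5% reference level), with optional
#' Benjamini-Hochberg adjustment appended as a column.
#'
#' @param cohort data.frame with `patient_id`, parameter columns `k1`, `k2`,
#'   `c`, and optional `R`, `age`, `rif_1h`, `rif_48h` plus covariate columns.
#' @param covariates Extra covariate column names to cross against the
#'   parameters.
#' @param adjust If `TRUE` append a `p_adj` column (BH).
#' @return data.frame of stacked [correlate()] rows.
#' @export
correlation_battery <- function(cohort, covariates = character(),
                                adjust = FALSE) {
  pairs <- list(c("k1", "k2"), c("k1", "c"), c("k2", "c"))
  for (v in intersect("R", names(cohort)))
    pairs <- c(pairs, list(c("k1", "R"), c("k2", "R"), c("c", "R")))
  if ("age" %in% names(cohort)) {
    for (p in c("k1", "k2", "c")) pairs <- c(pairs, list(c("age", p)))
    for (p in intersect(c("rif_1h", "rif_48h", "R"), names(cohort)))
      pairs <- c(pairs, list(c("age", p)))
  }
  for (cv in intersect(covariates, names(cohort)))
    for (p in c("k1", "k2", "c")) pairs <- c(pairs, list(c(cv, p)))
  pairs <- unique(pairs)
  rows <- lapply(pairs, function(pr) {
    tryCatch(correlate(cohort[[pr[1]]], cohort[[pr[2]]], labels = pr),
             error = function(e) NULL)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (adjust && nrow(out)) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
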