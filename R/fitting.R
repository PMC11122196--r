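#' Options controlling the nonlinear kinetic fits
#'
#' @param min_points Minimum number of valid post-administration RIF points
#'   required to fit (default 8); fewer leads to exclusion with reason
#'   `"too-few-points"`.
#' @param se_factor A fit is excluded with reason `"large-errors"` when the
#'   standard error of any parameter in `se_params` exceeds `se_factor` times
#'   the absolute parameter value (default 2).
#' @param se_params Parameters the error rule is tested on (default `c` and
#'   `k1`; set to `c("c","alpha","k1","k2")` to test all).
#' @param chi2_tol Relative chi-square convergence tolerance for the
#'   Levenberg-Marquardt iterations (default 1e-9).
#' @param maxiter Maximum LM iterations per start.
#' @param start_c,start_k1,start_k2,start_alpha Deterministic multi-start
#'   grids; every combination is tried and the best weighted chi-square wins,
#'   ties broken towards the smaller `k1`.
#' @param n0_bound Half-width of the `N0` box constraint; `NULL` (default)
#'   uses the baseline count's propagated uncertainty carried by the
#'   `rif_series` (falling back to the largest point uncertainty), so the
#'   intercept must stay within the uncertainty of the experimental data.
#' @return List of class `fit_options`.
#' @export
fit_options <- function(min_points = 8L,
                        se_factor = 2,
                        se_params = c("c", "k1"),
                        chi2_tol = 1e-9,
                        maxiter = 150L,
                        start_c = c(0.01, 0.03, 0.1),
                        start_k1 = c(0.2, 0.5, 1.5),
                        start_k2 = c(0.001, 0.01, 0.05),
                        start_alpha = c(0.9, 0.99),
                        n0_bound = NULL) {
  structure(list(min_points = min_points, se_factor = se_factor,
                 se_params = se_params, chi2_tol = chi2_tol,
                 maxiter = maxiter, start_c = start_c, start_k1 = start_k1,
                 start_k2 = start_k2, start_alpha = start_alpha,
                 n0_bound = n0_bound), class = "fit_options")
}

# Valid fit points: finite value and positive finite sigma. When the series
# carries a baseline uncertainty (attribute "sigma0" from rif_from_counts) and
# has no t = 0 row, the baseline anchor (RIF = 0 at t = 0, sigma = sigma0) is
# prepended: the pre-therapy sample defines the zero of the RIF scale and is
# counted as a data point.
.fit_points <- function(rif, anchor = TRUE) {
  ok <- rif$t >= 0 & is.finite(rif$N) & is.finite(rif$sigma) & rif$sigma > 0
  out <- rif[ok, , drop = FALSE]
  s0 <- attr(rif, "sigma0")
  if (anchor && !is.null(s0) && is.finite(s0) && s0 > 0 && !any(out$t == 0)) {
    out <- rbind(data.frame(t = 0, N = 0, sigma = s0), out)
  }
  out
}

.n0_bound <- function(rif, opts) {
  if (!is.null(opts$n0_bound)) return(opts$n0_bound)
  s0 <- attr(rif, "sigma0")
  if (!is.null(s0) && is.finite(s0) && s0 > 0) return(s0)
  max(rif$sigma)
}

# Weighted LM minimisation of the compartment model over one or more patients.
# data: list of list(rif = data.frame(t, N, sigma), pd = patient_dosimetry).
# free: character vector among c("c","alpha","k1","k2","N0").
.lm_kinetic <- function(data, opts, n0_bound, fixed_alpha = NULL) {
  t_all <- unlist(lapply(data, function(d) d$rif$t))
  y <- unlist(lapply(data, function(d) d$rif$N))
  sig <- unlist(lapply(data, function(d) d$rif$sigma))
  w <- 1 / sig^2
  idx <- rep(seq_along(data), vapply(data, function(d) nrow(d$rif), 1L))

  simplified <- !is.null(fixed_alpha)
  predict_fn <- function(p) {
    if (simplified) {
      kp <- kinetic_params(c = p[1], alpha = fixed_alpha, k1 = p[2], k2 = 0,
                           N0 = p[3], canonicalize = FALSE)
    } else {
      kp <- kinetic_params(c = p[1], alpha = p[2], k1 = p[3], k2 = p[4],
                           N0 = p[5], canonicalize = FALSE)
    }
    out <- numeric(length(y))
    for (i in seq_along(data))
      out[idx == i] <- model_rif(t_all[idx == i], kp, data[[i]]$pd)
    out
  }
  resid_fn <- function(p) sqrt(w) * (y - predict_fn(p))

  if (simplified) {
    lower <- c(0, 1e-8, -n0_bound); upper <- c(Inf, Inf, n0_bound)
    starts <- expand.grid(c = opts$start_c, k1 = opts$start_k1, N0 = 0)
  } else {
    lower <- c(0, 0, 1e-8, 0, -n0_bound)
    upper <- c(Inf, 1, Inf, Inf, n0_bound)
    starts <- expand.grid(c = opts$start_c, alpha = opts$start_alpha,
                          k1 = opts$start_k1, k2 = opts$start_k2, N0 = 0)
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[s, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = opts$chi2_tol, ptol = 1e-10,
                           maxiter = opts$maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    k1_here <- if (simplified) fit$par[2] else fit$par[3]
    take <- FALSE
    if (is.null(best)) take <- TRUE
    else if (chi2 < best$chi2 * (1 - 1e-9)) take <- TRUE
    else if (chi2 <= best$chi2 * (1 + 1e-9) && k1_here < best$k1) take <- TRUE
    if (take) best <- list(fit = fit, chi2 = chi2, k1 = k1_here)
  }
  if (is.null(best)) return(NULL)

  fit <- best$fit
  p <- fit$par
  n <- length(y)
  npar <- length(p)
  dof <- n - npar
  se <- rep(NA_real_, npar)
  cv <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cv) && dof > 0) se <- sqrt(pmax(diag(cv), 0) * best$chi2 / dof)

  ybar <- stats::weighted.mean(y, w)
  sstot <- sum(w * (y - ybar)^2)
  r2 <- if (sstot > 0) 1 - best$chi2 / sstot else NA_real_

  if (simplified) {
    params <- kinetic_params(c = p[1], alpha = 1, k1 = p[2], k2 = 0, N0 = p[3],
                             canonicalize = FALSE)
    se_named <- c(c = se[1], alpha = NA_real_, k1 = se[2], k2 = NA_real_,
                  N0 = se[3])
  } else {
    # canonical k1 >= k2: swap rates, relabel alpha and the SEs
    if (p[4] > p[3]) {
      p <- p[c(1, 2, 4, 3, 5)]; p[2] <- 1 - p[2]
      se <- se[c(1, 2, 4, 3, 5)]
    }
    params <- kinetic_params(c = p[1], alpha = p[2], k1 = p[3], k2 = p[4],
                             N0 = p[5], canonicalize = FALSE)
    se_named <- c(c = se[1], alpha = se[2], k1 = se[3], k2 = se[4], N0 = se[5])
  }
  list(params = params, se = se_named, chi2 = best$chi2, r2 = r2,
       converged = fit$info %in% 1:4, n_points = n)
}

.fit_result <- function(params = NULL, se = NULL, r2 = NA_real_,
                        n_points = 0L, converged = FALSE, excluded = FALSE,
                        reason = NA_character_, chi2 = NA_real_) {
  structure(list(params = params, se = se, r2 = r2, n_points = n_points,
                 converged = converged, excluded = excluded, reason = reason,
                 chi2 = chi2), class = "rif_fit")
}

#' @export
print.rif_fit <- function(x, ...) {
  cat("RIF kinetic fit:", x$n_points, "points;",
      if (x$excluded) paste0("EXCLUDED (", x$reason, ")") else
        if (x$converged) "converged" else "not converged", "\n")
  if (!is.null(x$params)) {
    p <- x$params
    cat(sprintf("  c = %.4f mGy^-1, alpha = %.3f, k1 = %.3f h^-1, k2 = %.4f h^-1, N0 = %.4f\n",
                p$c, p$alpha, p$k1, p$k2, p$N0))
    if (!is.null(x$se))
      cat("  SE:", paste(sprintf("%s=%.4g", names(x$se), x$se), collapse = ", "), "\n")
    cat(sprintf("  r2 = %.3f, chi2 = %.4g\n", x$r2, x$chi2))
  }
  invisible(x)
}

#' Fit the compartment model to one patient's RIF series
#'
#' Weighted (1/sigma^2) Levenberg-Marquardt estimation of
#' `(c, alpha, k1, k2, N0)` with bounds `c >= 0`, `alpha` in [0, 1],
#' `k1, k2 > 0` and `|N0|` within the uncertainty of the experimental data
#' (the baseline count's propagated sigma). The pre-therapy baseline defines
#' the zero of the RIF scale and enters the fit as the anchor point
#' `(t = 0, N = 0, sigma = sigma0)`; it is counted as a data point, so a
#' patient sampled at all eight post-administration nominal times has nine.
#' A deterministic multi-start grid makes the result seed-free; the canonical
#' ordering `k1 >= k2` is applied afterwards.
#'
#' Exclusion rules: fewer than `min_points` valid points leads to
#' `excluded = TRUE` with reason `"too-few-points"` (no parameters reported);
#' a converged fit whose `c` or `k1` standard error exceeds twice the
#' parameter value is marked `excluded` with reason `"large-errors"` (the
#' parameters are kept for inspection).
#'
#' @param rif A [rif_from_counts()] series (or data.frame with `t`, `N`,
#'   `sigma`).
#' @param pd The patient's [patient_dosimetry()].
#' @param opts [fit_options()].
#' @return A `rif_fit` object.
#' @export
fit_patient <- function(rif, pd, opts = fit_options()) {
  pts <- .fit_points(rif)
  if (nrow(pts) < opts$min_points)
    return(.fit_result(n_points = nrow(pts), excluded = TRUE,
                       reason = "too-few-points"))
  res <- .lm_kinetic(list(list(rif = pts, pd = pd)), opts,
                     n0_bound = .n0_bound(rif, opts))
  if (is.null(res))
    return(.fit_result(n_points = nrow(pts), converged = FALSE,
                       reason = "degenerate"))
  out <- .fit_result(params = res$params, se = res$se, r2 = res$r2,
                     n_points = res$n_points, converged = res$converged,
                     chi2 = res$chi2)
  est <- unlist(res$params[c("c", "alpha", "k1", "k2", "N0")])
  for (nm in opts$se_params) {
    if (is.finite(res$se[[nm]]) && res$se[[nm]] > opts$se_factor * abs(est[[nm]])) {
      out$excluded <- TRUE
      out$reason <- "large-errors"
      break
    }
  }
  if (any(!is.finite(res$se[c("c", "k1")]))) {
    out$excluded <- TRUE
    out$reason <- "large-errors"
  }
  out
}

#' Pooled fit across several patients
#'
#' One shared parameter vector `(c, alpha, k1, k2, N0)` minimising the
#' weighted residual over all patients' RIF points, each point evaluated
#' through its own patient's dosimetry. Used for the group-wise pooled fits
#' after stratifying by `k1`.
#'
#' @param data List with one element per patient, each a list with components
#'   `rif` and `pd`.
#' @param opts [fit_options()]. The minimum-points rule applies to the pooled
#'   point count.
#' @return A `rif_fit`.
#' @export
fit_pooled <- function(data, opts = fit_options()) {
  stopifnot(length(data) >= 1L)
  data <- lapply(data, function(d) list(rif = .fit_points(d$rif), pd = d$pd))
  n <- sum(vapply(data, function(d) nrow(d$rif), 1L))
  if (n < opts$min_points)
    return(.fit_result(n_points = n, excluded = TRUE, reason = "too-few-points"))
  bound <- max(vapply(data, function(d) max(d$rif$sigma), 1))
  res <- .lm_kinetic(data, opts, n0_bound = bound)
  if (is.null(res))
    return(.fit_result(n_points = n, converged = FALSE, reason = "degenerate"))
  .fit_result(params = res$params, se = res$se, r2 = res$r2,
              n_points = res$n_points, converged = res$converged,
              chi2 = res$chi2)
}

#' Simplified single-rate fit (alpha = 1)
#'
#' Refits the model with the fast-pool fraction frozen at 1 so that only one
#' repair rate `k1` acts (`k2` drops out). Comparing its r-squared with the
#' full fit quantifies what the slow component adds.
#'
#' @inheritParams fit_patient
#' @return A `rif_fit` with `alpha = 1`, `k2 = 0` and `NA` standard errors for
#'   the frozen parameters.
#' @export
fit_simplified <- function(rif, pd, opts = fit_options()) {
  pts <- .fit_points(rif)
  if (nrow(pts) < opts$min_points)
    return(.fit_result(n_points = nrow(pts), excluded = TRUE,
                       reason = "too-few-points"))
  res <- .lm_kinetic(list(list(rif = pts, pd = pd)), opts,
                     n0_bound = .n0_bound(rif, opts), fixed_alpha = 1)
  if (is.null(res))
    return(.fit_result(n_points = nrow(pts), converged = FALSE,
                       reason = "degenerate"))
  .fit_result(params = res$params, se = res$se, r2 = res$r2,
              n_points = res$n_points, converged = res$converged,
              chi2 = res$chi2)
}

#' Robustness of a patient fit
#'
#' Re-runs the fit (a) from initial values perturbed by factors of 3 around
#' the converged optimum and (b) on every 8-point subset obtained by dropping
#' one post-administration point (the baseline is never dropped since it is
#' not fit data), and reports the maximum relative variation of each
#' parameter. The effect of dropping the last time point — which anchors the
#' slow rate `k2` — is reported separately.
#'
#' @inheritParams fit_patient
#' @param fit Optional previously computed full fit (recomputed if missing).
#' @return List with `perturbed` (max relative variation per parameter over
#'   perturbed starts), `drop_one` (same, over leave-one-out refits),
#'   `drop_last` (relative change per parameter when the last time point is
#'   dropped) and the refit parameter tables.
#' @export
robustness_check <- function(rif, pd, opts = fit_options(), fit = NULL) {
  if (is.null(fit)) fit <- fit_patient(rif, pd, opts)
  if (is.null(fit$params)) stop_rifkin("robustness check requires a fitted patient")
  ref <- unlist(fit$params[c("c", "alpha", "k1", "k2", "N0")])

  refit_with_starts <- function(o) {
    f <- fit_patient(rif, pd, o)
    if (is.null(f$params)) return(rep(NA_real_, 5))
    unlist(f$params[c("c", "alpha", "k1", "k2", "N0")])
  }

  # (a) starts perturbed around the optimum by x/3 and x3
  fac <- c(1 / 3, 1, 3)
  pert <- list()
  for (f1 in fac) for (f2 in fac) {
    o <- opts
    o$start_c <- ref[["c"]] * f1
    o$start_k1 <- max(ref[["k1"]] * f2, 1e-4)
    o$start_k2 <- max(ref[["k2"]] * f2, 1e-5)
    o$start_alpha <- min(max(ref[["alpha"]], 0.05), 0.95)
    pert[[length(pert) + 1L]] <- refit_with_starts(o)
  }
  pert <- do.call(rbind, pert)

  # (b) drop-one-point refits down to min 8 points
  pts <- .fit_points(rif)
  drops <- list()
  drop_last <- rep(NA_real_, 5)
  o8 <- opts
  o8$min_points <- min(opts$min_points, nrow(pts) - 1L)
  for (i in seq_len(nrow(pts))) {
    sub <- pts[-i, , drop = FALSE]
    attr(sub, "sigma0") <- attr(rif, "sigma0")
    f <- fit_patient(sub, pd, o8)
    v <- if (is.null(f$params)) rep(NA_real_, 5) else
      unlist(f$params[c("c", "alpha", "k1", "k2", "N0")])
    drops[[i]] <- v
    if (i == nrow(pts)) drop_last <- v
  }
  drops <- do.call(rbind, drops)

  rel <- function(m) {
    out <- numeric(5)
    for (j in 1:5) {
      col <- m[, j]; col <- col[is.finite(col)]
      denom <- max(abs(ref[j]), 1e-12)
      out[j] <- if (length(col)) max(abs(col - ref[j])) / denom else NA_real_
    }
    names(out) <- names(ref)
    out
  }
  list(reference = ref,
       perturbed = rel(pert),
       drop_one = rel(drops),
       drop_last = stats::setNames(abs(drop_last - ref) / pmax(abs(ref), 1e-12),
                                   names(ref)),
       perturbed_fits = pert, drop_fits = drops)
}

.linear_fit <- function(x, y, xlab) {
  if (length(x) < 3L) stop_rifkin("linear fit needs at least 3 points")
  if (stats::sd(x) == 0) stop_rifkin("degenerate regressor (constant)")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  r2 <- if (stats::sd(y) == 0) 0 else sm$r.squared
  structure(list(slope = co[2, 1], intercept = co[1, 1],
                 slope_se = co[2, 2], intercept_se = co[1, 2],
                 r2 = r2, n = length(x), regressor = xlab),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("N = (%.4f +/- %.4f) * %s + (%.4f +/- %.4f), r2 = %.3f, n = %d\n",
              x$slope, x$slope_se, x$regressor, x$intercept, x$intercept_se,
              x$r2, x$n))
  invisible(x)
}

#' Linear dose-response of early RIF induction
#'
#' Ordinary least squares of pooled RIF per cell against the absorbed dose to
#' the blood at the sampling time, intended for the early points (t < 6 h)
#' where repair has not yet removed much damage. The slope is an effective
#' induction coefficient in mGy^-1.
#'
#' @param dose Absorbed dose at each point (mGy).
#' @param N RIF per cell at each point.
#' @return A `linear_fit` with slope, intercept, their standard errors and r2.
#' @export
linear_fit_induction <- function(dose, N) .linear_fit(dose, N, "D [mGy]")

#' Linear dependence of late RIF level on the dose rate
#'
#' Ordinary least squares of pooled RIF per cell against the absorbed dose
#' rate, intended for late points (t >= 20 h) where the foci level tracks the
#' quasi-equilibrium between ongoing induction and repair. The slope has units
#' h mGy^-1.
#'
#' @param dose_rate Absorbed dose rate at each point (mGy/h).
#' @param N RIF per cell at each point.
#' @return A `linear_fit`.
#' @export
linear_fit_doserate <- function(dose_rate, N) .linear_fit(dose_rate, N, "dD/dt [mGy/h]")
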