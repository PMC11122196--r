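#' Kinetic parameters of foci induction and repair
#'
#' The linear one-compartment model: foci are induced in proportion to the
#' absorbed dose rate (induction constant `c`, mGy^-1) and disappear by
#' first-order repair. A fraction `alpha` of the induced damage enters a fast
#' pool repaired at rate `k1`, the remainder a slow pool repaired at `k2`;
#' `N0` is a pure intercept absorbing the uncertainty of the baseline count.
#'
#' The labels "fast"/"slow" are made unambiguous by the canonical ordering
#' `k1 >= k2`, enforced here by swapping the rates and relabelling
#' `alpha <- 1 - alpha` when needed.
#'
#' @param c Induction constant (mGy^-1, >= 0).
#' @param alpha Fast-pool fraction in [0, 1].
#' @param k1 Fast repair rate (h^-1, >= 0).
#' @param k2 Slow repair rate (h^-1, >= 0).
#' @param N0 Intercept (foci/cell).
#' @param canonicalize Enforce `k1 >= k2` by swapping (default TRUE).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(c, alpha, k1, k2, N0 = 0, canonicalize = TRUE) {
  check_scalar(c, "c", nonneg = TRUE)
  check_scalar(alpha, "alpha")
  check_scalar(k1, "k1", nonneg = TRUE)
  check_scalar(k2, "k2", nonneg = TRUE)
  check_scalar(N0, "N0")
  if (alpha < 0 || alpha > 1) stop_rifkin("alpha must be in [0, 1]")
  if (canonicalize && k2 > k1) {
    tmp <- k1; k1 <- k2; k2 <- tmp
    alpha <- 1 - alpha
  }
  structure(list(c = c, alpha = alpha, k1 = k1, k2 = k2, N0 = N0),
            class = "kinetic_params")
}

#' Radiation-induced foci per cell from raw counts
#'
#' Converts total focus counts in scored cells to baseline-subtracted
#' radiation-induced foci (RIF) per cell with Poisson-propagated
#' uncertainties:
#' `N = n/m - n_b/m_b`, `sigma = sqrt(n/m^2 + n_b/m_b^2)`.
#' Counts are assumed Poisson; a zero count contributes a floor variance of
#' one count so that no data point receives infinite weight. Negative RIF
#' values are legal (sampling fluctuation below baseline) and are never
#' clipped.
#'
#' @param t Sample times (h), vectorised.
#' @param foci Total co-localising foci counted over all scored cells.
#' @param cells Number of scored cells per sample (nominally 100).
#' @param baseline_foci,baseline_cells The pre-therapy baseline count.
#' @return A data.frame of class `rif_series` with columns `t`, `N`, `sigma`;
#'   attribute `sigma0` carries the baseline's own Poisson uncertainty
#'   (used as the `N0` fit bound).
#' @export
rif_from_counts <- function(t, foci, cells, baseline_foci, baseline_cells) {
  stopifnot(length(t) == length(foci), length(foci) == length(cells))
  if (any(cells < 1) || baseline_cells < 1) stop_rifkin("cells must be >= 1")
  if (any(foci < 0) || baseline_foci < 0) stop_rifkin("counts must be >= 0")
  vb <- max(baseline_foci, 1) / baseline_cells^2
  N <- foci / cells - baseline_foci / baseline_cells
  sigma <- sqrt(pmax(foci, 1) / cells^2 + vb)
  out <- data.frame(t = t, N = N, sigma = sigma)
  class(out) <- c("rif_series", "data.frame")
  attr(out, "sigma0") <- sqrt(vb)
  out
}

# E(k, lam, t) = (exp(-lam t) - exp(-k t)) / (k - lam), with the analytic
# k -> lam limit t * exp(-lam t); uniformly accurate near the degeneracy.
.ee <- function(k, lam, t) {
  x <- (k - lam) * t
  small <- abs(x) < 1e-5
  out <- numeric(length(t))
  if (any(small)) {
    xs <- x[small]
    out[small] <- t[small] * exp(-lam * t[small]) * (1 - xs / 2 + xs^2 / 6)
  }
  if (any(!small)) {
    tb <- t[!small]
    out[!small] <- (exp(-lam * tb) - exp(-k * tb)) / (k - lam)
  }
  out
}

# H(k, t): dose (mGy) delivered on [0, t] filtered through first-order decay
# at rate k — the convolution int_0^t exp(-k (t-s)) dD/ds ds in closed form.
.conv_dose <- function(pd, k, t) {
  co <- pd$coefficients
  r <- .pd_rates(pd)
  beta <- co$dk_beta * (pd$blood$a[1] * .ee(k, r$lam[1], t) +
                          pd$blood$a[2] * .ee(k, r$lam[2], t))
  gam <- co$dk_gamma * pd$wt^(-2 / 3) *
    (pd$wholebody$a[1] * .ee(k, r$mu[1], t) +
       pd$wholebody$a[2] * .ee(k, r$mu[2], t))
  1000 * pd$A0 * (beta + gam)
}

#' Closed-form model of RIF per cell over time
#'
#' Solution of the two-pool compartment model under bi-exponential dosimetry:
#' `N(t) = alpha * c * H(k1, t) + (1 - alpha) * c * H(k2, t) + N0`, where
#' `H(k, t)` is the absorbed dose on `[0, t]` filtered through first-order
#' repair at rate `k` (a sum of exponential-difference terms). Degeneracies
#' `k ~ lam_i` are evaluated by their analytic limits, so the function is
#' smooth in all parameters including `k2 = 0`, where the slow pool simply
#' accumulates `(1 - alpha) * c * D(t)`.
#'
#' @param t Times (h), vectorised.
#' @param params [kinetic_params()].
#' @param pd [patient_dosimetry()] (closed form) or `piecewise_dosimetry`
#'   (delegates to the numerical ODE solver).
#' @return Foci per cell.
#' @export
model_rif <- function(t, params, pd) {
  stopifnot(inherits(params, "kinetic_params"))
  if (inherits(pd, "piecewise_dosimetry")) {
    grid <- sort(unique(c(0, t)))
    tr <- model_rif_ode(grid, params, function(s) dose_rate(pd, s))
    return(tr$N[match(t, grid)])
  }
  with(params,
       alpha * c * .conv_dose(pd, k1, t) +
         (1 - alpha) * c * .conv_dose(pd, k2, t) + N0)
}

#' Numerical ODE reference solution of the compartment model
#'
#' Integrates the two-pool system
#' `dN1/dt = -k1 N1 + alpha * c * dD/dt`,
#' `dN2/dt = -k2 N2 + (1 - alpha) * c * dD/dt`, `N1(0) = N2(0) = 0`,
#' `N = N1 + N2 + N0`, with `lsoda`. Used as the independent oracle for the
#' closed form and as the evaluator for non-exponential (piecewise) dose
#' rates.
#'
#' @param t Output time grid (h), starting at 0 or will be prepended.
#' @param params [kinetic_params()].
#' @param dose_rate_fn Function of time returning the dose rate in mGy/h.
#' @param rtol,atol Solver tolerances.
#' @return data.frame with columns `t`, `N`.
#' @export
model_rif_ode <- function(t, params, dose_rate_fn, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"), is.function(dose_rate_fn))
  grid <- sort(unique(c(0, t)))
  deriv <- function(tt, y, parms) {
    r <- dose_rate_fn(tt)
    list(c(-params$k1 * y[1] + params$alpha * params$c * r,
           -params$k2 * y[2] + (1 - params$alpha) * params$c * r))
  }
  sol <- deSolve::ode(y = c(N1 = 0, N2 = 0), times = grid, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop_rifkin("ODE solver failed to converge (istate ",
                attr(sol, "istate")[1], ")")
  data.frame(t = grid, N = sol[, "N1"] + sol[, "N2"] + params$N0)
}

#' Time and height of the foci maximum
#'
#' Finds the global maximum of `model_rif(t) - N0` on [0, 500 h] by a dense
#' grid bracket refined with golden-section/parabolic search, and also reports
#' the modelled RIF level at 168 h (the last nominal sampling time).
#'
#' @param params [kinetic_params()] with `c > 0`.
#' @param pd [patient_dosimetry()].
#' @param t_upper Upper search limit (h).
#' @return List with `t_max` (h), `N_max` (foci/cell above `N0`) and `N_168`.
#' @export
time_of_max <- function(params, pd, t_upper = 500) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$c <= 0) stop_rifkin("no maximum: c must be > 0")
  f <- function(tt) model_rif(tt, params, pd) - params$N0
  grid <- seq(0, t_upper, length.out = 2001)
  v <- f(grid)
  if (max(v) <= 0) stop_rifkin("no maximum: model is flat or non-positive")
  i <- which.max(v)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-9)
  list(t_max = opt$maximum, N_max = opt$objective,
       N_168 = model_rif(168, params, pd))
}
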