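#' Bi-exponential clearance curve
#'
#' Represents the retention of activity in a compartment as a sum of two
#' exponentials, `f(t) = a1 * exp(-l1 * t) + a2 * exp(-l2 * t)`, where the
#' rates `l` are *biological* clearance constants in h^-1 (physical decay is
#' composed in at evaluation time). For blood the amplitudes are the fraction
#' of the administered activity per millilitre of blood; for the whole body
#' they are dimensionless retention fractions summing to ~1.
#'
#' A negative amplitude is allowed (it encodes an uptake phase) as long as the
#' curve itself stays non-negative.
#'
#' @param a Numeric vector of two amplitudes.
#' @param l Numeric vector of two biological rate constants (h^-1, >= 0).
#' @param l_phys Physical decay constant used for the non-negativity check
#'   (h^-1).
#' @return An object of class `biexp_clearance`.
#' @export
biexp_clearance <- function(a, l, l_phys = 0.00360) {
  if (length(a) != 2L || length(l) != 2L)
    stop_rifkin("a bi-exponential clearance needs exactly two components")
  if (!all(is.finite(a)) || !all(is.finite(l)))
    stop_rifkin("amplitudes and rates must be finite")
  if (any(l < 0)) stop_rifkin("biological rates must be >= 0")
  if (!any(a > 0)) stop_rifkin("at least one amplitude must be > 0")
  if (sum(a) < 0) stop_rifkin("f(0) = sum(a) must be >= 0")
  obj <- structure(list(a = as.numeric(a), l = as.numeric(l)),
                   class = "biexp_clearance")
  grid <- seq(0, 2000, length.out = 401)
  fv <- clearance_value(obj, grid, l_phys)
  if (!all(is.finite(fv)) || any(fv < -1e-12 * max(abs(a))))
    stop_rifkin("decay-inclusive clearance curve must be finite and >= 0 on [0, 2000 h]")
  obj
}

#' Evaluate a decay-inclusive clearance curve
#'
#' @param bc A [biexp_clearance()] object.
#' @param t Times in hours.
#' @param l_phys Physical decay constant (h^-1).
#' @return `sum_i a_i * exp(-(l_i + l_phys) * t)`.
#' @export
clearance_value <- function(bc, t, l_phys = 0.00360) {
  bc$a[1] * exp(-(bc$l[1] + l_phys) * t) + bc$a[2] * exp(-(bc$l[2] + l_phys) * t)
}

#' Absorbed-dose coefficients for blood dosimetry
#'
#' The absorbed dose rate to the blood has a beta self-irradiation term driven
#' by the activity concentration in blood and a photon term driven by the
#' whole-body activity scaled by `wt^(-2/3)`. The two coefficients are
#' instrument- and nuclide-specific inputs (for ^131I they are tabulated in
#' the EANM standard operating procedure on pre-therapeutic blood and bone
#' marrow dosimetry); they are therefore required configuration, with a shipped
#' example config available via [reference_dose_coefficients()].
#'
#' @param dk_beta Blood self-irradiation coefficient (Gy mL GBq^-1 h^-1).
#' @param dk_gamma Whole-body-to-blood photon coefficient
#'   (Gy kg^(2/3) GBq^-1 h^-1).
#' @param l_phys Physical decay constant of the nuclide (h^-1); defaults to
#'   0.00360 h^-1 for ^131I.
#' @return An object of class `dose_coefficients`.
#' @export
dose_coefficients <- function(dk_beta, dk_gamma, l_phys = 0.00360) {
  check_scalar(dk_beta, "dk_beta", positive = TRUE)
  check_scalar(dk_gamma, "dk_gamma", positive = TRUE)
  check_scalar(l_phys, "l_phys", positive = TRUE)
  structure(list(dk_beta = dk_beta, dk_gamma = dk_gamma, l_phys = l_phys),
            class = "dose_coefficients")
}

#' Patient dosimetry model
#'
#' Bundles the administered activity, body weight, fitted blood and whole-body
#' clearance curves and the dose coefficients into the evaluator used by
#' [dose_rate()], [cumulative_dose()] and [total_dose()].
#'
#' @param A0 Administered activity (GBq).
#' @param wt Body weight (kg).
#' @param blood [biexp_clearance()] for the blood (amplitudes per mL).
#' @param wholebody [biexp_clearance()] for the whole body (retention
#'   fractions).
#' @param coefficients [dose_coefficients()].
#' @param check_wb_norm If `TRUE` (default) require the whole-body retention at
#'   t = 0 to lie in [0.9, 1.1]: immediately after administration the whole
#'   body contains essentially all of the activity.
#' @return An object of class `patient_dosimetry`.
#' @export
patient_dosimetry <- function(A0, wt, blood, wholebody, coefficients,
                              check_wb_norm = TRUE) {
  check_scalar(A0, "A0", positive = TRUE)
  check_scalar(wt, "wt", positive = TRUE)
  stopifnot(inherits(blood, "biexp_clearance"),
            inherits(wholebody, "biexp_clearance"),
            inherits(coefficients, "dose_coefficients"))
  if (check_wb_norm) {
    f0 <- sum(wholebody$a)
    if (f0 < 0.9 || f0 > 1.1)
      stop_rifkin(sprintf(
        "whole-body retention at t=0 is %.3f; expected within [0.9, 1.1] (override with check_wb_norm = FALSE)",
        f0))
  }
  structure(list(A0 = A0, wt = wt, blood = blood, wholebody = wholebody,
                 coefficients = coefficients),
            class = "patient_dosimetry")
}

# decay-inclusive rate constants for the two source terms
.pd_rates <- function(pd) {
  lp <- pd$coefficients$l_phys
  list(lam = pd$blood$l + lp, mu = pd$wholebody$l + lp)
}

#' Absorbed dose rate to the blood
#'
#' `dD/dt(t) = A0 * [Dk_beta * f_bl(t) + Dk_gamma * wt^(-2/3) * f_wb(t)]`
#' where `f_bl`, `f_wb` are the decay-inclusive blood (per mL) and whole-body
#' retention curves. Returned in mGy/h.
#'
#' @param pd A `patient_dosimetry` (or piecewise) object.
#' @param t Times in hours (>= 0), vectorised.
#' @return Absorbed dose rate in mGy/h.
#' @export
dose_rate <- function(pd, t) UseMethod("dose_rate")

#' @export
dose_rate.patient_dosimetry <- function(pd, t) {
  if (any(t < 0)) stop_rifkin("t must be >= 0")
  lp <- pd$coefficients$l_phys
  beta <- pd$coefficients$dk_beta * clearance_value(pd$blood, t, lp)
  gam <- pd$coefficients$dk_gamma * pd$wt^(-2 / 3) *
    clearance_value(pd$wholebody, t, lp)
  1000 * pd$A0 * (beta + gam)
}

# (1 - exp(-x)) / x, accurate for small |x|
.phi <- function(x) {
  out <- ifelse(abs(x) < 1e-5,
                1 - x / 2 + x^2 / 6,
                -expm1(-x) / ifelse(x == 0, 1, x))
  out
}

# int_0^t exp(-lam s) ds = t * phi(lam t); handles lam -> 0 analytically
.int_exp <- function(lam, t) t * .phi(lam * t)

#' Cumulative absorbed dose to the blood
#'
#' Closed-form integral of [dose_rate()] on `[0, t]`:
#' `D(t) = A0 * [Dk_beta * sum_i a_i (1 - exp(-lam_i t)) / lam_i + ...]`
#' with `lam_i = l_i + l_phys`. The degenerate `lam -> 0` limit uses the
#' analytic expansion `a * t`, so a component that is never cleared still
#' yields the correct finite-time dose.
#'
#' @inheritParams dose_rate
#' @return Absorbed dose in mGy, non-decreasing in `t`, `D(0) = 0`.
#' @export
cumulative_dose <- function(pd, t) UseMethod("cumulative_dose")

#' @export
cumulative_dose.patient_dosimetry <- function(pd, t) {
  if (any(t < 0)) stop_rifkin("t must be >= 0")
  r <- .pd_rates(pd)
  beta <- pd$coefficients$dk_beta *
    (pd$blood$a[1] * .int_exp(r$lam[1], t) + pd$blood$a[2] * .int_exp(r$lam[2], t))
  gam <- pd$coefficients$dk_gamma * pd$wt^(-2 / 3) *
    (pd$wholebody$a[1] * .int_exp(r$mu[1], t) + pd$wholebody$a[2] * .int_exp(r$mu[2], t))
  1000 * pd$A0 * (beta + gam)
}

#' Total absorbed dose to the blood
#'
#' The `t -> Inf` limit of [cumulative_dose()],
#' `A0 * (Dk_beta * tau_bl + Dk_gamma * wt^(-2/3) * tau_wb)` with the
#' time-integrated activity coefficients `tau = sum_i a_i / lam_i`.
#'
#' @inheritParams dose_rate
#' @return Total absorbed dose in mGy.
#' @export
total_dose <- function(pd) UseMethod("total_dose")

#' @export
total_dose.patient_dosimetry <- function(pd) {
  r <- .pd_rates(pd)
  if (any(r$lam <= 0) || any(r$mu <= 0))
    stop_rifkin("non-convergent TIAC: all decay-inclusive rates must be > 0")
  tau_bl <- sum(pd$blood$a / r$lam)
  tau_wb <- sum(pd$wholebody$a / r$mu)
  1000 * pd$A0 * (pd$coefficients$dk_beta * tau_bl +
                    pd$coefficients$dk_gamma * pd$wt^(-2 / 3) * tau_wb)
}

#' Time-integrated activity coefficients
#'
#' @param pd A `patient_dosimetry` object.
#' @return List with `tau_bl` (h/mL) and `tau_wb` (h).
#' @export
tiac <- function(pd) {
  r <- .pd_rates(pd)
  list(tau_bl = sum(pd$blood$a / r$lam), tau_wb = sum(pd$wholebody$a / r$mu))
}

#' Fit a bi-exponential clearance curve to a time-activity series
#'
#' Measured series are decay-inclusive; the fit estimates decay-inclusive
#' rates and stores biological rates `l_i = rate_i - l_phys`. A fitted rate
#' below `l_phys` implies retention faster than pure physical decay can
#' explain ("super-physical retention"); the biological rate is clamped to 0
#' and a warning is recorded in the diagnostics (and raised as an R warning).
#'
#' Initialisation is a deterministic multi-start: rate pairs are taken from a
#' log-spaced grid, the amplitudes are solved linearly for each pair, and each
#' start is polished by Levenberg-Marquardt; the best residual sum of squares
#' wins. No random numbers are used.
#'
#' @param t Sample times (h), strictly increasing, at least 5.
#' @param value Measured decay-inclusive values (blood: GBq/mL; whole body:
#'   retention fraction).
#' @param A0 Administered activity used to normalise blood series to fraction
#'   of administered activity per mL. Use `A0 = 1` for already-normalised
#'   series such as whole-body retention fractions.
#' @param sigma Optional measurement uncertainties (same units as `value`);
#'   used as `1/sigma^2` weights when `weighted = TRUE`.
#' @param weighted Logical; default `FALSE` (unweighted least squares).
#' @param l_phys Physical decay constant (h^-1).
#' @return A [biexp_clearance()] with attributes `r2`, `rss`, `se`
#'   (approximate parameter standard errors) and `clamped` (logical).
#' @export
fit_biexponential <- function(t, value, A0 = 1, sigma = NULL, weighted = FALSE,
                              l_phys = 0.00360) {
  stopifnot(is.numeric(t), is.numeric(value), length(t) == length(value))
  if (length(t) < 5L) stop_rifkin("bi-exponential fit needs at least 5 samples")
  if (any(diff(t) <= 0)) stop_rifkin("sample times must be strictly increasing")
  if (!all(is.finite(value))) stop_rifkin("values must be finite")
  y <- value / A0
  w <- rep(1, length(y))
  if (weighted) {
    if (is.null(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
      stop_rifkin("weighted fit requires positive finite sigma")
    w <- (A0 / sigma)^2
  }

  # model in decay-inclusive rates r1 > r2 >= 0
  fx <- function(p, tt) p[1] * exp(-p[3] * tt) + p[2] * exp(-p[4] * tt)
  resid_fn <- function(p) sqrt(w) * (y - fx(p, t))

  # deterministic multi-start: log-spaced decay-inclusive rate grid
  rates <- exp(seq(log(2e-3), log(2), length.out = 7))
  starts <- list()
  for (i in seq_along(rates)) for (j in seq_along(rates)) {
    if (rates[i] <= rates[j]) next
    X <- cbind(exp(-rates[i] * t), exp(-rates[j] * t))
    amp <- tryCatch(stats::lsfit(X, y, wt = w, intercept = FALSE)$coefficients,
                    error = function(e) NULL)
    if (is.null(amp) || any(!is.finite(amp))) next
    starts[[length(starts) + 1L]] <- c(amp, rates[i], rates[j])
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = c(-Inf, -Inf, 0, 0),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15 * (1 + best$rss)) {
      best <- list(par = fit$par, rss = rss, fit = fit)
    }
  }
  if (is.null(best)) stop_rifkin("bi-exponential fit failed from every start")

  p <- best$par
  # order components: fast rate first
  if (p[3] < p[4]) p <- p[c(2, 1, 4, 3)]
  clamped <- FALSE
  l_bio <- p[3:4] - l_phys
  if (any(l_bio < 0)) {
    neg <- which(l_bio < 0)
    # warn only when the offending component actually carries amplitude;
    # a degenerate (near-zero) second component is a legitimate nested fit
    material <- abs(p[neg]) > 1e-8 * max(abs(p[1:2]))
    if (any(l_bio[neg] < -1e-10 & material)) {
      clamped <- TRUE
      warning("super-physical retention: fitted decay-inclusive rate below l_phys; biological rate clamped to 0")
    }
    l_bio[neg] <- 0
  }
  out <- biexp_clearance(a = p[1:2], l = l_bio, l_phys = l_phys)

  ybar <- stats::weighted.mean(y, w)
  sstot <- sum(w * (y - ybar)^2)
  r2 <- if (sstot > 0) 1 - best$rss / sstot else NA_real_
  se <- rep(NA_real_, 4)
  hv <- tryCatch(solve(best$fit$hessian), error = function(e) NULL)
  dof <- length(y) - 4L
  if (!is.null(hv) && dof > 0)
    se <- sqrt(pmax(diag(hv), 0) * best$rss / dof)
  attr(out, "r2") <- r2
  attr(out, "rss") <- best$rss
  attr(out, "se") <- se
  attr(out, "clamped") <- clamped
  out
}

#' Piecewise dose evaluator for re-uptake curves
#'
#' Some patients show a renewed rise in blood activity late after
#' administration, which a bi-exponential cannot represent. This evaluator
#' uses the bi-exponential fit of the blood curve only up to a breakpoint and
#' completes the time-activity curve section by section afterwards: linear
#' interpolation (trapezoidal integration) through the measured values, then a
#' pure physical-decay tail beyond the last sample. The whole-body photon term
#' is taken from the template dosimetry throughout. Cumulative dose is
#' continuous at the breakpoint.
#'
#' @param pd Template [patient_dosimetry()] fitted over the full range (its
#'   blood part is used before the breakpoint).
#' @param t Blood sample times (h).
#' @param value Measured decay-inclusive blood activity concentrations
#'   (GBq/mL), normalised internally by `pd$A0`.
#' @param breakpoint One of the sample times; must leave >= 2 samples after it.
#' @return An object of class `piecewise_dosimetry` supporting [dose_rate()],
#'   [cumulative_dose()] and [total_dose()].
#' @export
piecewise_tiac <- function(pd, t, value, breakpoint) {
  stopifnot(inherits(pd, "patient_dosimetry"))
  if (!any(abs(t - breakpoint) < 1e-9))
    stop_rifkin("breakpoint must be one of the sample times")
  if (breakpoint >= max(t)) stop_rifkin("breakpoint beyond last sample")
  if (sum(t > breakpoint + 1e-9) < 2L)
    stop_rifkin("need at least 2 samples after the breakpoint")
  keep <- t >= breakpoint - 1e-9
  ts <- t[keep]
  # normalised fraction of administered activity per mL, decay-inclusive;
  # the measured value at the breakpoint starts the trapezoid section, so the
  # cumulative dose is continuous there (the dose *rate* may step by the fit
  # residual at the breakpoint sample)
  fs <- value[keep] / pd$A0
  structure(list(pd = pd, bp = breakpoint, ts = ts, fs = fs,
                 lp = pd$coefficients$l_phys),
            class = c("piecewise_dosimetry"))
}

# measured-section blood curve (fraction/mL, decay-inclusive)
.pw_blood <- function(pw, t) {
  out <- numeric(length(t))
  pre <- t < pw$bp
  out[pre] <- clearance_value(pw$pd$blood, t[pre], pw$lp)
  mid <- t >= pw$bp & t <= max(pw$ts)
  out[mid] <- stats::approx(pw$ts, pw$fs, xout = t[mid])$y
  post <- t > max(pw$ts)
  out[post] <- pw$fs[length(pw$fs)] * exp(-pw$lp * (t[post] - max(pw$ts)))
  out
}

#' @export
dose_rate.piecewise_dosimetry <- function(pd, t) {
  if (any(t < 0)) stop_rifkin("t must be >= 0")
  pw <- pd
  co <- pw$pd$coefficients
  beta <- co$dk_beta * .pw_blood(pw, t)
  gam <- co$dk_gamma * pw$pd$wt^(-2 / 3) *
    clearance_value(pw$pd$wholebody, t, co$l_phys)
  1000 * pw$pd$A0 * (beta + gam)
}

#' @export
cumulative_dose.piecewise_dosimetry <- function(pd, t) {
  pw <- pd
  co <- pw$pd$coefficients
  vapply(t, function(tt) {
    if (tt < 0) stop_rifkin("t must be >= 0")
    # gamma term: closed form all the way
    gam <- co$dk_gamma * pw$pd$wt^(-2 / 3) *
      (pw$pd$wholebody$a[1] * .int_exp(pw$pd$wholebody$l[1] + co$l_phys, tt) +
       pw$pd$wholebody$a[2] * .int_exp(pw$pd$wholebody$l[2] + co$l_phys, tt))
    # beta term, piecewise
    r <- pw$pd$blood$l + co$l_phys
    t1 <- min(tt, pw$bp)
    beta <- pw$pd$blood$a[1] * .int_exp(r[1], t1) +
      pw$pd$blood$a[2] * .int_exp(r[2], t1)
    if (tt > pw$bp) {
      tl <- max(pw$ts)
      t2 <- min(tt, tl)
      # trapezoid over the measured section up to t2
      gr <- sort(unique(c(pw$ts[pw$ts <= t2 + 1e-12], t2)))
      fg <- .pw_blood(pw, gr)
      beta <- beta + sum(diff(gr) * (utils::head(fg, -1) + utils::tail(fg, -1)) / 2)
      if (tt > tl) {
        f_last <- pw$fs[length(pw$fs)]
        beta <- beta + f_last * .int_exp(pw$lp, tt - tl)
      }
    }
    1000 * pw$pd$A0 * (co$dk_beta * beta + gam)
  }, numeric(1))
}

#' @export
total_dose.piecewise_dosimetry <- function(pd) {
  pw <- pd
  co <- pw$pd$coefficients
  tl <- max(pw$ts)
  f_last <- pw$fs[length(pw$fs)]
  base <- cumulative_dose(pw, tl)
  tail_beta <- 1000 * pw$pd$A0 * co$dk_beta * f_last / pw$lp
  mu <- pw$pd$wholebody$l + co$l_phys
  gam_tail <- 1000 * pw$pd$A0 * co$dk_gamma * pw$pd$wt^(-2 / 3) *
    sum(pw$pd$wholebody$a * exp(-mu * tl) / mu)
  base + tail_beta + gam_tail
}
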