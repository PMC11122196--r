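#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the design of a radioiodine-therapy biodosimetry
#' study: ~3.5 GBq administered activity, blood sampling at the nominal times
#' 1/2/3/4/24/48/96/168 h plus a pre-therapy baseline, 100 scored cells per
#' sample, Poisson-distributed focus counts, bi-exponential blood and
#' whole-body clearance tuned so total blood doses fall in the 200-600 mGy
#' band, and a bimodal fast repair rate (slow mode ~0.35 h^-1, fast mode
#' ~1.3 h^-1) so that group-recovery analyses have real structure.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param nominal_times Post-administration sampling grid (h).
#' @param wb_times Whole-body retention measurement times (h).
#' @param cells_per_sample Scored cells per sample.
#' @param baseline_range Uniform range of the pre-therapy baseline focus rate
#'   (foci/cell).
#' @param a0_range Administered activity range (GBq).
#' @param wt_range Body weight range (kg).
#' @param c_slow,c_fast Induction-constant ranges (mGy^-1) for the slow- and
#'   fast-repair groups.
#' @param k1_slow,k1_fast Fast-repair-rate ranges (h^-1) of the two modes.
#' @param k2_slow,k2_fast Slow-repair-rate ranges (h^-1).
#' @param alpha_range Fast-pool fraction range.
#' @param n0_true True intercept (default 0: the intercept is a fit nuisance).
#' @param prop_fast Probability that a patient belongs to the fast-repair
#'   group (default 6/14, the observed proportion).
#' @param a1_bl,a2_bl,l1_bl,l2_bl Blood clearance amplitude (fraction of
#'   administered activity per mL) and biological rate (h^-1) ranges.
#' @param u_wb,l1_wb,l2_wb Whole-body fast-fraction and rate ranges; the two
#'   amplitudes are `u` and `1 - u` so retention starts at 1.
#' @param dose_band Accepted total-blood-dose band (mGy); clearance parameters
#'   are rejected and resampled until the total dose falls inside.
#' @param missing_prob Per-nominal-time probability that the blood/foci sample
#'   is missing (defaults mirror the observed missingness: occasional losses
#'   early, ~1/3 at 96 h).
#' @param activity_cv Relative measurement noise on activity samples.
#' @param dk_beta,dk_gamma,l_phys Dose coefficients (defaults: the standard
#'   blood-dosimetry values for ^131I).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 18L,
                             seed = 1L,
                             nominal_times = c(1, 2, 3, 4, 24, 48, 96, 168),
                             wb_times = c(4, 24, 48, 72, 96, 168),
                             cells_per_sample = 100L,
                             baseline_range = c(0.05, 0.3),
                             a0_range = c(3.43, 3.91),
                             wt_range = c(46, 115),
                             c_slow = c(0.012, 0.028),
                             c_fast = c(0.044, 0.071),
                             k1_slow = c(0.19, 0.56),
                             k1_fast = c(1.14, 1.55),
                             k2_slow = c(0.000, 0.018),
                             k2_fast = c(0.006, 0.044),
                             alpha_range = c(0.92, 0.99),
                             n0_true = 0,
                             prop_fast = 6 / 14,
                             a1_bl = c(1.0e-05, 2.0e-05),
                             a2_bl = c(0.4e-05, 1.0e-05),
                             l1_bl = c(0.06, 0.14),
                             l2_bl = c(0.008, 0.016),
                             u_wb = c(0.65, 0.85),
                             l1_wb = c(0.05, 0.09),
                             l2_wb = c(0.004, 0.009),
                             dose_band = c(200, 600),
                             missing_prob = c(`1` = 0, `2` = 1 / 18, `3` = 1 / 18,
                                              `4` = 0, `24` = 0, `48` = 0,
                                              `96` = 1 / 3, `168` = 1 / 18),
                             activity_cv = 0.02,
                             dk_beta = 108,
                             dk_gamma = 0.0188,
                             l_phys = 0.00360) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1, all(missing_prob >= 0 & missing_prob <= 1),
            dose_band[1] < dose_band[2])
  class(cfg) <- "generator_config"
  cfg
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

# draw clearance parameters, rejecting until the total dose is in band
.draw_dosimetry <- function(cfg, co) {
  A0 <- runif1(cfg$a0_range)
  wt <- runif1(cfg$wt_range)
  for (i in seq_len(10000L)) {
    bl <- biexp_clearance(a = c(runif1(cfg$a1_bl), runif1(cfg$a2_bl)),
                          l = c(runif1(cfg$l1_bl), runif1(cfg$l2_bl)),
                          l_phys = cfg$l_phys)
    u <- runif1(cfg$u_wb)
    wb <- biexp_clearance(a = c(u, 1 - u),
                          l = c(runif1(cfg$l1_wb), runif1(cfg$l2_wb)),
                          l_phys = cfg$l_phys)
    pd <- patient_dosimetry(A0, wt, bl, wb, co)
    td <- total_dose(pd)
    if (td >= cfg$dose_band[1] && td <= cfg$dose_band[2]) return(pd)
  }
  stop_rifkin("could not reach the configured total-dose band after 10000 draws")
}

#' Generate a synthetic patient cohort with ground truth
#'
#' For each patient: draw the repair group, kinetic truth and clearance
#' parameters (resampled until the total blood dose is inside the configured
#' band); compute the expected foci per cell at each nominal time as
#' `baseline_rate + max(model_rif(t), 0)`; draw Poisson counts with
#' `cells_per_sample` cells; apply the missing-sample mask; and emit noisy
#' blood/whole-body activity samples for the dosimetry stage. Fully
#' reproducible from `cfg$seed`; the caller's RNG state is untouched.
#'
#' @param cfg A [generator_config()].
#' @return List of class `synthetic_cohort`; each element has `record`
#'   (id, age, weight, A0), `pd` (true dosimetry), `truth` (kinetic
#'   parameters, group, baseline rate), `counts` (t, foci, cells,
#'   is_baseline), `blood` and `wholebody` activity samples.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  co <- dose_coefficients(cfg$dk_beta, cfg$dk_gamma, cfg$l_phys)
  with_local_seed(cfg$seed, {
    patients <- lapply(seq_len(cfg$n_patients), function(i) {
      id <- sprintf("SP%02d", i)
      pd <- .draw_dosimetry(cfg, co)
      fast <- stats::runif(1) < cfg$prop_fast
      truth <- kinetic_params(
        c = runif1(if (fast) cfg$c_fast else cfg$c_slow),
        alpha = runif1(cfg$alpha_range),
        k1 = runif1(if (fast) cfg$k1_fast else cfg$k1_slow),
        k2 = runif1(if (fast) cfg$k2_fast else cfg$k2_slow),
        N0 = cfg$n0_true)
      base_rate <- runif1(cfg$baseline_range)
      age <- stats::runif(1, 19, 66)

      tt <- cfg$nominal_times
      keep <- stats::runif(length(tt)) >=
        cfg$missing_prob[match(as.character(tt), names(cfg$missing_prob))]
      keep[is.na(keep)] <- TRUE
      tt <- tt[keep]

      mu <- base_rate + pmax(model_rif(tt, truth, pd) - truth$N0, -base_rate) +
        truth$N0
      mu <- pmax(mu, 0)  # Poisson expectation floor (logged via attribute)
      foci <- stats::rpois(length(tt), cfg$cells_per_sample * mu)
      base_foci <- stats::rpois(1, cfg$cells_per_sample * base_rate)
      counts <- data.frame(
        t = c(0, tt),
        foci = c(base_foci, foci),
        cells = cfg$cells_per_sample,
        is_baseline = c(1L, rep(0L, length(tt))))

      lp <- cfg$l_phys
      bl_t <- tt[tt > 0]
      blood <- data.frame(
        t = bl_t,
        value = clearance_value(pd$blood, bl_t, lp) * pd$A0 *
          exp(stats::rnorm(length(bl_t), 0, cfg$activity_cv)),
        sigma = NA_real_)
      blood$sigma <- pmax(blood$value * cfg$activity_cv, 1e-12)
      wb_t <- cfg$wb_times
      wholebody <- data.frame(
        t = wb_t,
        value = clearance_value(pd$wholebody, wb_t, lp) *
          exp(stats::rnorm(length(wb_t), 0, cfg$activity_cv)),
        sigma = NA_real_)
      wholebody$sigma <- pmax(wholebody$value * cfg$activity_cv, 1e-12)

      list(record = list(patient_id = id, age = age, weight = pd$wt,
                         A0 = pd$A0),
           pd = pd, truth = truth,
           group = if (fast) "2" else "1",
           baseline_rate = base_rate,
           counts = counts, blood = blood, wholebody = wholebody)
    })
    structure(patients, class = "synthetic_cohort", config = cfg)
  })
}

#' Flatten a synthetic cohort into the pipeline input tables
#'
#' Produces the four input tables consumed by [run_pipeline()] plus a `truth`
#' table for recovery scoring. When `dir` is given the tables are also written
#' as CSV files (`patients.csv`, `blood_activity.csv`,
#' `wholebody_retention.csv`, `foci_counts.csv`, `truth.csv`); the truth file
#' is never read by the pipeline.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Optional output directory.
#' @return Named list of data.frames `patients`, `blood`, `wholebody`, `foci`,
#'   `truth`.
#' @export
cohort_to_tables <- function(cohort, dir = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  patients <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$record$patient_id, age_y = p$record$age,
               weight_kg = p$record$weight, a0_gbq = p$record$A0)))
  blood <- do.call(rbind, lapply(cohort, function(p)
    cbind(patient_id = p$record$patient_id,
          stats::setNames(p$blood, c("t_h", "activity_gbq_per_ml", "sigma")))))
  wholebody <- do.call(rbind, lapply(cohort, function(p)
    cbind(patient_id = p$record$patient_id,
          stats::setNames(p$wholebody, c("t_h", "retention_fraction", "sigma")))))
  foci <- do.call(rbind, lapply(cohort, function(p)
    cbind(patient_id = p$record$patient_id,
          stats::setNames(p$counts, c("t_h", "foci_total", "cells", "is_baseline")))))
  truth <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$record$patient_id,
               c = p$truth$c, alpha = p$truth$alpha, k1 = p$truth$k1,
               k2 = p$truth$k2, n0 = p$truth$N0, group = p$group,
               baseline_rate = p$baseline_rate,
               total_dose_mgy = total_dose(p$pd))))
  out <- list(patients = patients, blood = blood, wholebody = wholebody,
              foci = foci, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(patients = "patients.csv", blood = "blood_activity.csv",
               wholebody = "wholebody_retention.csv", foci = "foci_counts.csv",
               truth = "truth.csv")
    for (nm in names(files))
      utils::write.csv(out[[nm]], file.path(dir, files[[nm]]), row.names = FALSE)
  }
  out
}

#' Cohort medians of dose, dose rate and RIF on the nominal schedule
#'
#' Computes, for each nominal time point, the cohort median (and range) of the
#' cumulative absorbed dose, the absorbed dose rate and the observed RIF per
#' cell — the standard summary table used to check that a generated cohort
#' matches the scale of a therapy cohort (doses increase with time, dose rates
#' decrease).
#'
#' @param cohort A [generate_cohort()] result (may be empty).
#' @param times Nominal times (h); defaults to the generator schedule.
#' @return data.frame with one row per time point.
#' @export
replay_nominal_schedule <- function(cohort,
                                    times = c(1, 2, 3, 4, 24, 48, 96, 168)) {
  if (length(cohort) == 0)
    return(data.frame(t = numeric(), dose_median = numeric(),
                      dose_rate_median = numeric(), rif_median = numeric(),
                      n = integer()))
  rows <- lapply(times, function(tt) {
    doses <- vapply(cohort, function(p) cumulative_dose(p$pd, tt), 1)
    rates <- vapply(cohort, function(p) dose_rate(p$pd, tt), 1)
    rifs <- unlist(lapply(cohort, function(p) {
      base <- p$counts[p$counts$is_baseline == 1L, ]
      row <- p$counts[p$counts$is_baseline == 0L & abs(p$counts$t - tt) < 1e-9, ]
      if (!nrow(row)) return(NULL)
      row$foci / row$cells - base$foci / base$cells
    }))
    data.frame(t = tt, dose_median = stats::median(doses),
               dose_rate_median = stats::median(rates),
               rif_median = if (length(rifs)) stats::median(rifs) else NA_real_,
               n = length(rifs))
  })
  out <- do.call(rbind, rows)
  tot <- vapply(cohort, function(p) total_dose(p$pd), 1)
  attr(out, "total_dose_median") <- stats::median(tot)
  attr(out, "total_dose_range") <- range(tot)
  out
}
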