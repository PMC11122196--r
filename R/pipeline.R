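#' Read the example dose-coefficient configuration
#'
#' Loads the shipped YAML config with the standard ^131I blood-dosimetry
#' coefficients (blood self-irradiation 108 Gy mL GBq^-1 h^-1, whole-body
#' photon term 0.0188 Gy kg^(2/3) GBq^-1 h^-1, physical decay 0.00360 h^-1).
#'
#' @param path Optional path to a YAML file with fields `dk_beta`, `dk_gamma`,
#'   `l_phys`; defaults to the packaged example.
#' @return A [dose_coefficients()] object.
#' @export
reference_dose_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dose_coefficients.yaml", package = "rifkin")
  cfg <- yaml::read_yaml(path)
  dose_coefficients(cfg$dk_beta, cfg$dk_gamma, cfg$l_phys)
}

#' Reference cohort tables
#'
#' `reference_fit_params()` returns the published per-patient kinetic fit
#' parameters of an 18-patient radioiodine-therapy reference cohort (the 14
#' patients with a successful fit; `k2` is missing for the one patient whose
#' damage was entirely fast-repaired), including standard errors, r-squared,
#' point counts, the k1-based group label and the ex vivo repair rate `R`.
#' `reference_clinical()` returns the matching demographic table for all 18
#' patients. These tables drive the regression tests of the cohort statistics
#' and the clustering analysis.
#'
#' @return data.frame.
#' @export
reference_fit_params <- function() {
  utils::read.csv(system.file("extdata", "cohort_fit_params.csv",
                              package = "rifkin"))
}

#' @rdname reference_fit_params
#' @export
reference_clinical <- function() {
  utils::read.csv(system.file("extdata", "cohort_clinical.csv",
                              package = "rifkin"))
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_rifkin(sprintf("%s is missing required column(s): %s", what,
                        paste(miss, collapse = ", ")))
  invisible(df)
}

#' Run the full analysis pipeline
#'
#' Executes the stages dosimetry (bi-exponential fits of the blood and
#' whole-body time-activity tables, TIACs, dose table) -> RIF preprocessing
#' (baseline subtraction with Poisson error propagation) -> per-patient
#' kinetic fits with exclusion rules -> k1 grouping and pooled group fits ->
#' pooled linear dose/dose-rate fits -> cohort statistics. Per-patient fit
#' failures are recorded in the output, not fatal.
#'
#' @param tables Named list of data.frames as produced by [cohort_to_tables()]
#'   (`patients`, `blood`, `wholebody`, `foci`), or a directory containing the
#'   corresponding CSV files.
#' @param coefficients [dose_coefficients()].
#' @param opts [fit_options()].
#' @param out_dir Optional directory; when given, writes `dosimetry.csv`,
#'   `fits.csv`, `pooled_fits.csv`, `linear_fits.csv`, `cohort_stats.json` and
#'   `summary.json`.
#' @param group_thresholds Length-2 numeric, the k1 gap boundaries.
#' @return List with `dosimetry`, `rif`, `fits` (data.frame),
#'   `fit_objects`, `groups`, `pooled`, `linear`, `stats`, `summary`.
#' @export
run_pipeline <- function(tables, coefficients, opts = fit_options(),
                         out_dir = NULL, group_thresholds = c(0.6, 1.1)) {
  if (is.character(tables)) {
    dir <- tables
    rd <- function(f) utils::read.csv(file.path(dir, f))
    tables <- list(patients = rd("patients.csv"),
                   blood = rd("blood_activity.csv"),
                   wholebody = rd("wholebody_retention.csv"),
                   foci = rd("foci_counts.csv"))
  }
  .require_cols(tables$patients, c("patient_id", "weight_kg", "a0_gbq"), "patients")
  .require_cols(tables$blood, c("patient_id", "t_h", "activity_gbq_per_ml"), "blood")
  .require_cols(tables$wholebody, c("patient_id", "t_h", "retention_fraction"),
                "wholebody")
  .require_cols(tables$foci, c("patient_id", "t_h", "foci_total", "cells",
                               "is_baseline"), "foci")

  ids <- tables$patients$patient_id
  pds <- list(); rifs <- list(); fit_objects <- list()
  dosim_rows <- list(); fit_rows <- list()

  for (id in ids) {
    rec <- tables$patients[tables$patients$patient_id == id, ][1, ]
    bl <- tables$blood[tables$blood$patient_id == id, ]
    wb <- tables$wholebody[tables$wholebody$patient_id == id, ]
    fc <- tables$foci[tables$foci$patient_id == id, ]
    pd <- NULL
    err <- NA_character_
    pd <- tryCatch({
      blood_fit <- fit_biexponential(bl$t_h, bl$activity_gbq_per_ml,
                                     A0 = rec$a0_gbq,
                                     l_phys = coefficients$l_phys)
      wb_fit <- fit_biexponential(wb$t_h, wb$retention_fraction, A0 = 1,
                                  l_phys = coefficients$l_phys)
      patient_dosimetry(rec$a0_gbq, rec$weight_kg, blood_fit, wb_fit,
                        coefficients)
    }, error = function(e) {
      err <<- conditionMessage(e)
      NULL
    })
    if (is.null(pd)) {
      warning(sprintf("dosimetry failed for %s: %s", id, err))
      next
    }
    pds[[id]] <- pd
    tc <- tiac(pd)
    dosim_rows[[id]] <- data.frame(
      patient_id = id,
      a1_bl = pd$blood$a[1], a2_bl = pd$blood$a[2],
      l1_bl = pd$blood$l[1], l2_bl = pd$blood$l[2],
      a1_wb = pd$wholebody$a[1], a2_wb = pd$wholebody$a[2],
      l1_wb = pd$wholebody$l[1], l2_wb = pd$wholebody$l[2],
      tau_bl = tc$tau_bl, tau_wb = tc$tau_wb,
      dose_24h = cumulative_dose(pd, 24), dose_168h = cumulative_dose(pd, 168),
      total_dose = total_dose(pd))

    base <- fc[fc$is_baseline == 1L, ][1, ]
    post <- fc[fc$is_baseline == 0L, ]
    rif <- rif_from_counts(post$t_h, post$foci_total, post$cells,
                           base$foci_total, base$cells)
    rifs[[id]] <- rif
    fit <- fit_patient(rif, pd, opts)
    fit_objects[[id]] <- fit
    p <- fit$params
    fit_rows[[id]] <- data.frame(
      patient_id = id,
      c = if (is.null(p)) NA_real_ else p$c,
      alpha = if (is.null(p)) NA_real_ else p$alpha,
      k1 = if (is.null(p)) NA_real_ else p$k1,
      k2 = if (is.null(p)) NA_real_ else p$k2,
      n0 = if (is.null(p)) NA_real_ else p$N0,
      se_c = if (is.null(fit$se)) NA_real_ else fit$se[["c"]],
      se_alpha = if (is.null(fit$se)) NA_real_ else fit$se[["alpha"]],
      se_k1 = if (is.null(fit$se)) NA_real_ else fit$se[["k1"]],
      se_k2 = if (is.null(fit$se)) NA_real_ else fit$se[["k2"]],
      se_n0 = if (is.null(fit$se)) NA_real_ else fit$se[["N0"]],
      r2 = fit$r2, n_points = fit$n_points,
      excluded = fit$excluded, reason = fit$reason)
  }

  fits <- do.call(rbind, fit_rows)
  dosimetry <- do.call(rbind, dosim_rows)
  rownames(fits) <- rownames(dosimetry) <- NULL

  ok <- !fits$excluded & !is.na(fits$k1)
  fits$group <- NA_character_
  fits$group[ok] <- group_by_k1(fits$k1[ok], group_thresholds[1],
                                group_thresholds[2])

  pooled <- list()
  for (g in c("1", "2")) {
    gids <- fits$patient_id[ok & fits$group %in% g]
    if (length(gids) >= 2) {
      pooled[[g]] <- fit_pooled(lapply(gids, function(id)
        list(rif = rifs[[id]], pd = pds[[id]])), opts)
    }
  }

  # pooled linear fits: early points vs dose, late points vs dose rate
  pts <- do.call(rbind, lapply(names(rifs), function(id) {
    r <- rifs[[id]]
    data.frame(patient_id = id, t = r$t, N = r$N,
               dose = cumulative_dose(pds[[id]], r$t),
               rate = dose_rate(pds[[id]], r$t))
  }))
  early <- pts[pts$t < 6, ]
  late <- pts[pts$t >= 20, ]
  linear <- list(
    induction = if (nrow(early) >= 3) linear_fit_induction(early$dose, early$N) else NULL,
    doserate = if (nrow(late) >= 3) linear_fit_doserate(late$rate, late$N) else NULL)

  cohort <- fits[ok, c("patient_id", "c", "k1", "k2")]
  if ("age_y" %in% names(tables$patients))
    cohort$age <- tables$patients$age_y[match(cohort$patient_id,
                                              tables$patients$patient_id)]
  if ("ex_vivo_R" %in% names(tables$patients))
    cohort$R <- tables$patients$ex_vivo_R[match(cohort$patient_id,
                                                tables$patients$patient_id)]
  stats_df <- if (sum(ok) >= 4) correlation_battery(cohort) else NULL
  summary_rec <- summarize_cohort(fits[ok, ])

  res <- list(dosimetry = dosimetry, rif = rifs, fits = fits,
              fit_objects = fit_objects, pooled = pooled, linear = linear,
              stats = stats_df, summary = summary_rec, points = pts)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(dosimetry, file.path(out_dir, "dosimetry.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    pooled_df <- do.call(rbind, lapply(names(pooled), function(g) {
      p <- pooled[[g]]$params
      data.frame(group = g, c = p$c, alpha = p$alpha, k1 = p$k1, k2 = p$k2,
                 n0 = p$N0, r2 = pooled[[g]]$r2,
                 n_points = pooled[[g]]$n_points)
    }))
    if (!is.null(pooled_df))
      utils::write.csv(pooled_df, file.path(out_dir, "pooled_fits.csv"),
                       row.names = FALSE)
    lin_df <- do.call(rbind, lapply(names(linear), function(nm) {
      l <- linear[[nm]]
      if (is.null(l)) return(NULL)
      data.frame(fit = nm, slope = l$slope, slope_se = l$slope_se,
                 intercept = l$intercept, intercept_se = l$intercept_se,
                 r2 = l$r2, n = l$n)
    }))
    if (!is.null(lin_df))
      utils::write.csv(lin_df, file.path(out_dir, "linear_fits.csv"),
                       row.names = FALSE)
    if (!is.null(stats_df))
      jsonlite::write_json(stats_df, file.path(out_dir, "cohort_stats.json"),
                           dataframe = "rows", digits = NA)
    jsonlite::write_json(lapply(summary_rec, function(x)
      if (is.table(x)) as.list(x) else x),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Recompute the reference cohort statistics
#'
#' Reruns the cohort-level analysis on the shipped reference fit-parameter and
#' clinical tables: parameter summaries, the Spearman correlation panel, the
#' k-means clustering of `(k1, k2, c)` on the 12 patients with complete
#' parameters after outlier removal, and the k2 group comparison. Returns the
#' computed values alongside the published ones with a pass/fail flag.
#'
#' @param tol_r Tolerance on correlation coefficients (printed precision).
#' @return data.frame with columns `quantity`, `computed`, `published`, `pass`.
#' @export
reproduce_tables <- function(tol_r = 5e-4) {
  fits <- reference_fit_params()
  clin <- reference_clinical()
  fits$age <- clin$age_y[match(fits$patient_id, clin$patient_id)]

  out <- list()
  add <- function(q, comp, pub, tol) {
    out[[length(out) + 1L]] <<- data.frame(
      quantity = q, computed = comp, published = pub,
      pass = abs(comp - pub) <= tol)
  }
  sm <- summarize_cohort(fits)
  add("median c [mGy^-1]", sm$c[["median"]], 0.026, 5e-4)
  add("mean alpha [%]", sm$alpha_percent[["mean"]], 96, 0.5)
  add("mean N0", sm$N0[["mean"]], -0.018, 5e-4)
  add("min k1", sm$k1[["min"]], 0.193, 5e-4)
  add("max k1", sm$k1[["max"]], 3.028, 5e-4)

  sp <- function(a, b) correlate(fits[[a]], fits[[b]], method = "spearman")$estimate
  add("spearman(k1, c)", sp("k1", "c"), 0.947, tol_r)
  add("spearman(k1, k2)", sp("k1", "k2"), 0.661, tol_r)
  add("spearman(k2, c)", sp("k2", "c"), 0.616, tol_r)
  add("spearman(age, k1)", sp("age", "k1"), -0.541, tol_r)
  add("spearman(age, k2)", sp("age", "k2"), -0.615, tol_r)
  add("spearman(age, c)", sp("age", "c"), -0.624, tol_r)

  outliers <- detect_outliers(fits)
  km <- kmeans_params(fits, k = 2, exclude = outliers)
  add("kmeans centroid k1 (slow)", km$centers[1, "k1"], 0.37429, 5e-5)
  add("kmeans centroid c (slow)", km$centers[1, "c"], 0.02143, 5e-5)
  add("kmeans centroid k2 (slow)", km$centers[1, "k2"], 0.00657, 5e-5)
  add("kmeans centroid k1 (fast)", km$centers[2, "k1"], 1.3208, 5e-4)
  add("kmeans centroid c (fast)", km$centers[2, "c"], 0.052, 5e-4)
  add("kmeans centroid k2 (fast)", km$centers[2, "k2"], 0.0276, 5e-4)

  cg <- compare_groups(fits$k2, fits$group, method = "mann-whitney")
  add("p (k2 by group, Mann-Whitney)", cg$p, 0.017, 5e-4)

  do.call(rbind, out)
}
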