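#' Apply quality-control exclusions
#'
#' Marks rows flagged with a motion artefact as excluded
#' (`included = FALSE`, reason `"motion_artefact"`). Never drops rows.
#'
#' @param cohort A [cohort_table()].
#' @return List with `cohort` (flags updated) and `log` (data frame of
#'   `id`, `reason`, one row per excluded participant).
#' @export
apply_exclusions <- function(cohort) {
  hit <- which(cohort$motion_artefact)
  cohort$included[hit] <- FALSE
  log <- data.frame(id = cohort$id[hit],
                    reason = rep("motion_artefact", length(hit)),
                    stringsAsFactors = FALSE)
  list(cohort = cohort, log = log)
}

#' Analysis configuration
#'
#' Settings for [run_all()]. Exactly one input mode is used:
#' `"simulate"` (generate a calibrated synthetic cohort),
#' `"cohort-table"` (read a cohort CSV) or `"label-volumes"` (compute
#' morphometry from per-participant NIfTI label volumes plus a metadata
#' CSV with columns `id`, `sex`, `age`, `motion_artefact`).
#'
#' @param mode Input mode (see above).
#' @param seed Integer seed recorded in every output.
#' @param cohort_path CSV path for `"cohort-table"` mode.
#' @param volumes_dir Directory of `<id>.nii[.gz]` files for
#'   `"label-volumes"` mode.
#' @param metadata_path Metadata CSV for `"label-volumes"` mode.
#' @param n_per_group Group sizes for `"simulate"` mode.
#' @param alpha Significance level used in reporting.
#' @param min_age_sensitivity Minimum age (years) of the sensitivity
#'   analysis; `NULL` disables it.
#' @param spline_K,spline_lambda,constancy_tol Spline settings, see
#'   [fit_pspline()] and [relative_volume_trends()].
#' @param out_dir Output directory for emitted tables; `NULL` to skip
#'   writing files.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("simulate", "cohort-table", "label-volumes"),
                            seed = 1L,
                            cohort_path = NULL, volumes_dir = NULL,
                            metadata_path = NULL,
                            n_per_group = reference_group_sizes(),
                            alpha = 0.05, min_age_sensitivity = 5,
                            spline_K = 10, spline_lambda = "auto",
                            constancy_tol = 0.05, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "cohort-table" && is.null(cohort_path)) {
    stop("config error: cohort-table mode requires cohort_path")
  }
  if (mode == "label-volumes" && (is.null(volumes_dir) || is.null(metadata_path))) {
    stop("config error: label-volumes mode requires volumes_dir and metadata_path")
  }
  structure(list(mode = mode, seed = as.integer(seed), cohort_path = cohort_path,
                 volumes_dir = volumes_dir, metadata_path = metadata_path,
                 n_per_group = n_per_group, alpha = alpha,
                 min_age_sensitivity = min_age_sensitivity,
                 spline_K = spline_K, spline_lambda = spline_lambda,
                 constancy_tol = constancy_tol, out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose fields
#'   match the arguments of [analysis_config()].
#' @return Object of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$n_per_group)) raw$n_per_group <- as.data.frame(raw$n_per_group)
  do.call(analysis_config, raw)
}

# Small deterministic fingerprint (polynomial rolling hash over the
# serialized config; stays within exact double arithmetic).
config_fingerprint <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' End to end: obtain a cohort (simulated, read from CSV, or computed
#' from label volumes), apply motion-artefact exclusions, build the
#' grouped summary table, run the sex-stratified isometry analysis on
#' the full age range and restricted to the sensitivity minimum age,
#' fit absolute and relative spline trends, and (optionally) write all
#' tables to `out_dir`. Deterministic for a fixed seed; strata too small
#' for the joint test are reported as warnings, not errors.
#'
#' @param config An [analysis_config()].
#' @return Object of class `run_report`: counts (recruited, excluded,
#'   analysed, per-stratum), exclusion log, isometry results (full and
#'   sensitivity), trend summaries, output paths, seed and fingerprint.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- switch(config$mode,
    "simulate" = simulate_cohort(calibrate_reference(),
                                 n_per_group = config$n_per_group,
                                 seed = config$seed),
    "cohort-table" = read_cohort(config$cohort_path),
    "label-volumes" = cohort_from_volumes(config$volumes_dir, config$metadata_path)
  )
  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort
  analysed <- cohort[cohort$included, , drop = FALSE]

  summary_tab <- summarize_groups(cohort)
  iso_full <- run_stratified(cohort, min_age = NULL)
  iso_sens <- if (!is.null(config$min_age_sensitivity)) {
    run_stratified(cohort, min_age = config$min_age_sensitivity)
  } else NULL
  trends_abs <- tryCatch(
    absolute_volume_trends(cohort, K = config$spline_K, lambda = config$spline_lambda),
    error = function(e) NULL)
  trends_rel <- tryCatch(
    relative_volume_trends(cohort, K = config$spline_K, lambda = config$spline_lambda,
                           constancy_tol = config$constancy_tol),
    error = function(e) NULL)

  strata <- summarize_counts(cohort)
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    paths <- write_outputs(config$out_dir, cohort, summary_tab,
                           iso_full, iso_sens, trends_abs, trends_rel)
  }
  report <- structure(list(
    recruited = nrow(cohort),
    excluded = nrow(excl$log),
    analysed = nrow(analysed),
    exclusion_log = excl$log,
    strata = strata,
    isometry_full = iso_full,
    isometry_sensitivity = iso_sens,
    trends_absolute = trends_abs,
    trends_relative = trends_rel,
    summary = summary_tab,
    paths = paths,
    seed = config$seed,
    fingerprint = paste0(config_fingerprint(config), "-", "legallometry-",
                         as.character(utils::packageVersion("legallometry")))
  ), class = "run_report")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(report_as_list(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

cohort_from_volumes <- function(volumes_dir, metadata_path) {
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    files <- file.path(volumes_dir, paste0(meta$id[i], c(".nii", ".nii.gz")))
    f <- files[file.exists(files)][1]
    if (is.na(f)) stop("missing label volume for participant ", meta$id[i])
    vr <- volume_record(read_label_volume(f), id = meta$id[i])
    v <- as.list(vr$volumes[leg_muscles()])
    names(v) <- volume_cols()
    data.frame(id = meta$id[i], sex = meta$sex[i], age = meta$age[i],
               body_mass = NA_real_, height = NA_real_,
               tibia_length = vr$tibia_length, fibula_length = vr$fibula_length,
               v, motion_artefact = as.logical(meta$motion_artefact[i]),
               included = TRUE, stringsAsFactors = FALSE)
  })
  cohort_table(do.call(rbind, rows))
}

summarize_counts <- function(cohort) {
  d <- cohort[cohort$included, , drop = FALSE]
  d$band <- band_of(d$age)
  d$band[is.na(d$band)] <- "unbinned"
  as.data.frame(table(sex = d$sex, band = d$band), responseName = "n")
}

write_outputs <- function(out_dir, cohort, summary_tab, iso_full, iso_sens,
                          trends_abs, trends_rel) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit_csv <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    p
  }
  paths <- c(paths, emit_csv(as.data.frame(cohort), "cohort.csv"))
  paths <- c(paths, emit_csv(summary_tab, "summary.csv"))
  iso_list <- list()
  for (tag in c("full", "sensitivity")) {
    iso <- if (tag == "full") iso_full else iso_sens
    if (is.null(iso)) next
    for (sx in names(iso$results)) {
      r <- iso$results[[sx]]
      paths <- c(paths, emit_csv(r$pairwise, sprintf("pairwise_%s_%s.csv", sx, tag)))
      iso_list[[tag]][[sx]] <- list(statistic = r$statistic, df1 = r$df1,
                                    df2 = r$df2, p_value = r$p.value, n = r$n)
    }
    if (length(iso$skipped)) iso_list[[tag]]$skipped <- iso$skipped
  }
  p <- file.path(out_dir, "isometry.json")
  jsonlite::write_json(iso_list, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  if (!is.null(trends_abs) && !is.null(trends_abs$grid)) {
    paths <- c(paths, emit_csv(trends_abs$grid, "trends_absolute.csv"))
  }
  if (!is.null(trends_rel) && !is.null(trends_rel$grid)) {
    paths <- c(paths, emit_csv(trends_rel$grid, "trends_relative.csv"))
    if (!is.null(trends_rel$flags)) {
      paths <- c(paths, emit_csv(trends_rel$flags, "relative_constancy_flags.csv"))
    }
  }
  paths
}

report_as_list <- function(report) {
  iso <- function(s) {
    if (is.null(s)) return(NULL)
    out <- lapply(s$results, function(r) {
      list(statistic = r$statistic, df1 = r$df1, df2 = r$df2,
           p_value = r$p.value, n = r$n)
    })
    if (length(s$skipped)) out$skipped <- s$skipped
    out
  }
  list(recruited = report$recruited, excluded = report$excluded,
       analysed = report$analysed,
       exclusion_reasons = report$exclusion_log,
       strata = report$strata,
       isometry_full = iso(report$isometry_full),
       isometry_sensitivity = iso(report$isometry_sensitivity),
       seed = report$seed, fingerprint = report$fingerprint,
       paths = report$paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: %d recruited, %d excluded, %d analysed (seed %d)\n",
              x$recruited, x$excluded, x$analysed, x$seed))
  for (tag in c("isometry_full", "isometry_sensitivity")) {
    s <- x[[tag]]
    if (is.null(s)) next
    lab <- if (tag == "isometry_full") "full age range"
           else sprintf("age >= %g", s$min_age)
    for (sx in names(s$results)) {
      r <- s$results[[sx]]
      cat(sprintf("  isometry (%s, %s): F = %.2f, p %s\n", sx, lab,
                  r$statistic, format_pval(r$p.value)))
    }
    for (sk in s$skipped) cat("  ", lab, ": ", sk, "\n", sep = "")
  }
  invisible(x)
}
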