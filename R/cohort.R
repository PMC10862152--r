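#' Construct a cohort table
#'
#' A cohort table holds one row per participant: identifier, sex, age,
#' optional body mass and height, tibia and fibula length, the ten muscle
#' volumes (columns `V_LG` ... `V_FHL`, in cm^3), a motion-artefact flag
#' and an inclusion flag. The derived aggregates TSURAE and TOTAL are
#' never stored; use [total_volume()] and [tsurae_volume()].
#'
#' @param df A data frame with the columns described above.
#' @return `df` validated and classed as `cohort_table`.
#' @export
cohort_table <- function(df) {
  required <- c("id", "sex", "age", "tibia_length", "fibula_length",
                volume_cols(), "motion_artefact", "included")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(df$sex %in% c("boy", "girl"))) {
    stop("sex must be 'boy' or 'girl'")
  }
  if (any(df$age < 0, na.rm = TRUE)) stop("age must be non-negative")
  if (any(df$tibia_length <= 0, na.rm = TRUE)) stop("tibia length must be positive")
  inc <- which(df$included)
  if (length(inc) > 0) {
    V <- as.matrix(df[inc, volume_cols(), drop = FALSE])
    if (any(!is.finite(V)) || any(V <= 0)) {
      stop("all muscle volumes of included rows must be positive and finite")
    }
  }
  for (nm in c("body_mass", "height")) {
    if (!nm %in% names(df)) df[[nm]] <- NA_real_
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

volume_cols <- function() paste0("V_", leg_muscles())

#' Derived volume aggregates
#'
#' `total_volume()` is the sum of the ten muscle-group volumes; `tsurae_volume()`
#' is the triceps surae aggregate (LG + MG + SOL). Both are always derived
#' from the per-muscle columns, never stored.
#'
#' @param cohort A [cohort_table()].
#' @return Numeric vector, one value per row, in cm^3.
#' @export
total_volume <- function(cohort) {
  rowSums(as.matrix(cohort[, volume_cols(), drop = FALSE]))
}

#' @rdname total_volume
#' @export
tsurae_volume <- function(cohort) {
  rowSums(as.matrix(cohort[, paste0("V_", c("LG", "MG", "SOL")), drop = FALSE]))
}

#' Read or write a cohort table as CSV
#'
#' The CSV has one row per participant with the documented cohort columns;
#' optional fields may be empty.
#'
#' @param path File path.
#' @param cohort A [cohort_table()].
#' @return `read_cohort()` returns a [cohort_table()]; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$motion_artefact <- as.logical(df$motion_artefact)
  df$included <- as.logical(df$included)
  for (nm in c("body_mass", "height")) {        # all-empty columns read as logical
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  }
  cohort_table(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d participants (%d included; %d boys, %d girls)\n",
              nrow(x), sum(x$included), sum(x$sex == "boy"), sum(x$sex == "girl")))
  if (nrow(x) > 0) {
    cat(sprintf("  age range %.2f-%.2f y; total muscle volume %.1f-%.1f cm^3\n",
                min(x$age), max(x$age), min(total_volume(x)), max(total_volume(x))))
  }
  invisible(x)
}
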