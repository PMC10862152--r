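#' Spline trends of absolute and relative muscle volume
#'
#' `absolute_volume_trends()` fits a penalized cubic spline of each
#' muscle's absolute volume (cm^3, untransformed) against age and tibia
#' length, per sex. `relative_volume_trends()` does the same for the
#' natural log of relative volume (muscle volume over the ten-muscle
#' total); because a perfectly synchronous cohort has constant relative
#' volumes, each fitted log-relative curve is additionally flagged as
#' `constant` when its total rise or fall over the predictor range stays
#' within `constancy_tol` log units. The flag is descriptive; the
#' inferential claim about synchrony belongs to [isometry_test()].
#'
#' Only included rows are used; fit failures for single muscles are
#' collected, not fatal.
#'
#' @param cohort A [cohort_table()].
#' @param predictors Subset of `c("age", "tibia_length")`.
#' @param K,lambda Passed to [fit_pspline()].
#' @param constancy_tol Constancy tolerance in log units (relative
#'   trends only; default 0.05).
#' @return Object of class `trend_collection`: `fits` (named list of
#'   [fit_pspline()] results, names `sex.muscle.predictor`), `grid` (tidy
#'   data frame: `sex`, `muscle`, `predictor`, `x`, `fit`, `se`),
#'   `flags` (relative trends: data frame with `constant` and the fitted
#'   total change), `errors` (character), and `response`.
#' @export
absolute_volume_trends <- function(cohort, predictors = c("age", "tibia_length"),
                                   K = 10, lambda = "auto") {
  volume_trends(cohort, predictors, K, lambda, response = "absolute",
                constancy_tol = NULL)
}

#' @rdname absolute_volume_trends
#' @export
relative_volume_trends <- function(cohort, predictors = c("age", "tibia_length"),
                                   K = 10, lambda = "auto", constancy_tol = 0.05) {
  volume_trends(cohort, predictors, K, lambda, response = "log_relative",
                constancy_tol = constancy_tol)
}

volume_trends <- function(cohort, predictors, K, lambda, response, constancy_tol) {
  predictors <- match.arg(predictors, c("age", "tibia_length"), several.ok = TRUE)
  d <- cohort[cohort$included, , drop = FALSE]
  V <- as.matrix(d[, volume_cols(), drop = FALSE])
  R <- V / rowSums(V)
  fits <- list(); grids <- list(); flags <- list(); errors <- character(0)
  for (sx in intersect(c("boy", "girl"), unique(d$sex))) {
    rows <- d$sex == sx
    for (pred in predictors) {
      xv <- d[[pred]][rows]
      for (m in seq_along(leg_muscles())) {
        mus <- leg_muscles()[m]
        yv <- if (response == "absolute") V[rows, m] else log(R[rows, m])
        key <- paste(sx, mus, pred, sep = ".")
        ft <- tryCatch(fit_pspline(xv, yv, K = K, lambda = lambda),
                       error = function(e) e)
        if (inherits(ft, "error")) {
          errors <- c(errors, paste0(key, ": ", conditionMessage(ft)))
          next
        }
        fits[[key]] <- ft
        grids[[key]] <- data.frame(sex = sx, muscle = mus, predictor = pred,
                                   ft$grid, stringsAsFactors = FALSE)
        if (!is.null(constancy_tol)) {
          change <- max(ft$grid$fit) - min(ft$grid$fit)
          flags[[key]] <- data.frame(sex = sx, muscle = mus, predictor = pred,
                                     change = change,
                                     constant = change <= constancy_tol,
                                     stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(
    fits = fits,
    grid = if (length(grids)) do.call(rbind, c(grids, make.row.names = FALSE)) else NULL,
    flags = if (length(flags)) do.call(rbind, c(flags, make.row.names = FALSE)) else NULL,
    errors = errors, response = response
  ), class = "trend_collection")
}

#' @export
print.trend_collection <- function(x, ...) {
  cat(sprintf("Spline trend collection (%s response): %d fits",
              x$response, length(x$fits)))
  if (length(x$errors)) cat(sprintf(", %d failed", length(x$errors)))
  cat("\n")
  if (!is.null(x$flags)) {
    cat(sprintf("  %d of %d curves flagged constant (tolerance on total change)\n",
                sum(x$flags$constant), nrow(x$flags)))
  }
  invisible(x)
}
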