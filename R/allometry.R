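#' Major-axis (Model II) slope of a log-volume pair
#'
#' The slope of the first principal axis of the 2x2 covariance matrix of
#' `(x, y)`: with sample variances `s2x`, `s2y` and covariance `sxy`,
#' `b = (s2y - s2x + sqrt((s2y - s2x)^2 + 4 sxy^2)) / (2 sxy)` when
#' `sxy != 0`. Appropriate when both variables carry error, as log
#' volumes do. When `sxy == 0` the axis is one of the coordinate axes
#' (slope 0 or infinite); if additionally `s2x == s2y` the covariance is
#' isotropic and the slope is undefined.
#'
#' @param x,y Numeric vectors (log volumes), length >= 3.
#' @return A list of class `ma_slope` with `slope`, `angle` (radians),
#'   `n`, `s2x`, `s2y`, `sxy`.
#' @export
ma_slope <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("major-axis fit needs n >= 3")
  s2x <- stats::var(x); s2y <- stats::var(y); sxy <- stats::cov(x, y)
  if (s2x + s2y == 0) stop("degenerate input: zero variance in both variables")
  if (sxy == 0) {
    if (s2x == s2y) stop("isotropic covariance: major-axis slope undefined")
    slope <- if (s2y > s2x) Inf else 0
  } else {
    slope <- (s2y - s2x + sqrt((s2y - s2x)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  structure(list(slope = slope, angle = atan(slope), n = n,
                 s2x = s2x, s2y = s2y, sxy = sxy), class = "ma_slope")
}

#' Small-sample test of a hypothesized major-axis slope
#'
#' Rotated-scores correlation test: under `H0: slope = b0`, the scores
#' `u = y - b0 x` and `v = x + b0 y` are uncorrelated, so their sample
#' correlation `r` gives `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; the two-sided p-value is returned.
#'
#' @inheritParams ma_slope
#' @param b0 Hypothesized slope (finite); 1 corresponds to isometry of
#'   the pair.
#' @return Two-sided p-value, with attribute `flag` set to
#'   `"collinear-on-null"` when the data lie exactly on the hypothesized
#'   axis (p = 1) or `"exact-collinearity"` when `|r| = 1` (p = 0).
#' @export
ma_slope_test <- function(x, y, b0 = 1) {
  n <- length(x)
  stopifnot(length(y) == n, is.finite(b0))
  if (n < 3) stop("slope test needs n >= 3")
  u <- y - b0 * x
  v <- x + b0 * y
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    return(structure(1, flag = "collinear-on-null"))
  }
  r <- stats::cor(u, v)
  if (abs(r) >= 1) return(structure(0, flag = "exact-collinearity"))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  structure(2 * stats::pt(-abs(tstat), df = n - 2), flag = NA_character_)
}

#' Small-sample confidence interval for the major-axis slope
#'
#' Interval on the major-axis angle, mapped through the tangent:
#' `theta_hat +/- arcsin(q)/2` with
#' `q^2 = 4 F(level; 1, n-2) (s2x s2y - sxy^2) /
#' ((n - 2) ((s2y - s2x)^2 + 4 sxy^2))`.
#' The interval inverts [ma_slope_test()]: `b0` lies inside the interval
#' at level `level` exactly when its test p-value exceeds `1 - level`.
#' When `q^2 >= 1` the angle is unconstrained and the interval is the
#' whole line, flagged `unbounded`.
#'
#' @inheritParams ma_slope
#' @param level Confidence level (default 0.95); requires n >= 4.
#' @return List with `lo`, `hi`, `level`, logical `unbounded`, and
#'   logical `wraps` (TRUE when the angle interval crosses the vertical,
#'   so the slope region is the complement of `(hi, lo)`).
#' @export
ma_slope_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  if (n < 4) stop("confidence interval needs n >= 4")
  fit <- ma_slope(x, y)
  q2 <- 4 * stats::qf(level, 1, n - 2) * (fit$s2x * fit$s2y - fit$sxy^2) /
    ((n - 2) * ((fit$s2y - fit$s2x)^2 + 4 * fit$sxy^2))
  if (q2 >= 1) {
    return(list(lo = -Inf, hi = Inf, level = level, unbounded = TRUE, wraps = FALSE))
  }
  half <- asin(sqrt(q2)) / 2
  th <- fit$angle + c(-half, half)
  wraps <- any(abs(th) > pi / 2)
  list(lo = tan(th[1]), hi = tan(th[2]), level = level,
       unbounded = FALSE, wraps = wraps)
}

#' Log-volume matrix of an included stratum
#'
#' Natural-log muscle volumes of the included rows of a cohort,
#' optionally filtered by sex and minimum age; columns in canonical
#' muscle order.
#'
#' @param cohort A [cohort_table()].
#' @param sex `"boy"`, `"girl"` or `NULL` for both.
#' @param min_age Keep rows with `age >= min_age` (`NULL`: no filter).
#' @return Numeric matrix with muscle-code column names and attributes
#'   `sex` and `min_age`.
#' @export
log_volume_matrix <- function(cohort, sex = NULL, min_age = NULL) {
  d <- cohort[cohort$included, , drop = FALSE]
  if (!is.null(sex)) d <- d[d$sex == sex, , drop = FALSE]
  if (!is.null(min_age)) d <- d[d$age >= min_age, , drop = FALSE]
  M <- log(as.matrix(d[, volume_cols(), drop = FALSE]))
  colnames(M) <- leg_muscles()
  rownames(M) <- d$id
  attr(M, "sex") <- if (is.null(sex)) "all" else sex
  attr(M, "min_age") <- min_age
  M
}

#' Major-axis fits for all muscle pairs
#'
#' One major-axis fit per unordered pair of columns (45 pairs for the 10
#' canonical muscles), in canonical order, with the small-sample slope
#' test against `b0` and confidence interval, and Holm-adjusted p-values
#' across the family of pairs.
#'
#' @param M Log-volume matrix from [log_volume_matrix()] (or any numeric
#'   matrix with named columns).
#' @param b0 Hypothesized slope for the per-pair test (default 1).
#' @param level Confidence level for the per-pair interval.
#' @return Data frame of class `ma_fit_table`: `muscle_x`, `muscle_y`,
#'   `n`, `slope`, `angle`, `ci_lo`, `ci_hi`, `p`, `p_holm`, `flag`.
#' @export
pairwise_slopes <- function(M, b0 = 1, level = 0.95) {
  p <- ncol(M)
  cn <- colnames(M)
  if (is.null(cn)) cn <- paste0("V", seq_len(p))
  pairs <- utils::combn(p, 2)
  out <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    j <- pairs[1, i]; k <- pairs[2, i]
    x <- M[, j]; y <- M[, k]
    res <- tryCatch({
      fit <- ma_slope(x, y)
      pv <- ma_slope_test(x, y, b0 = b0)
      ci <- ma_slope_ci(x, y, level = level)
      data.frame(muscle_x = cn[j], muscle_y = cn[k], n = fit$n,
                 slope = fit$slope, angle = fit$angle,
                 ci_lo = ci$lo, ci_hi = ci$hi, p = as.numeric(pv),
                 p_holm = NA_real_, flag = attr(pv, "flag"),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(muscle_x = cn[j], muscle_y = cn[k], n = nrow(M),
                 slope = NA_real_, angle = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, p = NA_real_, p_holm = NA_real_,
                 flag = paste0("degenerate: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  tab <- do.call(rbind, out)
  tab$p_holm <- stats::p.adjust(tab$p, method = "holm")
  class(tab) <- c("ma_fit_table", "data.frame")
  tab
}

#' Joint test of isometry (synchronous growth)
#'
#' Tests whether the first principal axis of the p-variate log-volume
#' covariance is proportional to the isometric direction
#' `c = (1, ..., 1)/sqrt(p)`, i.e. whether all pairwise allometric slopes
#' are 1 simultaneously. With `S` the sample covariance and `lambda1` its
#' largest eigenvalue, the bracket
#' `T = lambda1 c'S^-1 c + c'S c / lambda1 - 2` is zero exactly when `c`
#' is the dominant eigenvector. The p-value uses the small-sample
#' calibration `F = (n - p)/(p - 1) T` against `F(p - 1, n - p)`; the
#' large-sample chi-square form `X2 = (n - 1) T` on `p - 1` df is also
#' reported. The Holm-adjusted pairwise slope-vs-1 surface
#' ([pairwise_slopes()]) accompanies the joint test as its descriptive
#' counterpart.
#'
#' @param M Log-volume matrix (n x p), e.g. from [log_volume_matrix()].
#' @param pairwise Compute the pairwise descriptive surface (default
#'   `TRUE`; set `FALSE` to skip it, e.g. inside simulation loops).
#' @return Object of class `isometry_result`: `statistic` (F form),
#'   `X2` (chi-square form), `bracket`, `df1`, `df2`, `p.value`,
#'   `lambda1`, `eigen_gap`, `multiplicity_flag`, `n`, `p`, `stratum`,
#'   `min_age`, `pairwise` (the [pairwise_slopes()] table) and
#'   `pairwise_holm` (symmetric p x p matrix of Holm-adjusted p-values).
#' @export
isometry_test <- function(M, pairwise = TRUE) {
  n <- nrow(M); p <- ncol(M)
  if (n < p + 2) stop("joint isometry test needs n >= p + 2 (got n = ", n, ")")
  S <- stats::cov(M)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[p] <= ev$values[1] * 1e-12) {
    cm <- stats::cor(M)
    diag(cm) <- 0
    idx <- which(abs(cm) > 1 - 1e-10, arr.ind = TRUE)
    cols <- if (nrow(idx) > 0) {
      paste(unique(apply(idx, 1, function(r) paste(colnames(M)[sort(r)], collapse = "~"))),
            collapse = ", ")
    } else "unidentified"
    stop("singular log-volume covariance; collinear columns: ", cols)
  }
  l1 <- ev$values[1]
  gap <- (ev$values[1] - ev$values[2]) / ev$values[1]
  c0 <- rep(1 / sqrt(p), p)
  bracket <- drop(l1 * crossprod(c0, solve(S, c0)) + crossprod(c0, S %*% c0) / l1 - 2)
  bracket <- max(bracket, 0)
  Fstat <- (n - p) / (p - 1) * bracket
  pw <- NULL; Pm <- NULL
  if (pairwise) {
    pw <- pairwise_slopes(M)
    Pm <- matrix(NA_real_, p, p, dimnames = list(colnames(M), colnames(M)))
    for (i in seq_len(nrow(pw))) {
      Pm[pw$muscle_x[i], pw$muscle_y[i]] <- pw$p_holm[i]
      Pm[pw$muscle_y[i], pw$muscle_x[i]] <- pw$p_holm[i]
    }
  }
  structure(list(
    statistic = Fstat, X2 = (n - 1) * bracket, bracket = bracket,
    df1 = p - 1, df2 = n - p,
    p.value = stats::pf(Fstat, p - 1, n - p, lower.tail = FALSE),
    lambda1 = l1, eigen_gap = gap, multiplicity_flag = gap < 1e-8,
    n = n, p = p,
    stratum = attr(M, "sex") %||% "all", min_age = attr(M, "min_age"),
    pairwise = pw, pairwise_holm = Pm,
    method = "first-eigenvector test of isometry (small-sample F calibration)"
  ), class = "isometry_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sex-stratified isometry analysis
#'
#' Applies exclusion flags and an optional minimum-age filter, log
#' transforms the absolute muscle volumes, and runs [isometry_test()]
#' separately for boys and girls. Strata too small for the joint test
#' (n < p + 2) are skipped with an explicit warning record.
#'
#' @param cohort A [cohort_table()].
#' @param min_age Optional minimum age in years (e.g. 5 for the
#'   infant-exclusion sensitivity analysis); `NULL` for the full range.
#' @return Object of class `stratified_isometry`: list with `results`
#'   (named list of [isometry_test()] results), `skipped` (character),
#'   and `min_age`.
#' @export
run_stratified <- function(cohort, min_age = NULL) {
  results <- list(); skipped <- character(0)
  for (sx in c("boy", "girl")) {
    M <- log_volume_matrix(cohort, sex = sx, min_age = min_age)
    if (nrow(M) < ncol(M) + 2) {
      skipped <- c(skipped, sprintf("%s: n = %d < p + 2, stratum skipped", sx, nrow(M)))
      next
    }
    results[[sx]] <- isometry_test(M)
  }
  structure(list(results = results, skipped = skipped, min_age = min_age),
            class = "stratified_isometry")
}

#' @export
print.ma_slope <- function(x, ...) {
  cat(sprintf("Major-axis slope %.4f (angle %.2f deg, n = %d)\n",
              x$slope, x$angle * 180 / pi, x$n))
  invisible(x)
}

#' @export
print.isometry_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  stratum: %s%s; n = %d, p = %d\n", x$stratum,
              if (!is.null(x$min_age)) sprintf(" (age >= %g)", x$min_age) else "",
              x$n, x$p))
  cat(sprintf("  F = %.3f on (%d, %d) df, p %s\n", x$statistic, x$df1, x$df2,
              format_pval(x$p.value)))
  if (x$multiplicity_flag) {
    cat("  warning: leading eigenvalue nearly multiple; test unreliable\n")
  }
  invisible(x)
}

#' @export
print.stratified_isometry <- function(x, ...) {
  cat("Sex-stratified isometry analysis",
      if (!is.null(x$min_age)) sprintf("(age >= %g)", x$min_age) else "(full age range)", "\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: F = %.3f on (%d, %d) df, p %s\n", nm, r$statistic,
                r$df1, r$df2, format_pval(r$p.value)))
  }
  for (s in x$skipped) cat("  skipped -", s, "\n")
  invisible(x)
}
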