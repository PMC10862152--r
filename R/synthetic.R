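#' Log-normal parameters matched to a target mean and SD
#'
#' Moment matching on the natural scale: for a target mean `m` and standard
#' deviation `s`, the log-scale variance is `sigma2 = log(1 + s^2/m^2)` and
#' the log-scale mean is `log(m) - sigma2/2`, so that simulated draws
#' reproduce `m` and `s` as the sample grows.
#'
#' @param mean,sd Target mean and SD on the natural (cm^3) scale; both must
#'   be positive (`sd = 0` is allowed and gives a point mass).
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  if (any(mean <= 0) || any(sd < 0)) {
    stop("invalid summary: means must be positive and SDs non-negative")
  }
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Specify a structural allometric growth model
#'
#' Defines the generative model used by [simulate_cohort()] in its
#' "allometric" mode: for muscle m, `log V_m = a_m + b_m * log S + eps_m`,
#' where `S` is tibia length (the latent size scale), `b_m` is the
#' muscle-specific allometric exponent, and `eps_m ~ N(0, sigma_m^2)`.
#' Growth is synchronous (isometric across muscles) exactly when all
#' exponents are equal *and* all residual SDs are equal; the default spec
#' is that synchronous case.
#'
#' @param exponents Named numeric vector of 10 allometric exponents, one
#'   per muscle in [leg_muscles()] order.
#' @param log_intercepts Named numeric vector of 10 log-intercepts `a_m`.
#'   Default: anchored so that at the reference tibia length of the boys
#'   7.5-10 y band, muscle volumes match the bundled reference means.
#' @param sigma Residual log-SDs; scalar or vector of 10, all positive.
#' @param sex_effect Multiplicative volume effect, named `boy` and `girl`.
#' @param bands Age-band table as in [age_bands()]; bands must be disjoint
#'   half-open intervals. Custom bands (e.g. one spanning the 0.3-5 y gap)
#'   may be supplied for exploration.
#' @param artefact_prob Probability that a participant's scan carries a
#'   motion artefact (default 2/210, the reference cohort's rate).
#' @param tibia_cv Multiplicative (coefficient-of-variation) noise on the
#'   age-to-tibia growth curve.
#' @return An object of class `growth_model_spec`.
#' @export
growth_model_spec <- function(exponents = stats::setNames(rep(1, 10), leg_muscles()),
                              log_intercepts = NULL,
                              sigma = 0.15,
                              sex_effect = c(boy = 1, girl = 0.93),
                              bands = age_bands(),
                              artefact_prob = 2 / 210,
                              tibia_cv = 0.07) {
  muscles <- leg_muscles()
  if (is.null(names(exponents))) names(exponents) <- muscles
  if (!identical(sort(names(exponents)), sort(muscles)) || anyDuplicated(names(exponents))) {
    stop("exponents must be named by the 10 canonical muscle codes")
  }
  exponents <- exponents[muscles]
  if (length(sigma) == 1) sigma <- rep(sigma, 10)
  if (any(sigma <= 0)) stop("all residual log-SDs must be positive")
  names(sigma) <- muscles
  check_bands(bands)
  curve <- reference_tibia_curve()
  if (is.null(log_intercepts)) {
    ref <- reference_summary()
    anchor <- ref[ref$sex == "boy" & ref$band == "7.5-10", ]
    vm <- anchor$mean[match(muscles, anchor$variable)]
    tib <- anchor$mean[anchor$variable == "tibia_length"]
    log_intercepts <- stats::setNames(log(vm) - exponents * log(tib), muscles)
  }
  structure(list(
    mode = "allometric", muscles = muscles, bands = bands,
    exponents = exponents, log_intercepts = log_intercepts[muscles],
    sigma = sigma, sex_effect = sex_effect, artefact_prob = artefact_prob,
    tibia_curve = curve, tibia_cv = tibia_cv
  ), class = "growth_model_spec")
}

check_bands <- function(bands) {
  stopifnot(all(c("band", "lo", "hi") %in% names(bands)))
  if (any(bands$hi <= bands$lo)) stop("age bands must have lo < hi")
  o <- order(bands$lo)
  if (any(bands$lo[o][-1] < bands$hi[o][-nrow(bands)])) {
    stop("age bands must be disjoint half-open intervals [lo, hi)")
  }
  invisible(bands)
}

# Sex-specific monotone age -> tibia length (cm) interpolants through the
# reference band means, linearly extrapolated outside the observed range.
reference_tibia_curve <- function() {
  ref <- reference_summary()
  out <- list()
  for (sx in c("boy", "girl")) {
    r <- ref[ref$sex == sx & ref$variable %in% c("age", "tibia_length"), ]
    ag <- r$mean[r$variable == "age"][match(age_bands()$band, r$band[r$variable == "age"])]
    tb <- r$mean[r$variable == "tibia_length"][match(age_bands()$band, r$band[r$variable == "tibia_length"])]
    out[[sx]] <- stats::splinefun(ag, tb, method = "monoH.FC")
  }
  out
}

#' Calibrate a band-wise generator to the bundled reference summary
#'
#' Builds a "banded" generative spec whose per-band, per-sex, per-muscle
#' log-normal parameters are moment-matched to the supplied group means
#' and SDs (see [lognormal_params()]), so that simulated group summaries
#' converge to the reference values as the group size grows. Within each
#' sex-by-band group, muscles share a single latent size factor on the log
#' scale (equicorrelation `rho`); `rho` is itself moment-matched, per
#' group, so that the variance of the derived TOTAL aggregate reproduces
#' the printed TOTAL SD. Tibia/fibula length, body mass and height are
#' drawn from the same latent factor with their own matched log-normals.
#'
#' @param summary A summary table in the layout of [reference_summary()].
#' @param artefact_prob Motion-artefact probability (default 2/210).
#' @return An object of class `growth_model_spec` with mode `"banded"`.
#' @export
calibrate_reference <- function(summary = reference_summary(),
                                artefact_prob = 2 / 210) {
  muscles <- leg_muscles()
  need <- c(muscles, "TOTAL", "tibia_length", "fibula_length")
  groups <- unique(summary[summary$variable == "TOTAL", c("sex", "band")])
  if (nrow(groups) == 0) stop("invalid summary: no TOTAL rows")
  params <- list()
  for (i in seq_len(nrow(groups))) {
    sx <- groups$sex[i]; bd <- groups$band[i]
    s <- summary[summary$sex == sx & summary$band == bd, ]
    row_of <- function(v) {
      r <- s[s$variable == v, ]
      if (nrow(r) != 1) stop("invalid summary: missing ", v, " for ", sx, " ", bd)
      r
    }
    mus <- t(vapply(muscles, function(m) {
      r <- row_of(m)
      if (!is.finite(r$mean) || r$mean <= 0 || !is.finite(r$sd) || r$sd <= 0) {
        stop("invalid summary: non-positive mean or SD for ", m)
      }
      p <- lognormal_params(r$mean, r$sd)
      c(meanlog = p$meanlog, sdlog = p$sdlog, mean = r$mean, sd = r$sd)
    }, numeric(4)))
    tot <- row_of("TOTAL")
    ssum <- sum(mus[, "sd"]); ssq <- sum(mus[, "sd"]^2)
    rho <- (tot$sd^2 - ssq) / (ssum^2 - ssq)
    rho <- min(max(rho, 0), 0.98)
    aux <- lapply(c(tibia_length = "tibia_length", fibula_length = "fibula_length",
                    body_mass = "body_mass", height = "height"), function(v) {
      r <- s[s$variable == v, ]
      if (nrow(r) != 1) return(NULL)
      lognormal_params(r$mean, r$sd)
    })
    params[[paste(sx, bd, sep = ".")]] <- list(sex = sx, band = bd,
      n_ref = tot$n, muscle = mus, rho = rho, aux = aux)
  }
  structure(list(
    mode = "banded", muscles = muscles, bands = age_bands(),
    groups = params, artefact_prob = artefact_prob
  ), class = "growth_model_spec")
}

#' Reference group sizes
#'
#' The sex-by-band participant counts of the bundled reference cohort
#' (total 210 recruited), used as the default design of
#' [simulate_cohort()].
#'
#' @return Data frame with columns `sex`, `band`, `n`.
#' @export
reference_group_sizes <- function() {
  ref <- reference_summary()
  g <- unique(ref[ref$variable == "TOTAL", c("sex", "band", "n")])
  rownames(g) <- NULL
  g
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort table from a [growth_model_spec()]. Ages are uniform
#' within each band. In `"banded"` mode (from [calibrate_reference()])
#' muscle volumes are group-wise correlated log-normals whose marginal
#' means/SDs match the calibration targets; in `"allometric"` mode they
#' follow the structural model `log V_m = a_m + b_m log(tibia) + eps_m`,
#' giving a known ground truth for slope-recovery and size/power studies.
#' Motion-artefact flags are Bernoulli with the spec's probability. The
#' result is bitwise-reproducible for a fixed seed.
#'
#' @param spec A [growth_model_spec()] or [calibrate_reference()] result.
#' @param n_per_group Data frame with columns `sex`, `band`, `n`; defaults
#'   to [reference_group_sizes()].
#' @param seed Integer seed; all randomness flows from it and the global
#'   RNG state is left untouched.
#' @return A [cohort_table()].
#' @export
simulate_cohort <- function(spec, n_per_group = reference_group_sizes(), seed) {
  stopifnot(inherits(spec, "growth_model_spec"))
  if (missing(seed)) stop("an explicit integer seed is required")
  bad_band <- setdiff(n_per_group$band, spec$bands$band)
  if (length(bad_band) > 0) stop("unknown band in n_per_group: ", paste(bad_band, collapse = ", "))
  if (!all(n_per_group$sex %in% c("boy", "girl"))) stop("unknown sex in n_per_group")
  withr::with_seed(seed, simulate_cohort_impl(spec, n_per_group))
}

simulate_cohort_impl <- function(spec, n_per_group) {
  muscles <- spec$muscles
  rows <- list()
  for (i in seq_len(nrow(n_per_group))) {
    n <- n_per_group$n[i]
    if (n == 0) next
    sx <- n_per_group$sex[i]; bd <- n_per_group$band[i]
    b <- spec$bands[spec$bands$band == bd, ]
    age <- stats::runif(n, b$lo, b$hi)
    if (spec$mode == "banded") {
      g <- spec$groups[[paste(sx, bd, sep = ".")]]
      if (is.null(g)) stop("calibration has no group for ", sx, " ", bd)
      Z <- stats::rnorm(n)                       # latent within-group size factor
      E <- matrix(stats::rnorm(n * 10), n, 10)
      L <- sqrt(g$rho) * Z %o% rep(1, 10) + sqrt(1 - g$rho) * E
      V <- exp(sweep(L %*% diag(g$muscle[, "sdlog"]), 2, g$muscle[, "meanlog"], "+"))
      drew <- function(v) {
        p <- g$aux[[v]]
        if (is.null(p)) return(rep(NA_real_, n))
        exp(p$meanlog + p$sdlog * (sqrt(g$rho) * Z + sqrt(1 - g$rho) * stats::rnorm(n)))
      }
      tib <- drew("tibia_length"); fib <- drew("fibula_length")
      mass <- drew("body_mass"); ht <- drew("height")
    } else {
      mu_t <- spec$tibia_curve[[sx]](age)
      sd_log <- sqrt(log(1 + spec$tibia_cv^2))
      tib <- exp(log(mu_t) - sd_log^2 / 2 + stats::rnorm(n, 0, sd_log))
      fib <- tib * 0.97
      mass <- rep(NA_real_, n); ht <- rep(NA_real_, n)
      E <- matrix(stats::rnorm(n * 10), n, 10) %*% diag(spec$sigma)
      lv <- outer(log(tib), spec$exponents) +
        matrix(spec$log_intercepts, n, 10, byrow = TRUE) + E
      V <- exp(lv + log(spec$sex_effect[[sx]]))
    }
    colnames(V) <- volume_cols()
    rows[[length(rows) + 1]] <- data.frame(
      sex = sx, band = bd, age = age, body_mass = mass, height = ht,
      tibia_length = tib, fibula_length = fib, V,
      motion_artefact = stats::runif(n) < spec$artefact_prob,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    df <- data.frame(id = character(0), sex = character(0), age = numeric(0),
                     body_mass = numeric(0), height = numeric(0),
                     tibia_length = numeric(0), fibula_length = numeric(0))
    for (v in volume_cols()) df[[v]] <- numeric(0)
    df$motion_artefact <- logical(0); df$included <- logical(0)
    return(cohort_table(df))
  }
  df <- do.call(rbind, rows)
  df$band <- NULL
  df <- cbind(id = sprintf("P%03d", seq_len(nrow(df))), df, stringsAsFactors = FALSE)
  df$included <- TRUE
  rownames(df) <- NULL
  cohort_table(df)
}

#' @export
print.growth_model_spec <- function(x, ...) {
  if (x$mode == "banded") {
    cat(sprintf("Banded growth model: %d calibrated sex-by-band groups, artefact prob %.4f\n",
                length(x$groups), x$artefact_prob))
    rhos <- vapply(x$groups, `[[`, numeric(1), "rho")
    cat(sprintf("  within-group latent-size correlation rho: %.2f-%.2f\n",
                min(rhos), max(rhos)))
  } else {
    cat("Structural allometric growth model (latent size = tibia length)\n")
    cat("  exponents:", paste(sprintf("%s=%.2f", names(x$exponents), x$exponents),
                              collapse = " "), "\n")
    cat(sprintf("  residual log-SD %.3f-%.3f; artefact prob %.4f\n",
                min(x$sigma), max(x$sigma), x$artefact_prob))
  }
  invisible(x)
}
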