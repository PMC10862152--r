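# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except the installed reference summary.

# Bivariate normal sample with a prescribed population major-axis slope.
# The major axis is the direction (1, b) (noise isotropic around the axis).
rma_pair <- function(n, slope = 1, spread = 1, noise = 0.2) {
  t <- stats::rnorm(n, 0, spread)
  ax <- c(1, slope) / sqrt(1 + slope^2)
  perp <- c(-ax[2], ax[1])
  e <- stats::rnorm(n, 0, noise)
  cbind(x = t * ax[1] + e * perp[1], y = t * ax[2] + e * perp[2])
}

# Dominant-eigenvector slope from a full eigendecomposition (oracle route,
# independent of the closed-form expression in ma_slope()).
eigen_slope <- function(x, y) {
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v[2] / v[1]
}

# Minimal valid cohort table with given per-row fields.
toy_cohort <- function(n = 12, sex = rep(c("boy", "girl"), length.out = n),
                       age = seq(5, 14, length.out = n), seed = 1) {
  withr::with_seed(seed, {
    V <- matrix(stats::rlnorm(n * 10, meanlog = 3, sdlog = 0.3), n, 10)
    colnames(V) <- paste0("V_", leg_muscles())
    df <- data.frame(id = sprintf("T%03d", seq_len(n)), sex = sex, age = age,
                     body_mass = NA_real_, height = NA_real_,
                     tibia_length = 20 + age, fibula_length = 19 + age, V,
                     motion_artefact = FALSE, included = TRUE,
                     stringsAsFactors = FALSE)
    cohort_table(df)
  })
}

# One-record cohort from the reference group means of one stratum.
reference_mean_record <- function(sex, band) {
  ref <- reference_summary()
  s <- ref[ref$sex == sex & ref$band == band, ]
  v <- function(nm) s$mean[s$variable == nm]
  V <- as.list(vapply(leg_muscles(), v, numeric(1)))
  names(V) <- paste0("V_", leg_muscles())
  cohort_table(data.frame(id = paste0(sex, "-", band), sex = sex, age = v("age"),
                          body_mass = v("body_mass"), height = v("height"),
                          tibia_length = v("tibia_length"),
                          fibula_length = v("fibula_length"), V,
                          motion_artefact = FALSE, included = TRUE,
                          stringsAsFactors = FALSE))
}
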