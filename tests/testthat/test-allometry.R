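test_that("major-axis slope handles exact and degenerate geometries", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ma_slope(x, x)$slope, 1, tolerance = 1e-12)
  expect_equal(ma_slope(x, 2 * x + 3)$slope, 2, tolerance = 1e-12)
  expect_equal(ma_slope(x, -0.5 * x)$slope, -0.5, tolerance = 1e-12)

  expect_error(ma_slope(rep(1, 5), rep(2, 5)), "degenerate")
  # isotropic: uncorrelated with equal variances
  expect_error(ma_slope(c(-1, 1, -1, 1), c(-1, -1, 1, 1)), "isotropic")
  # zero covariance, unequal variances: axis-aligned slopes
  expect_equal(ma_slope(c(-1, 1, -1, 1), c(-2, -2, 2, 2))$slope, Inf)
  expect_equal(ma_slope(c(-2, 2, -2, 2), c(-1, -1, 1, 1))$slope, 0)
  expect_error(ma_slope(1:2, 1:2), "n >= 3")
})

test_that("closed-form slope equals the eigendecomposition oracle", {
  withr::with_seed(101, {
    worst <- 0
    for (i in 1:1000) {
      n <- sample(5:60, 1)
      XY <- rma_pair(n, slope = stats::runif(1, -3, 3),
                     spread = stats::runif(1, 0.3, 2),
                     noise = stats::runif(1, 0.01, 0.5))
      b <- ma_slope(XY[, 1], XY[, 2])$slope
      worst <- max(worst, abs(b - eigen_slope(XY[, 1], XY[, 2])))
    }
    expect_lt(worst, 1e-10)
  })
})

test_that("slopes are reciprocal, shift-equivariant and log-base invariant", {
  withr::with_seed(102, {
    for (i in 1:50) {
      XY <- rma_pair(30, slope = stats::runif(1, 0.3, 2.5), noise = 0.2)
      x <- XY[, 1]; y <- XY[, 2]
      expect_equal(ma_slope(y, x)$slope, 1 / ma_slope(x, y)$slope,
                   tolerance = 1e-10)
      # adding constants on the log scale = rescaling volumes
      expect_equal(ma_slope(x + 2.5, y - 1.3)$slope, ma_slope(x, y)$slope,
                   tolerance = 1e-12)
      expect_equal(as.numeric(ma_slope_test(x + 2.5, y - 1.3)),
                   as.numeric(ma_slope_test(x, y)), tolerance = 1e-12)
      # common rescaling of both axes (log10 vs natural log)
      k <- 1 / log(10)
      expect_equal(ma_slope(k * x, k * y)$slope, ma_slope(x, y)$slope,
                   tolerance = 1e-12)
      expect_equal(as.numeric(ma_slope_test(k * x, k * y)),
                   as.numeric(ma_slope_test(x, y)), tolerance = 1e-12)
    }
  })
})

test_that("slope test is exactly sized and collinearity is flagged", {
  # size at n = 30 under the null (moderate replication; the acceptance
  # suite runs the larger calibration study)
  withr::with_seed(103, {
    pvals <- replicate(2000, {
      XY <- rma_pair(30, slope = 1.4, noise = 0.3)
      as.numeric(ma_slope_test(XY[, 1], XY[, 2], b0 = 1.4))
    })
    expect_gt(mean(pvals < 0.05), 0.035)
    expect_lt(mean(pvals < 0.05), 0.065)
    # p-values are uniform enough for Holm to be meaningful
    expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.001)
  })

  x <- c(1, 2, 3, 4)
  p <- ma_slope_test(x, x, b0 = 1)
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "flag"), "collinear-on-null")
  p2 <- ma_slope_test(x, 2 * x, b0 = 1)
  expect_equal(as.numeric(p2), 0)
  expect_equal(attr(p2, "flag"), "exact-collinearity")
})

test_that("slope test has power against a false isometric null", {
  withr::with_seed(104, {
    rej <- mean(replicate(200, {
      XY <- rma_pair(200, slope = 1.5, noise = 0.2)
      as.numeric(ma_slope_test(XY[, 1], XY[, 2], b0 = 1)) < 0.05
    }))
    expect_gt(rej, 0.99)
  })
})

test_that("confidence interval inverts the slope test", {
  withr::with_seed(105, {
    for (i in 1:20) {
      XY <- rma_pair(sample(10:80, 1), slope = stats::runif(1, 0.5, 2),
                     noise = stats::runif(1, 0.05, 0.4))
      x <- XY[, 1]; y <- XY[, 2]
      fit <- ma_slope(x, y)
      ci <- ma_slope_ci(x, y, level = 0.95)
      if (ci$unbounded || ci$wraps) next
      expect_gte(fit$slope, ci$lo)
      expect_lte(fit$slope, ci$hi)
      for (b0 in seq(ci$lo - 0.5, ci$hi + 0.5, length.out = 23)) {
        inside <- b0 >= ci$lo & b0 <= ci$hi
        pv <- as.numeric(ma_slope_test(x, y, b0 = b0))
        if (abs(pv - 0.05) < 1e-6) next      # boundary tolerance
        expect_identical(inside, pv > 0.05)
      }
    }
  })
})

test_that("interval width shrinks with sample size", {
  withr::with_seed(106, {
    width <- function(n) {
      XY <- rma_pair(n, slope = 1, noise = 0.2)
      ci <- ma_slope_ci(XY[, 1], XY[, 2])
      ci$hi - ci$lo
    }
    expect_lt(width(10000), width(100))
  })
})

test_that("pairwise fits cover all 45 pairs in canonical order", {
  co <- toy_cohort(n = 25)
  M <- log_volume_matrix(co)
  tab <- pairwise_slopes(M)
  expect_equal(nrow(tab), choose(10, 2))
  expect_equal(tab$muscle_x[1], "LG")
  expect_equal(tab$muscle_y[1], "MG")
  expect_true(all(tab$p_holm >= tab$p - 1e-15, na.rm = TRUE))

  # identical columns: slope 1 everywhere; data lie exactly on the
  # hypothesized isometric axis, so the test is degenerate with p = 1
  M2 <- matrix(rep(rnorm(20), 3), 20, 3)
  colnames(M2) <- c("A", "B", "C")
  tab2 <- pairwise_slopes(M2)
  expect_equal(tab2$slope, rep(1, 3))
  expect_equal(tab2$flag, rep("collinear-on-null", 3))
  expect_equal(tab2$p, rep(1, 3))
})

test_that("isometry statistic is zero when the leading axis is isometric", {
  # construct data whose sample covariance has first eigenvector (1,..,1)/sqrt(p)
  p <- 10
  c0 <- rep(1 / sqrt(p), p)
  withr::with_seed(107, {
    Q <- qr.Q(qr(cbind(c0, matrix(rnorm(p * (p - 1)), p))))
    Z <- matrix(rnorm(40 * p), 40, p)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Z <- Z %*% solve(chol(cov(Z)))               # whiten exactly
    X <- Z %*% diag(sqrt(seq(5, 0.5, length.out = p))) %*% t(Q)
    colnames(X) <- leg_muscles()
    res <- isometry_test(X, pairwise = FALSE)
    expect_equal(res$bracket, 0, tolerance = 1e-10)
    expect_equal(res$p.value, 1, tolerance = 1e-8)
  })
})

test_that("isometry test demands enough rows and flags singular input", {
  M <- matrix(rnorm(11 * 10), 11, 10)
  colnames(M) <- leg_muscles()
  expect_error(isometry_test(M), "n >= p \\+ 2")

  withr::with_seed(108, {
    M2 <- matrix(rnorm(40 * 10), 40, 10)
    M2[, 2] <- 2 * M2[, 1] + 3                  # collinear pair
    colnames(M2) <- leg_muscles()
    expect_error(isometry_test(M2), "LG~MG")
  })
})

test_that("stratified analysis filters, skips and is order invariant", {
  spec <- calibrate_reference()
  co <- simulate_cohort(spec, seed = 9)
  co <- apply_exclusions(co)$cohort

  full <- run_stratified(co)
  expect_named(full$results, c("boy", "girl"))
  sens <- run_stratified(co, min_age = 5)
  expect_true(all(vapply(sens$results, `[[`, numeric(1), "n") <
                  vapply(full$results, `[[`, numeric(1), "n")))
  expect_equal(full$results$boy$n, sum(co$included & co$sex == "boy"))

  # permuting rows changes nothing
  perm <- co[rev(seq_len(nrow(co))), ]
  full2 <- run_stratified(perm)
  expect_equal(full2$results$boy$p.value, full$results$boy$p.value)
  expect_equal(full2$results$girl$statistic, full$results$girl$statistic)

  # boys-only cohort: girls stratum reported as skipped
  boys <- co[co$sex == "boy", ]
  one <- run_stratified(boys)
  expect_named(one$results, "boy")
  expect_match(one$skipped, "girl")
})

test_that("synchronous simulation satisfies the isometry null (quick check)", {
  # small-replication version; the calibration study with 1000 replicates
  # runs in the acceptance suite
  spec <- growth_model_spec()
  npg <- data.frame(sex = "boy", band = age_bands()$band, n = c(8, 23, 23, 23, 23))
  withr::with_seed(109, {
    rej <- mean(replicate(200, {
      co <- simulate_cohort(spec, npg, seed = sample.int(1e6, 1))
      isometry_test(log_volume_matrix(co), pairwise = FALSE)$p.value < 0.05
    }))
    expect_gt(rej, 0.01)
    expect_lt(rej, 0.10)
  })
})
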