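test_that("voxel-count volumetry is exact on axis-aligned cuboids", {
  ps <- phantom_spec(c(20, 20, 20), c(1, 1, 1), list(
    phantom_shape("cuboid", 1, "SOL", center = c(10, 10, 10), dim = c(10, 10, 10))))
  lv <- make_phantom(ps)
  expect_equal(label_volume(lv, "SOL"), 1.000, tolerance = 1e-12)
  expect_equal(label_volume(lv, 1), 1.000, tolerance = 1e-12)
  expect_error(label_volume(lv, "LG"), "unknown label")
  expect_error(label_volume(lv, 9), "unknown label")
})

test_that("a label present in the dictionary but absent in the array has volume 0", {
  arr <- array(0L, c(4, 4, 4)); arr[1, 1, 1] <- 1L
  lv <- as_label_volume(arr, c(1, 1, 1),
                        data.frame(label = 1:2, code = c("LG", "MG"),
                                   kind = "muscle"))
  expect_equal(label_volume(lv, "MG"), 0)
})

test_that("phantom volumes match analytic truth within 2% at 1 mm spacing", {
  ps <- phantom_spec(c(60, 50, 100), c(1, 1, 1), list(
    phantom_shape("ellipsoid", 1, "SOL", center = c(30, 25, 50),
                  dim = c(20, 15, 40)),
    phantom_shape("cylinder", 2, "tibia", kind = "bone",
                  center = c(8, 8, 50), dim = c(6, 90))))
  lv <- make_phantom(ps)
  gt <- attr(lv, "ground_truth")
  expect_equal(gt$analytic_volume_cm3[1], 4 * pi * 20 * 15 * 40 / 3 / 1000)
  for (i in 1:2) {
    rel <- abs(label_volume(lv, gt$label[i]) - gt$analytic_volume_cm3[i]) /
      gt$analytic_volume_cm3[i]
    expect_lt(rel, 0.02)
  }
  # volume is additive: labels + background fill the grid exactly
  total <- sum(vapply(gt$label, function(l) label_volume(lv, l), numeric(1)))
  background <- sum(lv$array == 0) * prod(lv$spacing) / 1000
  expect_equal(total + background, prod(dim(lv$array)) * prod(lv$spacing) / 1000)
})

test_that("overlapping shapes with different labels are rejected", {
  ps <- phantom_spec(c(30, 30, 30), c(1, 1, 1), list(
    phantom_shape("cuboid", 1, "A", center = c(15, 15, 15), dim = c(10, 10, 10)),
    phantom_shape("cuboid", 2, "B", center = c(18, 15, 15), dim = c(10, 10, 10))))
  expect_error(make_phantom(ps), "overlap")
})

test_that("bone length equals rod length and is rotation invariant", {
  rod <- function(angles) {
    ps <- phantom_spec(c(120, 120, 120), c(1, 1, 1), list(
      phantom_shape("cylinder", 1, "tibia", kind = "bone",
                    center = c(60, 60, 60), dim = c(5, 100), angles = angles)))
    bone_length(make_phantom(ps), "tibia")
  }
  straight <- rod(c(0, 0, 0))
  expect_equal(straight, 10.0, tolerance = 0.1)           # one voxel
  rotated <- rod(c(pi / 6, pi / 5, 0))
  voxel_diag <- sqrt(3) / 10                              # cm
  expect_lt(abs(rotated - straight), voxel_diag)

  # sphere: any principal axis gives the diameter
  ps <- phantom_spec(c(60, 60, 60), c(1, 1, 1), list(
    phantom_shape("ellipsoid", 1, "head", kind = "bone",
                  center = c(30, 30, 30), dim = c(20, 20, 20))))
  expect_equal(bone_length(make_phantom(ps), "head"), 4.0, tolerance = 0.1)

  # fewer than 2 voxels is degenerate
  arr <- array(0L, c(5, 5, 5)); arr[3, 3, 3] <- 1L
  lv <- as_label_volume(arr, c(1, 1, 1),
                        data.frame(label = 1, code = "tibia", kind = "bone"))
  expect_error(bone_length(lv, "tibia"), "degenerate")
})

test_that("relative volumes divide by the ten-muscle total and sum to one", {
  rec <- reference_mean_record("boy", "infant")
  r <- relative_volumes(rec[1, ])
  expect_equal(unname(r[["SOL"]]), 6.7 / 31.0, tolerance = 1e-12)
  expect_equal(sum(r), 1, tolerance = 1e-9)

  equal <- setNames(rep(3.2, 10), leg_muscles())
  expect_equal(unname(relative_volumes(equal)), rep(0.1, 10))

  # scale invariance
  v <- setNames(stats::runif(10, 1, 50), leg_muscles())
  expect_equal(relative_volumes(v * 17.3), relative_volumes(v), tolerance = 1e-12)

  v_bad <- v; v_bad["POP"] <- 0
  expect_error(relative_volumes(v_bad), "incomplete record")
  expect_error(relative_volumes(v[-1]), "incomplete record")
})

test_that("volume records from a phantom leg are internally consistent", {
  shapes <- lapply(seq_along(leg_muscles()), function(i) {
    phantom_shape("cuboid", i, leg_muscles()[i],
                  center = c(10 + 12 * ((i - 1) %% 5), 15 + 25 * ((i - 1) %/% 5), 40),
                  dim = c(8, 8, 30 + i))
  })
  shapes <- c(shapes, list(
    phantom_shape("cylinder", 11, "tibia", kind = "bone",
                  center = c(78, 30, 40), dim = c(6, 70))))
  lv <- make_phantom(phantom_spec(c(90, 60, 80), c(1, 1, 1), shapes))
  vr <- volume_record(lv, id = "PH1")
  expect_equal(sum(vr$relative), 1, tolerance = 1e-9)
  expect_equal(unname(vr$volumes["tibia"]),
               attr(lv, "ground_truth")$analytic_volume_cm3[11], tolerance = 0.03)
  expect_equal(vr$tibia_length, 7.0, tolerance = 0.15)
  expect_true(is.na(vr$fibula_length))
})

test_that("label volumes survive a NIfTI round trip", {
  ps <- phantom_spec(c(25, 20, 30), c(1, 1.5, 2), list(
    phantom_shape("cuboid", 1, "SOL", center = c(12, 15, 30), dim = c(10, 9, 20)),
    phantom_shape("cylinder", 2, "tibia", kind = "bone",
                  center = c(5, 5, 30), dim = c(3, 50))))
  lv <- make_phantom(ps)
  path <- file.path(withr::local_tempdir(), "phantom.nii.gz")
  write_label_volume(lv, path)
  lv2 <- read_label_volume(path)
  expect_identical(lv2$array, lv$array)
  expect_equal(lv2$spacing, lv$spacing, tolerance = 1e-6)
  expect_equal(lv2$labels, lv$labels)
  expect_equal(attr(lv2, "ground_truth")$analytic_volume_cm3,
               attr(lv, "ground_truth")$analytic_volume_cm3)
  expect_equal(label_volume(lv2, "SOL"), label_volume(lv, "SOL"))
})

test_that("group summaries follow the reference layout and conventions", {
  co <- toy_cohort(n = 13, age = c(0.1, seq(5.2, 14.5, length.out = 12)))
  co$age[13] <- 3.2                     # falls in no band
  s <- summarize_groups(co)

  # single-row stratum: mean = min = max = value, SD flagged undefined
  one <- s[s$band == "infant" & s$variable == "SOL", ]
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 1)
  expect_true(is.na(one$sd))
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)

  # linearity: mean TSURAE = mean LG + mean MG + mean SOL, exactly
  for (bd in unique(s$band)) for (sx in unique(s$sex)) {
    g <- s[s$band == bd & s$sex == sx, ]
    if (!"TSURAE" %in% g$variable) next
    pick <- function(v) g$mean[g$variable == v]
    expect_equal(pick("TSURAE"), pick("LG") + pick("MG") + pick("SOL"),
                 tolerance = 1e-12)
    expect_equal(pick("TOTAL"),
                 sum(vapply(leg_muscles(), pick, numeric(1))), tolerance = 1e-12)
  }

  # out-of-band ages are reported, not dropped
  expect_true("unbinned" %in% s$band)
  expect_equal(unique(s$n[s$band == "unbinned"]), 1)

  # excluded rows are omitted
  co$included[1] <- FALSE
  s2 <- summarize_groups(co)
  expect_false("infant" %in% s2$band)
})

test_that("TOTAL and TSURAE are derived, never stored", {
  co <- toy_cohort(n = 6)
  expect_false(any(c("TOTAL", "TSURAE", "V_TOTAL") %in% names(co)))
  expect_equal(total_volume(co),
               rowSums(as.matrix(co[, paste0("V_", leg_muscles())])))
  expect_equal(tsurae_volume(co),
               co$V_LG + co$V_MG + co$V_SOL)
})
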