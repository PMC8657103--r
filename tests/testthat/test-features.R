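test_that("discretize anchors bins at the in-mask minimum", {
  h <- discretize(c(0, 24.9, 25, 49), bin_width = 25)
  expect_equal(h$counts, c(2, 2))
  expect_equal(h$edges, c(0, 25, 50))

  # constant values collapse to a single bin regardless of width
  for (w in c(1, 10, 100))
    expect_equal(discretize(rep(7.5, 13), w)$counts, 13)

  # conservation: counts always sum to the voxel count
  for (s in 1:10) {
    v <- rnorm(sample(5:200, 1), sd = 50)
    expect_equal(sum(discretize(v, 25)$counts), length(v))
  }
  expect_error(discretize(numeric(0), 25), "empty")
  expect_error(discretize(1:3, 0), "positive")
})

test_that("hand-computed features on {1,2,2,3}", {
  f <- histogram_features(c(1, 2, 2, 3), bin_width = 1)
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["root_mean_square"]), sqrt(4.5))
  expect_equal(unname(f["variance"]), 0.5)  # population convention
  expect_equal(unname(f["standard_deviation"]), sqrt(0.5))
  # bins anchored at 1, width 1: counts (1, 2, 1) -> sum p^2 = 0.375
  expect_equal(unname(f["uniformity"]), 0.0625 + 0.25 + 0.0625)
})

test_that("constant patch: uniformity 1, entropy 0, variance 0, range 0", {
  p <- voxel_patch(array(42, dim = c(2, 3, 3)),
                   array(1, dim = c(2, 3, 3)), c(1, 1, 1))
  f <- extract_features(p)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["range"]), 0)
  expect_true(is.nan(f["skewness"]) && is.nan(f["kurtosis"]))
})

test_that("every feature matches the brute-force oracle on random patches", {
  for (s in 1:50) {
    p <- random_patch(s)
    f <- extract_features(p, bin_width = 25)
    o <- naive_features(p$intensities[p$mask], bin_width = 25)
    for (nm in histogram_feature_names()) {
      denom <- max(abs(o[nm]), 1)
      expect_lt(abs(f[nm] - o[nm]) / denom, 1e-9,
                label = sprintf("patch %d feature %s rel err", s, nm))
    }
  }
})

test_that("RMS identity and shift behaviour", {
  for (s in 1:20) {
    p <- random_patch(s + 100)
    f <- extract_features(p)
    expect_equal(unname(f["root_mean_square"]^2),
                 unname(f["mean"]^2 + f["variance"]),
                 tolerance = 1e-9)
    # adding a constant shifts location features, leaves spread untouched
    p2 <- p; p2$intensities <- p$intensities + 37.5
    f2 <- extract_features(p2)
    for (nm in c("mean", "median", "minimum", "maximum", "percentile_2_5",
                 "percentile_97_5"))
      expect_equal(unname(f2[nm]), unname(f[nm] + 37.5), tolerance = 1e-9)
    for (nm in c("variance", "uniformity", "entropy", "range",
                 "interquartile_range"))
      expect_equal(unname(f2[nm]), unname(f[nm]), tolerance = 1e-9)
  }
})

test_that("features depend only on in-mask voxels", {
  p <- random_patch(999)
  f <- extract_features(p)
  p2 <- p
  p2$intensities[!p2$mask] <- 1e6  # scramble background
  expect_equal(extract_features(p2), f)
})

test_that("volume is voxel count times voxel volume", {
  m <- array(0, dim = c(2, 5, 2)); m[1, 1:5, 1] <- 1; m[2, 1:5, 1] <- 1
  expect_equal(compute_volume(m, c(1, 1, 2)), 20)       # 10 voxels
  m2 <- array(1, dim = c(10, 10, 10))
  expect_equal(compute_volume(m2, c(0.625, 0.7, 0.7)), 1000 * 0.30625)
  expect_error(compute_volume(array(0, dim = c(2, 2, 2)), c(1, 1, 1)),
               "empty")
})

test_that("2.5D area follows the square-contour convention", {
  single <- array(0, dim = c(1, 3, 3)); single[1, 2, 2] <- 1
  expect_equal(area_2_5d(single, c(2, 1, 1)), 8)  # 4 mm perimeter x 2 mm

  # two identical slices double the single-slice value
  twosl <- array(0, dim = c(2, 4, 4))
  twosl[1, 2:3, 2:3] <- 1; twosl[2, 2:3, 2:3] <- 1
  onesl <- array(0, dim = c(1, 4, 4)); onesl[1, 2:3, 2:3] <- 1
  expect_equal(area_2_5d(twosl, c(1, 1, 1)), 2 * area_2_5d(onesl, c(1, 1, 1)))

  # doubling in-plane spacing doubles the area
  p <- random_patch(5)
  sp2 <- p$spacing * c(1, 2, 2)
  expect_equal(area_2_5d(p$mask, sp2), 2 * area_2_5d(p$mask, p$spacing))
  expect_error(area_2_5d(array(0, dim = c(1, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("plain-text patch round-trip preserves everything", {
  p <- random_patch(42)
  f <- file.path(tempdir(), "patch_rt.csv")
  write_patch(p, f)
  q <- read_patch(f)
  expect_equal(q$intensities, p$intensities)
  expect_equal(array(as.logical(q$mask), dim(p$mask)), p$mask)
  expect_equal(q$spacing, p$spacing)
  unlink(f)
})

test_that("voxel_patch validates its invariants", {
  a <- array(0, dim = c(2, 2, 2))
  expect_error(voxel_patch(a, array(0, dim = c(2, 2, 2)), c(1, 1, 1)),
               "foreground")
  expect_error(voxel_patch(a, array(1, dim = c(2, 2, 1)), c(1, 1, 1)),
               "shape")
  expect_error(voxel_patch(a, array(1, dim = c(2, 2, 2)), c(1, 0, 1)),
               "positive")
})
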