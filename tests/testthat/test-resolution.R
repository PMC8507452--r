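test_that("Gaussian fits recover exact profiles and the FWHM identity", {
  x <- seq(-30, 30, by = 2)
  prof <- list(positions = x, values = 5 * exp(-x^2 / (2 * 2^2)))
  ft <- fit_gaussian_fwhm(prof)
  expect_equal(ft$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-4)
  expect_equal(ft$fwhm / ft$sigma, 2.354820045, tolerance = 1e-9)
  # a constant offset is absorbed without changing the width
  prof$values <- prof$values + 10
  ft2 <- fit_gaussian_fwhm(prof)
  expect_equal(ft2$fwhm, ft$fwhm, tolerance = 1e-6)
  expect_equal(ft2$offset, 10, tolerance = 1e-6)
  expect_error(fit_gaussian_fwhm(list(positions = x,
                                      values = rep(1, length(x)))), "peak")
})

test_that("noisy Gaussian profiles are recovered within 2% on average", {
  set.seed(51)
  x <- seq(-30, 30, by = 2)
  truth <- 2 * sqrt(2 * log(2)) * 4
  est <- vapply(1:50, function(i) {
    yv <- 10 * exp(-x^2 / (2 * 4^2)) + rnorm(length(x), 0, 0.5)
    fit_gaussian_fwhm(list(positions = x, values = yv))$fwhm
  }, numeric(1))
  expect_equal(mean(est), truth, tolerance = 0.02)
})

test_that("profile extraction locates the peak before sampling", {
  vol <- blob_volume(center = c(6, -4), sigma = c(5, 5))
  # deliberately wrong nominal center within the search radius
  px <- extract_line_profile(vol, c(2, 0), "x")
  py <- extract_line_profile(vol, c(2, 0), "y")
  expect_equal(max(px$values), max(py$values)) # same peak sample
  expect_lt(abs(px$positions[which.max(px$values)] - 6), vol$spacing[1] / 2 + 1e-9)
  expect_lt(abs(py$positions[which.max(py$values)] - (-4)), vol$spacing[2] / 2 + 1e-9)
  # averaging identical slices equals a single slice
  p1 <- extract_line_profile(vol, c(6, -4), "x", slice_range = 5)
  p5 <- extract_line_profile(vol, c(6, -4), "x", slice_range = 3:7)
  expect_equal(p1$values, p5$values)
})

test_that("measured FWHM grows in quadrature under extra smoothing", {
  vol <- blob_volume(sigma = c(4, 4))
  f0 <- fit_gaussian_fwhm(extract_line_profile(vol, c(0, 0), "x"))$fwhm
  sm <- butterworth_filter(vol, order = 4, critical_frequency = 0.35)
  f1 <- fit_gaussian_fwhm(extract_line_profile(sm, c(0, 0), "x"))$fwhm
  expect_gte(f1^2, f0^2 * 0.999)
  expect_gt(f1, f0)
})

test_that("fwhm_table produces one row per line, direction and volume", {
  vols <- list("cam1.AC" = blob_volume(center = c(5, 5)),
               "cam2.AC" = blob_volume(center = c(5, 5)))
  specs <- list(A = line_source_spec("A", c(5, 5)))
  tab <- fwhm_table(vols, specs)
  expect_equal(nrow(tab), 2 * 1 * 2)
  expect_setequal(tab$realization, c("cam1", "cam2"))
  expect_setequal(tab$direction, c("x", "y"))
  # identical volumes give identical rows
  expect_equal(tab$fwhm_mm[tab$realization == "cam1"],
               tab$fwhm_mm[tab$realization == "cam2"])
})

test_that("elliptical fits report orientation and radial misalignment", {
  # isotropic blob: degenerate, no misalignment defined
  iso <- fit_ellipse_orientation(blob_volume(sigma = c(5, 5),
                                             center = c(0, 40)), c(0, 40))
  expect_true(iso$degenerate)
  expect_true(is.na(iso$radial_misalignment))
  # blob at (0, 40) elongated along y = its radial (toward-CoR) direction
  rad <- fit_ellipse_orientation(blob_volume(sigma = c(8, 4),
                                             center = c(0, 40),
                                             theta = pi / 2), c(0, 40))
  expect_false(rad$degenerate)
  expect_gte(rad$major_fwhm, rad$minor_fwhm)
  expect_lt(rad$radial_misalignment, 10)
  # rotating the blob 90 degrees makes it tangential
  tang <- fit_ellipse_orientation(blob_volume(sigma = c(4, 8),
                                              center = c(0, 40),
                                              theta = pi / 2), c(0, 40))
  expect_gt(tang$radial_misalignment, 80)
})

test_that("TNC measurement matches construction on ground-truth maps", {
  g <- small_grid(24, 12, 4.42)
  act <- g; act$values[] <- 1
  ctr <- c(12, 12, 6)
  les <- lesion_voxels(ctr, 1, dim(g$values))
  act$values[les] <- 8
  # explicit VOIs fully inside lesion / background
  tum <- les[1:4, , drop = FALSE]
  bg <- as.matrix(expand.grid(3:7, 3:5, 6))
  r <- measure_tnc(act, ctr, tum, bg)
  expect_equal(r$ratio, 8)
  # uniform volume gives unity with the default VOIs
  unif <- g; unif$values[] <- 2.5
  expect_equal(measure_tnc(unif, ctr)$ratio, 1)
  # partial-volume smoothing keeps the measured TNC strictly inside (1, 8)
  smv <- butterworth_filter(act, order = 4, critical_frequency = 0.4)
  rs <- measure_tnc(smv, ctr, tum, bg)
  expect_gt(rs$ratio, 1); expect_lt(rs$ratio, 8)
  expect_error(measure_tnc(act, ctr, tum, tum), "disjoint")
})

test_that("default VOIs are the documented 4 + 15 voxel construction", {
  g <- small_grid(24, 12, 4.42)
  set.seed(52)
  g$values[] <- runif(length(g$values))
  vois <- default_tnc_vois(g, c(12, 12, 6))
  expect_equal(nrow(vois$tumour), 4)
  expect_equal(nrow(vois$background), 15)
  keys <- function(m) apply(m, 1, paste, collapse = ",")
  expect_length(intersect(keys(vois$tumour), keys(vois$background)), 0)
  # all 19 voxels are non-corner members of the 3x3x3 box
  all19 <- rbind(vois$tumour, vois$background)
  off <- abs(sweep(all19, 2, c(12, 12, 6), "-"))
  expect_true(all(rowSums(off) <= 2))
  expect_true(all(off <= 1))
})
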