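osem_fixture <- function(n = 24, nz = 12, spacing = 5, n_angles = 8) {
  grid <- voxel_volume(array(0, c(n, n, nz)), spacing)
  mu <- make_cylinder_attenuation(50, 50, spacing, "water",
                                  dim = dim(grid$values))
  mu$origin <- grid$origin
  truth <- grid
  truth$values[10, 14, 6] <- 40
  truth$values[16, 9, 6] <- 25
  truth$values[12:14, 12:14, 5:7] <- 4
  sm <- system_model(pixel_size = spacing, matrix_size = n)
  angles <- projection_angles(n_angles)
  list(grid = grid, mu = mu, truth = truth, sm = sm, angles = angles)
}

test_that("subset partitioning interleaves angles and validates divisibility", {
  ss <- make_subsets(projection_angles(120), 10)
  expect_length(ss, 10)
  expect_true(all(lengths(ss) == 12))
  ang <- projection_angles(120)
  for (g in ss) expect_equal(unique(diff(ang[g])), 30) # 10 subsets x 3 deg
  expect_equal(sort(unlist(ss)), 1:120)
  expect_length(make_subsets(projection_angles(4), 4), 4)
  expect_true(all(lengths(make_subsets(projection_angles(4), 4)) == 1))
  expect_error(make_subsets(projection_angles(120), 7), "divide")
})

test_that("OSEM with one subset reproduces plain MLEM", {
  fx <- osem_fixture()
  y <- forward_project_set(fx$truth, fx$mu, fx$angles, fx$sm, 250,
                           attenuation_on = TRUE, psf_on = FALSE)
  rec <- osem_reconstruct(y, fx$mu, fx$sm,
                          recon_config("AC", n_iterations = 3, n_subsets = 1),
                          grid = fx$grid)
  # reference MLEM with the same operators, written out longhand
  support <- fx$mu$values > 0.5 * max(fx$mu$values)
  x <- array(0, dim(fx$grid$values)); x[support] <- 1
  sens <- back_project(projection_set(
    array(1, dim(y$frames)), fx$angles, 250, 5), fx$mu, NA, fx$grid,
    attenuation_on = TRUE)$values
  for (it in 1:3) {
    xv <- voxel_volume(x, fx$grid$spacing, fx$grid$origin)
    fp <- forward_project_set(xv, fx$mu, fx$angles, fx$sm, 250,
                              attenuation_on = TRUE, psf_on = FALSE)
    ratio <- y$frames / (fp$frames + 1e-10)
    ratio[y$frames == 0 & fp$frames <= 1e-10] <- 1
    bp <- back_project(projection_set(ratio, fx$angles, 250, 5), fx$mu, NA,
                       fx$grid, attenuation_on = TRUE)$values
    upd <- array(0, dim(x)); pos <- sens > 0
    upd[pos] <- bp[pos] / sens[pos]
    x <- x * upd
  }
  expect_equal(rec$values, x, tolerance = 1e-10)
})

test_that("OSEM iterates stay nonnegative and reduce NRMSE on matched data", {
  fx <- osem_fixture()
  y <- forward_project_set(fx$truth, fx$mu, fx$angles, fx$sm, 250,
                           attenuation_on = TRUE, psf_on = FALSE)
  nrmse <- vapply(c(1, 2, 4, 8, 16), function(k) {
    rec <- osem_reconstruct(y, fx$mu, fx$sm,
                            recon_config("AC", n_iterations = k,
                                         n_subsets = 4),
                            grid = fx$grid)
    expect_true(all(rec$values >= 0))
    sqrt(mean((rec$values - fx$truth$values)^2)) /
      sqrt(mean(fx$truth$values^2))
  }, numeric(1))
  expect_true(all(diff(nrmse) < 0))
})

test_that("one full MLEM pass preserves total counts through the sensitivity", {
  fx <- osem_fixture()
  y <- forward_project_set(fx$truth, fx$mu, fx$angles, fx$sm, 250,
                           attenuation_on = TRUE, psf_on = FALSE)
  rec <- osem_reconstruct(y, fx$mu, fx$sm,
                          recon_config("AC", n_iterations = 1, n_subsets = 1),
                          grid = fx$grid)
  sens <- back_project(projection_set(
    array(1, dim(y$frames)), fx$angles, 250, 5), fx$mu, NA, fx$grid,
    attenuation_on = TRUE)$values
  expect_equal(sum(rec$values * sens), sum(y$frames), tolerance = 0.02)
})

test_that("all-zero projections return a flat volume with a warning", {
  fx <- osem_fixture()
  y <- projection_set(array(0, c(24, 12, 8)), fx$angles, 250, 5)
  expect_warning(
    rec <- osem_reconstruct(y, fx$mu, fx$sm,
                            recon_config("AC", n_subsets = 4),
                            grid = fx$grid),
    "zero")
  expect_true(all(rec$values %in% c(0, 1)))
})

test_that("Butterworth filter has unit DC gain and the closed-form rolloff", {
  expect_equal(butterworth_gain(0.48, 10, 0.48), 1 / sqrt(2))
  expect_equal(butterworth_gain(0.96, 10, 0.48), (1 + 2^20)^(-1 / 2))
  expect_equal(butterworth_gain(0.96, 10, 0.48), 9.8e-4, tolerance = 1e-2)
  const <- voxel_volume(array(3.7, c(16, 16, 8)), 4.42)
  expect_equal(butterworth_filter(const, 10, 0.48)$values, const$values,
               tolerance = 1e-12)
  set.seed(41)
  noisy <- voxel_volume(array(rpois(16 * 16 * 8, 20), c(16, 16, 8)), 4.42)
  sm <- butterworth_filter(noisy, 10, 0.48)
  expect_lt(sd(sm$values), sd(noisy$values)) # low-pass reduces noise
  expect_equal(mean(sm$values), mean(noisy$values), tolerance = 1e-10) # DC kept
  expect_true(all(Im(sm$values) == 0))
  expect_error(butterworth_filter(const, 10, 0), "critical")
})

test_that("resolution recovery beats plain AC on blurred data", {
  # projections carry the distance-dependent blur; modelling it in the
  # reconstruction must narrow a point source
  fx <- osem_fixture(n = 32, nz = 12, n_angles = 12)
  truth <- fx$grid; truth$values[16, 22, 6] <- 100
  y <- forward_project_set(truth, fx$mu, fx$angles, fx$sm, 250,
                           attenuation_on = TRUE, psf_on = TRUE)
  widths <- vapply(c("AC", "ACRR"), function(v) {
    rec <- osem_reconstruct(y, fx$mu, fx$sm,
                            recon_config(v, n_iterations = 2, n_subsets = 4),
                            grid = fx$grid)
    pr <- extract_line_profile(rec, c(voxel_coords(fx$grid, 1)[16],
                                      voxel_coords(fx$grid, 2)[22]),
                               "y", slice_range = 6)
    fit_gaussian_fwhm(pr)$fwhm
  }, numeric(1))
  expect_lt(widths[["ACRR"]], widths[["AC"]])
})
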