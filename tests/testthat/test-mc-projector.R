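sim_setup <- function(n = 32, nz = 16, spacing = 5) {
  grid <- voxel_volume(array(0, c(n, n, nz)), spacing)
  list(grid = grid,
       system = system_model(pixel_size = spacing, matrix_size = n),
       protocol = acquisition_protocol(n_projections = 8, orbit_radius = 200,
                                       frame_duration = 10))
}

test_that("expected-mode simulation is reproducible and conserves counts", {
  s <- sim_setup()
  act <- s$grid; act$values[16, 16, 8] <- 1000
  mu <- make_cylinder_attenuation(70, 70, 5, "water", dim = dim(s$grid$values))
  mu$origin <- s$grid$origin
  p1 <- simulate_projections(act, mu, s$system, s$protocol, 2e4, seed = 5,
                             noise = "expected")
  p2 <- simulate_projections(act, mu, s$system, s$protocol, 2e4, seed = 5,
                             noise = "expected")
  expect_identical(p1$frames, p2$frames)
  p3 <- simulate_projections(act, mu, s$system, s$protocol, 2e4, seed = 6,
                             noise = "expected")
  expect_false(identical(p1$frames, p3$frames))
  # detected counts cannot exceed emitted photons
  total_emitted <- sum(act$values) * s$protocol$frame_duration *
    sum(in111_lines()$intensity)
  expect_lt(sum(p1$frames), total_emitted)
  expect_error(simulate_projections(s$grid, mu, s$system, s$protocol, 100),
               "zero")
})

test_that("a point source at the CoR projects to the detector center", {
  s <- sim_setup()
  act <- s$grid
  ctr <- c(16, 16, 8)
  act$values[ctr[1], ctr[2], ctr[3]] <- 1000
  mu_air <- voxel_volume(array(0, dim(s$grid$values)), 5)
  ps <- simulate_projections(act, mu_air, s$system, s$protocol, 5e4, seed = 2,
                             noise = "expected", scatter = FALSE)
  uc <- voxel_coords(s$grid, 2); vc <- voxel_coords(s$grid, 3)
  src_u <- uc[16]; src_v <- vc[8]
  for (a in seq_along(ps$angles)) {
    fr <- ps$frames[, , a]
    cu <- sum(outer(uc, rep(1, length(vc))) * fr) / sum(fr)
    cv <- sum(outer(rep(1, length(uc)), vc) * fr) / sum(fr)
    expect_lt(abs(cv - src_v), 5) # within one pixel axially
    expect_lt(abs(cu) - abs(src_u), 5)
  }
})

test_that("total-count uncertainty scales as one over sqrt histories", {
  s <- sim_setup(24, 8)
  act <- s$grid
  act$values[8:16, 8:16, 4] <- 10
  mu <- make_cylinder_attenuation(55, 40, 5, "water", dim = dim(s$grid$values))
  mu$origin <- s$grid$origin
  nh <- c(1000, 4000, 16000)
  relse <- vapply(nh, function(n) {
    tot <- vapply(1:6, function(r) {
      sum(simulate_projections(act, mu, s$system, s$protocol, n,
                               seed = 100 + 7 * r + n, noise = "expected",
                               angles = c(0, 90))$frames)
    }, numeric(1))
    sd(tot) / mean(tot)
  }, numeric(1))
  slope <- coef(lm(log(relse) ~ log(nh)))[2]
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.7)
})

test_that("with scatter disabled the MC projector matches the analytic one", {
  s <- sim_setup()
  act <- s$grid
  act$values[10:22, 10:22, 6:10] <- runif(13 * 13 * 5, 0, 5)
  mu <- make_cylinder_attenuation(70, 70, 5, "water", dim = dim(s$grid$values))
  mu$origin <- s$grid$origin
  angles <- c(0, 45, 120, 270)
  ps <- simulate_projections(act, mu, s$system, s$protocol, 2e6, seed = 9,
                             noise = "expected", scatter = FALSE,
                             angles = angles)
  # equivalent deterministic projection with the same efficiency factors
  lines <- in111_lines()
  scale_tot <- 0
  frames <- array(0, dim(ps$frames))
  for (i in seq_len(nrow(lines))) {
    e <- lines$energy_keV[i]
    mu_e <- voxel_volume(mu$values * mu_linear("water", e) /
                           mu_linear("water", 171), mu$spacing, mu$origin)
    w <- s$protocol$frame_duration * lines$intensity[i] *
      s$system$sensitivity *
      window_acceptance_prob(s$system, e, s$protocol$energy_windows)
    for (a in seq_along(angles)) {
      frames[, , a] <- frames[, , a] + w *
        forward_project(act, mu_e, angles[a], s$system, 200, psf_on = TRUE)
    }
  }
  rms <- sqrt(mean((ps$frames - frames)^2)) / sqrt(mean(frames^2))
  expect_lt(rms, 0.05)
})

test_that("raw projection addition is exact and checks geometry", {
  s <- sim_setup()
  act <- s$grid; act$values[16, 16, 8] <- 100
  mu <- voxel_volume(array(0.01, dim(s$grid$values)), 5)
  a <- simulate_projections(act, mu, s$system, s$protocol, 1e4, seed = 1)
  b <- simulate_lesion_raw(act, mu, s$system, s$protocol, 1e4, seed = 2)
  ab <- add_raw(a, b)
  expect_equal(ab$frames, a$frames + b$frames)
  expect_equal(sum(ab$frames), sum(a$frames) + sum(b$frames))
  # zero lesion raw data is an identity
  z <- b; z$frames[] <- 0
  expect_equal(add_raw(a, z)$frames, a$frames)
  bad <- projection_set(a$frames[, , 1:4], a$angles[1:4], a$orbit_radius,
                        a$pixel_size)
  expect_error(add_raw(a, bad), "match")
})

test_that("scatter adds a low-energy tail and grows with object size", {
  set.seed(31)
  # point source at the center of water cylinders of two radii
  frac_scatter <- vapply(c(40, 90), function(rad) {
    g <- voxel_volume(array(0, c(40, 40, 20)), 5)
    mu <- make_cylinder_attenuation(rad, 90, 5, "water", dim = c(40, 40, 20))
    mu$origin <- g$origin
    act <- g; act$values[20, 20, 10] <- 1
    em <- sample_emission(act, in111_lines(), 40000)
    esc <- transport_histories(em, mu)
    sc <- esc$n_scatters > 0
    # scattered escapees lose energy
    expect_lt(mean(esc$energy[sc]), mean(esc$energy[!sc]))
    mean(sc)
  }, numeric(1))
  expect_gt(frac_scatter[2], frac_scatter[1])
})
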