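test_that("emission sampling respects the activity map and line intensities", {
  set.seed(21)
  g <- small_grid(16, 8, 5)
  g$values[5, 9, 4] <- 2
  em <- sample_emission(g, in111_lines(), 4000)
  expect_true(all(em$voxel[, 1] == 5 & em$voxel[, 2] == 9 & em$voxel[, 3] == 4))
  # positions fall inside that voxel
  ctr <- c(voxel_coords(g, 1)[5], voxel_coords(g, 2)[9], voxel_coords(g, 3)[4])
  expect_true(all(abs(sweep(em$pos, 2, ctr, "-")) <= 2.5 + 1e-9))
  # energy split follows the intensity ratio (binomial 4 SE)
  p245 <- mean(em$energy > 200)
  p_true <- 0.941 / (0.907 + 0.941)
  expect_lt(abs(p245 - p_true), 4 * sqrt(p_true * (1 - p_true) / 4000))
  expect_error(sample_emission(small_grid(8), in111_lines(), 10), "zero")
})

test_that("emission directions are isotropic", {
  set.seed(22)
  n <- 40000
  d <- isotropic_directions(n)
  expect_equal(rowSums(d^2), rep(1, n), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(sqrt(sum(colMeans(d)^2)), 3 / sqrt(n))
})

test_that("Woodcock free paths follow the truncated exponential law", {
  set.seed(23)
  muv <- mu_linear("water", 171)
  mu <- voxel_volume(array(muv, c(60, 60, 60)), 5) # 30 cm cube
  n <- 60000
  pos <- matrix(0, n, 3)
  dir <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  st <- step_photon(pos, dir, rep(171, n), mu)
  d_cm <- (st$pos[, 1] - 0) / 10
  # photons travel along +x; escape at L = 15 cm from the start
  L <- 15
  p_esc <- exp(-muv * L)
  expect_lt(abs(mean(st$escaped) - p_esc),
            4 * sqrt(p_esc * (1 - p_esc) / n))
  # conditional mean free path of interacting photons (truncated exponential)
  m_true <- 1 / muv - L * p_esc / (1 - p_esc)
  m_obs <- mean(d_cm[st$interacted])
  se <- sd(d_cm[st$interacted]) / sqrt(sum(st$interacted))
  expect_lt(abs(m_obs - m_true), 4 * se)
  # nearly all interactions at these energies are Compton
  expect_gt(mean(st$compton[st$interacted]), 0.98)
})

test_that("photons escape a vacuum map without interacting", {
  mu <- voxel_volume(array(0, c(12, 12, 12)), 5)
  st <- step_photon(matrix(0, 50, 3), isotropic_directions(50), rep(171, 50), mu)
  expect_true(all(st$escaped))
  expect_false(any(st$interacted))
})

test_that("Compton kinematics follow the closed-form energy shift", {
  d <- matrix(c(1, 0, 0), 1)
  # theta = 0 leaves the energy unchanged
  cs0 <- compton_scatter(d, 171, costheta = 1)
  expect_equal(cs0$energy, 171)
  expect_equal(as.numeric(cs0$dir), c(1, 0, 0), tolerance = 1e-12)
  # backscatter of 171 keV
  cs180 <- compton_scatter(d, 171, costheta = -1)
  expect_equal(cs180$energy, 171 / (1 + 2 * 171 / 511), tolerance = 1e-9)
  expect_equal(cs180$energy, 102.44, tolerance = 1e-4)
  # scattered directions honor the sampled polar angle
  set.seed(24)
  n <- 500
  dirs <- isotropic_directions(n)
  ct <- runif(n, -1, 1)
  cs <- compton_scatter(dirs, rep(171, n), costheta = ct)
  expect_equal(rowSums(cs$dir * dirs), ct, tolerance = 1e-9)
})

test_that("sampled scattering angles match the Klein-Nishina density", {
  set.seed(25)
  kn_pdf <- function(m, E) {
    a <- E / 511; r <- 1 / (1 + a * (1 - m))
    r^2 * (r + 1 / r - (1 - m^2))
  }
  norm <- integrate(kn_pdf, -1, 1, E = 171)$value
  n <- 200000
  s <- sample_kn_costheta(rep(171, n))
  # moment check against numeric integration
  m1 <- integrate(function(m) m * kn_pdf(m, 171), -1, 1)$value / norm
  expect_lt(abs(mean(s) - m1), 4 * sd(s) / sqrt(n))
  # chi-squared over 10 equal-width bins
  breaks <- seq(-1, 1, length.out = 11)
  obs <- table(cut(s, breaks))
  pr <- vapply(seq_len(10), function(i) {
    integrate(kn_pdf, breaks[i], breaks[i + 1], E = 171)$value / norm
  }, numeric(1))
  chi2 <- sum((as.numeric(obs) - n * pr)^2 / (n * pr))
  expect_lt(chi2, qchisq(0.999, df = 9))
})

test_that("analog detection implements the acceptance-cone collimator", {
  sm <- system_model(pixel_size = 4)
  u_coords <- v_coords <- (-15:16 - 0.5) * 4
  w <- list(c(171, 0.2))
  # photon travelling parallel to the detector plane is never accepted
  r <- detect(matrix(c(0, 0, 0), 1), matrix(c(0, 1, 0), 1), 171, sm, 0, 250,
              w, u_coords, v_coords, 4)
  expect_equal(nrow(r), 0)
  # normal incidence is accepted into the photopeak window
  set.seed(26)
  r2 <- detect(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1), 171, sm, 0, 250,
               w, u_coords, v_coords, 4)
  expect_equal(nrow(r2), 1)
  # acceptance fraction of isotropic photons matches the cone solid angle
  n <- 200000
  dirs <- isotropic_directions(n)
  hits <- detect(matrix(0, n, 3), dirs, rep(171, n), sm, 0, 250,
                 list(c(171, 0.9)), u_coords, v_coords, 4)
  frac <- nrow(hits) / n
  expect_equal(frac, collimator_acceptance_fraction(sm), tolerance = 0.1)
})
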