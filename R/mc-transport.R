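#' Photon-history Monte Carlo transport
#'
#' Vectorized photon transport over a voxel grid: emission sampling
#' proportional to voxel activity, free-path sampling by Woodcock delta
#' tracking against a majorant attenuation coefficient, Compton scattering by
#' Klein-Nishina rejection sampling, photoelectric absorption, and detection
#' through a parallel-hole acceptance-cone collimator model with Gaussian
#' energy blurring and energy-window discrimination.
#'
#' Because the phantoms contain only water and air, the attenuation map at
#' any photon energy factorizes into a spatial relative-density map times the
#' water attenuation at that energy; a single reference map (at 171 keV)
#' therefore drives transport at all energies.
#'
#' Batches of photons are represented column-wise: `pos` (n x 3, mm), `dir`
#' (n x 3, unit vectors), `energy` (keV), `weight`.
#'
#' @name mc_transport
NULL

.REF_ENERGY <- 171

# relative density map (water = 1) from a reference attenuation map
.relative_density <- function(mu_ref) {
  mu_ref$values / mu_linear("water", .REF_ENERGY)
}

#' Sample photon emissions from an activity map
#'
#' Emission voxels are sampled proportional to voxel activity, positions
#' uniformly within the voxel, directions isotropically, energies from the
#' emission lines proportional to their intensities. Uses the current RNG
#' state.
#'
#' @param activity a [voxel_volume]; must contain positive values.
#' @param emission_lines data.frame with `energy_keV` and `intensity`.
#' @param n number of photons.
#' @return list with `pos`, `dir`, `energy`, `voxel` (n x 3 index matrix).
#' @export
sample_emission <- function(activity, emission_lines, n) {
  tot <- sum(activity$values)
  if (tot <= 0) stop("activity map is all zero")
  d <- dim(activity$values)
  flat <- sample.int(length(activity$values), n, replace = TRUE,
                     prob = as.numeric(activity$values))
  vox <- arrayInd(flat, d)
  pos <- sweep((vox - 1) + matrix(runif(3 * n), n, 3) - 0.5, 2,
               activity$spacing, "*")
  pos <- sweep(pos, 2, activity$origin, "+")
  dir <- isotropic_directions(n)
  energy <- emission_lines$energy_keV[
    sample.int(nrow(emission_lines), n, replace = TRUE,
               prob = emission_lines$intensity)]
  list(pos = pos, dir = dir, energy = energy, voxel = vox)
}

#' Isotropic unit direction vectors
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
isotropic_directions <- function(n) {
  cz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(1 - cz^2)
  cbind(st * cos(phi), st * sin(phi), cz)
}

# voxel index of positions; NA rows for positions outside the grid
.pos_to_voxel <- function(pos, grid) {
  d <- dim(grid$values)
  idx <- round(sweep(sweep(pos, 2, grid$origin, "-"), 2, grid$spacing, "/")) + 1
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
    idx[, 3] < 1 | idx[, 3] > d[3]
  idx[bad, ] <- NA_real_
  idx
}

#' Transport a photon batch to its next real interaction (Woodcock tracking)
#'
#' Free paths are sampled against the majorant attenuation of the grid at each
#' photon's energy; tentative collisions are accepted with probability
#' mu(x)/mu_max (null-collision rejection otherwise), which samples the
#' correct heterogeneous free-path distribution without ray tracing voxel
#' boundaries.
#'
#' @param pos,dir,energy photon batch (see [mc_transport]).
#' @param mu_ref reference attenuation [voxel_volume] at 171 keV.
#' @param max_steps safety cap on delta-tracking steps.
#' @return list with updated `pos`, logical `escaped`, and for the
#'   interacting photons the interaction type `compton` (logical; FALSE means
#'   photoelectric absorption).
#' @export
step_photon <- function(pos, dir, energy, mu_ref, max_steps = 10000) {
  n <- nrow(pos)
  rel <- .relative_density(mu_ref)
  rel_max <- max(rel)
  mu_w <- mu_linear("water", energy)       # cm^-1 per photon
  mu_maj <- mu_w * rel_max
  escaped <- rep(FALSE, n)
  interacted <- rep(FALSE, n)
  active <- rep(TRUE, n)
  if (rel_max <= 0) {
    return(list(pos = pos, escaped = rep(TRUE, n),
                interacted = rep(FALSE, n), compton = rep(FALSE, n)))
  }
  steps <- 0
  while (any(active) && steps < max_steps) {
    steps <- steps + 1
    ia <- which(active)
    # free path in cm against the majorant, advance in mm
    s_cm <- rexp(length(ia)) / mu_maj[ia]
    pos[ia, ] <- pos[ia, , drop = FALSE] + dir[ia, , drop = FALSE] * (s_cm * 10)
    vox <- .pos_to_voxel(pos[ia, , drop = FALSE], mu_ref)
    out <- is.na(vox[, 1])
    escaped[ia[out]] <- TRUE
    active[ia[out]] <- FALSE
    ins <- which(!out)
    if (length(ins)) {
      iv <- ia[ins]
      mu_here <- rel[vox[ins, , drop = FALSE]] * mu_w[iv]
      acc <- runif(length(iv)) < mu_here / mu_maj[iv]
      interacted[iv[acc]] <- TRUE
      active[iv[acc]] <- FALSE
    }
  }
  # classify accepted interactions: Compton vs photoelectric
  ii <- which(interacted)
  p_c <- mu_linear("water", energy[ii], component = "compton") /
    mu_linear("water", energy[ii], component = "total")
  compton <- rep(FALSE, n)
  compton[ii] <- runif(length(ii)) < p_c
  list(pos = pos, escaped = escaped, interacted = interacted,
       compton = compton)
}

#' Sample Klein-Nishina scattering angles
#'
#' Rejection sampling of cos(theta) from the Klein-Nishina angular density at
#' each photon's energy.
#'
#' @param energy_keV incident energies (vectorized).
#' @return numeric vector of cos(theta).
#' @export
sample_kn_costheta <- function(energy_keV) {
  n <- length(energy_keV)
  a <- energy_keV / 511
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  # density (unnormalized): f(mu) = r^2 (r + 1/r - (1 - mu^2)), r = 1/(1+a(1-mu))
  # bounded by its value at mu = 1, which is 2
  while (length(todo)) {
    m <- runif(length(todo), -1, 1)
    r <- 1 / (1 + a[todo] * (1 - m))
    f <- r^2 * (r + 1 / r - (1 - m^2))
    keep <- runif(length(todo)) < f / 2
    out[todo[keep]] <- m[keep]
    todo <- todo[!keep]
  }
  out
}

#' Compton-scatter a photon batch
#'
#' Rotates each direction by a Klein-Nishina-sampled polar angle (uniform
#' azimuth) and updates the energy by the Compton relation
#' `E' = E / (1 + (E/511)(1 - cos theta))`.
#'
#' @param dir n x 3 unit direction vectors.
#' @param energy keV.
#' @param costheta optional pre-sampled cos(theta); sampled from
#'   Klein-Nishina when `NULL`.
#' @return list with new `dir` and `energy`.
#' @export
compton_scatter <- function(dir, energy, costheta = NULL) {
  n <- length(energy)
  if (is.null(costheta)) costheta <- sample_kn_costheta(energy)
  new_energy <- energy / (1 + (energy / 511) * (1 - costheta))
  st <- sqrt(pmax(0, 1 - costheta^2))
  phi <- runif(n, 0, 2 * pi)
  # orthonormal frame around each incident direction
  u <- dir
  helper <- cbind(as.numeric(abs(u[, 1]) < 0.9), as.numeric(abs(u[, 1]) >= 0.9), 0)
  e1 <- cbind(helper[, 2] * u[, 3] - helper[, 3] * u[, 2],
              helper[, 3] * u[, 1] - helper[, 1] * u[, 3],
              helper[, 1] * u[, 2] - helper[, 2] * u[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  newdir <- u * costheta + (e1 * cos(phi) + e2 * sin(phi)) * st
  newdir <- newdir / sqrt(rowSums(newdir^2))
  list(dir = newdir, energy = new_energy)
}

#' Analog detection of escaped photons at one camera angle
#'
#' Geometric parallel-hole acceptance (direction within the collimator
#' acceptance cone of the detector normal), propagation to the detector plane
#' at the orbit radius, intrinsic-resolution Gaussian displacement, energy
#' blurring, energy-window discrimination, and binning to detector pixels.
#'
#' @param pos,dir,energy escaped-photon batch.
#' @param system a [system_model].
#' @param angle_deg camera angle.
#' @param orbit_radius mm.
#' @param windows list of `(center_keV, width_fraction)`.
#' @param nu,nv detector dimensions in pixels; pixel size and axial center
#'   are taken from `pixel_size` and `v_coords`.
#' @param pixel_size detector pixel size, mm.
#' @param u_coords,v_coords pixel-center coordinates, mm.
#' @return data.frame with `iu`, `iv` (pixel indices) for detected photons.
#' @export
detect <- function(pos, dir, energy, system, angle_deg, orbit_radius,
                   windows, u_coords, v_coords, pixel_size) {
  th <- angle_deg * pi / 180
  nrm <- c(cos(th), sin(th), 0)
  tng <- c(-sin(th), cos(th), 0)
  cosang <- dir[, 1] * nrm[1] + dir[, 2] * nrm[2]
  ok <- cosang >= cos(collimator_half_angle(system))
  if (!any(ok)) return(data.frame(iu = integer(0), iv = integer(0)))
  p <- pos[ok, , drop = FALSE]; dd <- dir[ok, , drop = FALSE]
  e <- energy[ok]; ca <- cosang[ok]
  t <- (orbit_radius - (p[, 1] * nrm[1] + p[, 2] * nrm[2])) / ca
  hit <- p + dd * t
  u <- hit[, 1] * tng[1] + hit[, 2] * tng[2]
  v <- hit[, 3]
  s_int <- system$intrinsic_fwhm * FWHM_TO_SIGMA
  u <- u + rnorm(length(u), 0, s_int)
  v <- v + rnorm(length(v), 0, s_int)
  e_blur <- e + rnorm(length(e), 0, energy_sigma(system, e))
  in_window <- rep(FALSE, length(e))
  for (w in windows) {
    b <- energy_window_bounds(w[[1]], w[[2]])
    in_window <- in_window | (e_blur >= b[["lo"]] & e_blur <= b[["hi"]])
  }
  iu <- round((u - u_coords[1]) / pixel_size) + 1
  iv <- round((v - v_coords[1]) / pixel_size) + 1
  keep <- in_window & iu >= 1 & iu <= length(u_coords) &
    iv >= 1 & iv <= length(v_coords)
  data.frame(iu = as.integer(iu[keep]), iv = as.integer(iv[keep]))
}
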