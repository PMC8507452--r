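#' Gamma-camera system model
#'
#' Bundles the detector and collimator parameters that the analytic and Monte
#' Carlo projectors share. Defaults describe a NaI(Tl) camera with a
#' medium-energy general-purpose parallel-hole collimator; all values are
#' configurable.
#'
#' The distance-dependent system resolution combines the intrinsic detector
#' blur with the geometric collimator blur in quadrature:
#' `FWHM(d) = sqrt(FWHM_int^2 + FWHM_coll(d)^2)` with
#' `FWHM_coll(d) = hole_diameter * (L_eff + d) / L_eff` and effective hole
#' length `L_eff = hole_length - 2/septal_mu` (septal penetration shortening).
#'
#' @param intrinsic_fwhm intrinsic spatial resolution, mm FWHM.
#' @param hole_diameter,hole_length,septal_thickness collimator geometry, mm.
#' @param septal_mu linear attenuation of the septal material (lead) at the
#'   photopeak energy, cm^-1.
#' @param crystal_thickness mm.
#' @param pixel_size detector pixel size, mm.
#' @param matrix_size detector matrix (n x n).
#' @param energy_resolution_fraction FWHM/E at 140 keV; scales as 1/sqrt(E).
#' @param sensitivity counts per emitted photon reaching the detector solid
#'   angle; `NULL` uses the collimator acceptance-cone solid-angle fraction.
#' @return object of class `system_model`.
#' @export
system_model <- function(intrinsic_fwhm = 3.9,
                         hole_diameter = 3.0, hole_length = 58,
                         septal_thickness = 1.05, septal_mu = 16.6,
                         crystal_thickness = 15.9,
                         pixel_size = 2.21, matrix_size = 256,
                         energy_resolution_fraction = 0.098,
                         sensitivity = NULL) {
  stopifnot(intrinsic_fwhm > 0, hole_diameter > 0, hole_length > 0,
            septal_thickness > 0, septal_mu > 0, crystal_thickness > 0,
            pixel_size > 0, matrix_size >= 1,
            energy_resolution_fraction > 0, energy_resolution_fraction < 0.3)
  sm <- structure(list(
    intrinsic_fwhm = intrinsic_fwhm, hole_diameter = hole_diameter,
    hole_length = hole_length, septal_thickness = septal_thickness,
    septal_mu = septal_mu, crystal_thickness = crystal_thickness,
    pixel_size = pixel_size, matrix_size = as.integer(matrix_size),
    energy_resolution_fraction = energy_resolution_fraction
  ), class = "system_model")
  sm$sensitivity <- if (is.null(sensitivity)) collimator_acceptance_fraction(sm)
                    else sensitivity
  sm
}

#' Acceptance half-angle and solid-angle fraction of the parallel-hole model
#'
#' The collimator is modelled as an acceptance cone: photons within
#' `atan(hole_diameter / L_eff)` of the detector normal pass. The solid-angle
#' fraction `(1 - cos(alpha)) / 2` of isotropic emissions falling inside the
#' cone is the geometric sensitivity of this model.
#'
#' @param system a [system_model].
#' @return for [collimator_half_angle()], radians; for
#'   [collimator_acceptance_fraction()], the dimensionless fraction.
#' @export
collimator_half_angle <- function(system) {
  atan(system$hole_diameter / effective_hole_length(system))
}

#' @rdname collimator_half_angle
#' @export
collimator_acceptance_fraction <- function(system) {
  (1 - cos(collimator_half_angle(system))) / 2
}

#' @keywords internal
effective_hole_length <- function(system) {
  # 2/mu in cm -> mm
  system$hole_length - 2 / system$septal_mu * 10
}

#' System spatial resolution at a source-to-collimator distance
#'
#' @param system a [system_model].
#' @param distance_mm distance from the source plane to the collimator face,
#'   mm (vectorized, >= 0).
#' @return FWHM in mm ([system_fwhm()]) or Gaussian sigma in mm ([sigma_at()]).
#' @export
#' @examples
#' sm <- system_model()
#' system_fwhm(sm, c(0, 100, 250))
system_fwhm <- function(system, distance_mm) {
  if (any(distance_mm < 0)) stop("distance must be >= 0")
  leff <- effective_hole_length(system)
  fwhm_coll <- system$hole_diameter * (leff + distance_mm) / leff
  sqrt(system$intrinsic_fwhm^2 + fwhm_coll^2)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' @rdname system_fwhm
#' @export
sigma_at <- function(system, distance_mm) {
  system_fwhm(system, distance_mm) * FWHM_TO_SIGMA
}

#' Energy resolution (Gaussian sigma, keV) at a photon energy
#'
#' Fractional FWHM scales as 1/sqrt(E) from its 140 keV reference value.
#' @param system a [system_model].
#' @param energy_keV photon energy (vectorized).
#' @return sigma in keV.
#' @export
energy_sigma <- function(system, energy_keV) {
  frac <- system$energy_resolution_fraction * sqrt(140 / energy_keV)
  frac * energy_keV * FWHM_TO_SIGMA
}

#' Energy window bounds
#'
#' @param center_keV window center.
#' @param width_fraction full fractional width, in (0, 1).
#' @return numeric length-2: `(lo, hi)` keV.
#' @export
#' @examples
#' energy_window_bounds(171, 0.20) # 153.9, 188.1
energy_window_bounds <- function(center_keV, width_fraction) {
  if (width_fraction <= 0 || width_fraction >= 1) {
    stop("width_fraction must be in (0, 1)")
  }
  c(lo = center_keV * (1 - width_fraction / 2),
    hi = center_keV * (1 + width_fraction / 2))
}

#' Probability that a photon of given energy is recorded in any window
#'
#' The detected energy is the true energy blurred by the camera's Gaussian
#' energy response; the acceptance probability is the Gaussian mass falling
#' inside the union of the (non-overlapping) windows.
#'
#' @param system a [system_model].
#' @param energy_keV true photon energy (vectorized).
#' @param windows list of `(center, width_fraction)` pairs.
#' @return acceptance probability in `[0, 1]`.
#' @export
window_acceptance_prob <- function(system, energy_keV, windows) {
  s <- energy_sigma(system, energy_keV)
  p <- 0
  for (w in windows) {
    b <- energy_window_bounds(w[[1]], w[[2]])
    p <- p + pnorm(b[["hi"]], energy_keV, s) - pnorm(b[["lo"]], energy_keV, s)
  }
  pmin(p, 1)
}

#' Acquisition protocol
#'
#' @param n_projections number of evenly spaced projections over 360 degrees.
#' @param orbit_radius CoR-to-collimator-face distance, mm (circular orbit).
#' @param frame_duration seconds per projection.
#' @param energy_windows list of `(center_keV, width_fraction)` pairs.
#' @param emission_lines data.frame with `energy_keV`, `intensity` columns.
#' @param start_angle first projection angle, degrees.
#' @return object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(n_projections = 120, orbit_radius = 250,
                                 frame_duration = 30,
                                 energy_windows = list(c(171, 0.20), c(245, 0.20)),
                                 emission_lines = in111_lines(),
                                 start_angle = 0) {
  stopifnot(n_projections >= 1, orbit_radius > 0, frame_duration > 0,
            all(emission_lines$intensity > 0), all(emission_lines$intensity <= 1))
  structure(list(n_projections = as.integer(n_projections),
                 orbit_radius = orbit_radius, frame_duration = frame_duration,
                 energy_windows = energy_windows,
                 emission_lines = emission_lines,
                 start_angle = start_angle),
            class = "acquisition_protocol")
}

#' Evenly spaced projection angles over 360 degrees
#'
#' @param n_projections number of projections (>= 1).
#' @param start_angle first angle, degrees.
#' @return numeric vector of angles in degrees.
#' @export
#' @examples
#' projection_angles(4) # 0 90 180 270
projection_angles <- function(n_projections, start_angle = 0) {
  stopifnot(n_projections >= 1)
  start_angle + (seq_len(n_projections) - 1) * 360 / n_projections
}
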