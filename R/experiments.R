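#' End-to-end study drivers
#'
#' Desk-scale versions of the two simulation studies the package is built
#' around: (1) the triple-line resolution phantom (in water or air) imaged,
#' reconstructed with the three OSEM variants and measured for FWHM and
#' elliptical-artifact orientation; (2) the torso/liver phantom with a
#' projection-space inserted spherical lesion, reconstructed with AC OSEM
#' (plus Butterworth post filter) and MC OSEM and measured for
#' tumour-to-normal contrast. Default problem sizes (64 x 64 x 32 grid,
#' 4.42 mm voxels, 60 projections, 2e6 photon histories) keep a full
#' realization to minutes on one CPU.
#'
#' @name experiments
NULL

#' Default scaled-down study setup
#'
#' @param n_transverse,n_axial grid dimensions.
#' @param spacing voxel size, mm.
#' @param n_projections projections over 360 degrees.
#' @param orbit_radius mm.
#' @return list with `grid`, `system`, `protocol`.
#' @export
study_setup <- function(n_transverse = 64, n_axial = 32, spacing = 4.42,
                        n_projections = 60, orbit_radius = 250) {
  grid <- voxel_volume(array(0, c(n_transverse, n_transverse, n_axial)),
                       spacing)
  system <- system_model(pixel_size = spacing, matrix_size = n_transverse)
  protocol <- acquisition_protocol(n_projections = n_projections,
                                   orbit_radius = orbit_radius)
  list(grid = grid, system = system, protocol = protocol)
}

#' Triple-line resolution experiment
#'
#' Simulates a Monte Carlo acquisition of the triple-line phantom (in a
#' water-filled cylinder or in air), reconstructs with the requested OSEM
#' variants, and measures per-line X/Y FWHM. For phantoms in air the
#' attenuation-corrected variants become their non-corrected counterparts.
#'
#' @param seed integer master seed.
#' @param medium `"water"` or `"air"`.
#' @param variants subset of `c("AC", "ACRR", "MC")`.
#' @param setup from [study_setup()].
#' @param n_histories photon histories for the acquisition simulation.
#' @param activity_per_mm line activity concentration (decays/s/mm).
#' @param cylinder_radius,cylinder_length phantom body dimensions, mm.
#' @param line_specs list of [line_source_spec]; default
#'   [triple_line_specs()].
#' @param mc_histories_per_subset MC OSEM forward budget.
#' @return list with `recons` (named list of [voxel_volume]), `fwhm`
#'   (data.frame from [fwhm_table()]), `data` ([projection_set]),
#'   `line_specs`, `mu`, `setup`, `seed`.
#' @export
run_resolution_experiment <- function(seed = 1, medium = "water",
                                      variants = c("AC", "ACRR", "MC"),
                                      setup = study_setup(),
                                      n_histories = 2e6,
                                      activity_per_mm = 5e3,
                                      cylinder_radius = 108,
                                      cylinder_length = 138,
                                      line_specs = NULL,
                                      mc_histories_per_subset = 2e5,
                                      n_subsets = 10) {
  grid <- setup$grid; system <- setup$system; protocol <- setup$protocol
  d <- dim(grid$values)
  if (is.null(line_specs)) {
    line_specs <- triple_line_specs(axis_extent = min(110, cylinder_length - 10))
  }
  mu <- make_cylinder_attenuation(cylinder_radius, cylinder_length,
                                  grid$spacing, medium, dim = d)
  mu$origin <- grid$origin
  activity <- make_triple_line_activity(line_specs, activity_per_mm, grid)
  data <- simulate_projections(activity, mu, system, protocol,
                               n_histories = n_histories, seed = seed,
                               noise = "poisson")
  attenuation_on <- medium == "water"
  recons <- list()
  for (v in variants) {
    cfg <- recon_config(v, attenuation = attenuation_on,
                        n_subsets = n_subsets,
                        mc_histories_per_subset = mc_histories_per_subset,
                        seed = seed + 1000L)
    recons[[v]] <- osem_reconstruct(data, mu, system, cfg, grid = grid,
                                    protocol = protocol)
  }
  names(recons) <- paste0("s", seed, ".", variants)
  fw <- fwhm_table(recons, line_specs)
  names(recons) <- variants
  list(recons = recons, fwhm = fw, data = data, line_specs = line_specs,
       mu = mu, setup = setup, seed = seed)
}

#' Elliptical-artifact measurement on a reconstruction
#'
#' Fits elliptical Gaussians to each line source of a reconstructed
#' triple-line volume and reports the major-axis misalignment from the
#' source-to-CoR direction.
#'
#' @param recon a reconstructed [voxel_volume].
#' @param line_specs list of [line_source_spec].
#' @return data.frame with `line`, `radius_mm` (distance from CoR),
#'   `major_fwhm`, `minor_fwhm`, `orientation`, `radial_misalignment`,
#'   `degenerate`.
#' @export
measure_ellipses <- function(recon, line_specs) {
  do.call(rbind, lapply(line_specs, function(sp) {
    ef <- fit_ellipse_orientation(recon, sp$center_xy)
    data.frame(line = sp$label,
               radius_mm = sqrt(sum(sp$center_xy^2)),
               major_fwhm = ef$major_fwhm, minor_fwhm = ef$minor_fwhm,
               orientation = ef$orientation,
               radial_misalignment = ef$radial_misalignment,
               degenerate = ef$degenerate)
  }))
}

#' Lesion-insertion contrast experiment
#'
#' Simulates the torso/liver background acquisition, inserts a spherical
#' lesion of true TNC 8 by adding its separately simulated raw projections,
#' reconstructs with AC OSEM + Butterworth post filter and with MC OSEM, and
#' measures the TNC of both reconstructions with the default VOIs.
#'
#' @param seed integer master seed (placement and acquisition noise).
#' @param setup from [study_setup()].
#' @param n_histories background acquisition histories.
#' @param n_histories_lesion lesion raw-data histories.
#' @param background_conc,liver_conc activity concentrations
#'   (decays/s/voxel).
#' @param tnc_true true lesion-to-liver concentration ratio.
#' @param butterworth `list(order, fc)` for the AC post filter.
#' @param mc_histories_per_subset MC OSEM forward budget.
#' @return list with `tnc` (named numeric for `AC` and `MC`), `recons`,
#'   `lesion` (the `lesion_spec`), `data`, `phantom`, `seed`.
#' @export
run_lesion_experiment <- function(seed = 1, setup = study_setup(),
                                  n_histories = 2e6,
                                  n_histories_lesion = 2e5,
                                  background_conc = 20, liver_conc = 60,
                                  tnc_true = 8,
                                  butterworth = list(order = 10, fc = 0.48),
                                  mc_histories_per_subset = 2e5,
                                  n_subsets = 10) {
  grid <- setup$grid; system <- setup$system; protocol <- setup$protocol
  ph <- make_liver_phantom(grid, background_conc, liver_conc)
  lesion <- place_lesion(ph$liver_mask, rng_seed = seed, radius_voxels = 1,
                         tnc_true = tnc_true)
  excess <- lesion_activity(lesion, liver_conc, grid)
  background <- simulate_projections(ph$activity, ph$mu, system, protocol,
                                     n_histories = n_histories, seed = seed,
                                     noise = "poisson")
  lesion_raw <- simulate_lesion_raw(excess, ph$mu, system, protocol,
                                    n_histories = n_histories_lesion,
                                    seed = seed + 500L, noise = "poisson")
  data <- add_raw(background, lesion_raw)
  cfg_ac <- recon_config("AC", n_subsets = n_subsets,
                         postfilter = list(type = "butterworth",
                                           order = butterworth$order,
                                           fc = butterworth$fc))
  cfg_mc <- recon_config("MC", n_subsets = n_subsets,
                         mc_histories_per_subset = mc_histories_per_subset,
                         seed = seed + 1000L)
  rec_ac <- osem_reconstruct(data, ph$mu, system, cfg_ac, grid = grid,
                             protocol = protocol)
  rec_mc <- osem_reconstruct(data, ph$mu, system, cfg_mc, grid = grid,
                             protocol = protocol)
  tnc <- c(AC = measure_tnc(rec_ac, lesion$center_voxel)$ratio,
           MC = measure_tnc(rec_mc, lesion$center_voxel)$ratio)
  list(tnc = tnc, recons = list(AC = rec_ac, MC = rec_mc), lesion = lesion,
       data = data, phantom = ph, seed = seed)
}
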