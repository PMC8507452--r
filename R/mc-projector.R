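#' Monte Carlo projection simulator
#'
#' Generates SPECT projection data from an activity map by photon-history
#' Monte Carlo. Emissions are sampled proportional to voxel activity; the
#' primary (unscattered) component of each sampled emission batch is
#' propagated to the detector through the attenuated, distance-dependently
#' blurred system model, while scattered photons are transported explicitly
#' (Woodcock tracking + Klein-Nishina scattering) and tallied at each
#' collision vertex with their energy-window acceptance, then propagated the
#' same way (a collision-estimator variance-reduction scheme; the analog
#' acceptance-cone detector model is available through [detect] and
#' [transport_histories] for validation). `"expected"` mode returns the
#' history-weight accumulations used as the OSEM forward step; `"poisson"`
#' mode draws counts for acquisition realism.
#'
#' @name mc_projector
NULL

#' Transport emitted photons through the object (analog histories)
#'
#' Runs the full scatter chain for a batch of emitted photons and returns the
#' photons that escape the grid, with their final position, direction, energy
#' and scatter order. Photons are terminated by photoelectric absorption,
#' energy below `energy_cutoff`, or exceeding `max_scatters` scatters.
#'
#' @param em emission batch from [sample_emission()].
#' @param mu_ref reference attenuation [voxel_volume] at 171 keV.
#' @param max_scatters,energy_cutoff termination controls (keV).
#' @param vertex_tally optional function called as
#'   `vertex_tally(voxel_index_matrix, energy_after_scatter)` at every Compton
#'   vertex (used by the collision estimator).
#' @return list with `pos`, `dir`, `energy`, `n_scatters` of escaped photons.
#' @export
transport_histories <- function(em, mu_ref, max_scatters = 10,
                                energy_cutoff = 50, vertex_tally = NULL) {
  pos <- em$pos; dir <- em$dir; energy <- em$energy
  n_sc <- rep(0L, nrow(pos))
  out_pos <- out_dir <- NULL
  out_energy <- out_nsc <- NULL
  alive <- rep(TRUE, nrow(pos))
  for (k in 0:max_scatters) {
    if (!any(alive)) break
    ia <- which(alive)
    st <- step_photon(pos[ia, , drop = FALSE], dir[ia, , drop = FALSE],
                      energy[ia], mu_ref)
    pos[ia, ] <- st$pos
    esc <- ia[st$escaped]
    out_pos <- rbind(out_pos, pos[esc, , drop = FALSE])
    out_dir <- rbind(out_dir, dir[esc, , drop = FALSE])
    out_energy <- c(out_energy, energy[esc])
    out_nsc <- c(out_nsc, n_sc[esc])
    alive[esc] <- FALSE
    # photoelectric absorption
    alive[ia[st$interacted & !st$compton]] <- FALSE
    # Compton scatter survivors
    ic <- ia[st$compton]
    if (length(ic)) {
      cs <- compton_scatter(dir[ic, , drop = FALSE], energy[ic])
      dir[ic, ] <- cs$dir
      energy[ic] <- cs$energy
      n_sc[ic] <- n_sc[ic] + 1L
      if (!is.null(vertex_tally)) {
        vox <- .pos_to_voxel(pos[ic, , drop = FALSE], mu_ref)
        keep <- !is.na(vox[, 1])
        vertex_tally(vox[keep, , drop = FALSE], energy[ic][keep])
      }
      dead <- ic[energy[ic] < energy_cutoff]
      alive[dead] <- FALSE
    }
  }
  list(pos = out_pos, dir = out_dir, energy = out_energy, n_scatters = out_nsc)
}

#' Simulate SPECT projections by Monte Carlo
#'
#' @param activity source [voxel_volume] (relative units, interpreted as
#'   decays per second per voxel).
#' @param mu attenuation [voxel_volume] at 171 keV (scaled internally to
#'   other photon energies through the water attenuation curve).
#' @param system a [system_model].
#' @param protocol an [acquisition_protocol] (windows, emission lines,
#'   frame duration, orbit).
#' @param n_histories photon histories to sample (>= 1).
#' @param seed integer seed; recorded in the metadata.
#' @param noise `"poisson"` draws counts; `"expected"` returns expectations.
#' @param scatter include the scattered component.
#' @param angles camera angles, degrees; default all protocol angles.
#' @param orbit_radius mm; default from protocol.
#' @return a [projection_set].
#' @export
simulate_projections <- function(activity, mu, system, protocol,
                                 n_histories, seed = 1,
                                 noise = c("poisson", "expected"),
                                 scatter = TRUE, angles = NULL,
                                 orbit_radius = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_histories >= 1)
  if (sum(activity$values) <= 0) stop("activity map is all zero")
  if (!same_grid(activity, mu)) stop("activity and mu grids differ")
  if (is.null(angles)) {
    angles <- projection_angles(protocol$n_projections, protocol$start_angle)
  }
  if (is.null(orbit_radius)) orbit_radius <- protocol$orbit_radius
  d <- dim(activity$values)
  lines <- protocol$emission_lines
  windows <- protocol$energy_windows
  total_emissions <- sum(activity$values) * protocol$frame_duration *
    sum(lines$intensity)
  with_seed(seed, {
    em <- sample_emission(activity, lines, as.integer(n_histories))
    w_hist <- total_emissions / n_histories
    eff <- system$sensitivity # counts per photon headed into the acceptance cone
    # per-energy primary source histograms
    frames <- array(0, c(d[2], d[3], length(angles)))
    src_chunks <- list()
    for (e in unique(lines$energy_keV)) {
      sel <- em$energy == e
      if (!any(sel)) next
      flat <- em$voxel[sel, 1] + (em$voxel[sel, 2] - 1) * d[1] +
        (em$voxel[sel, 3] - 1) * d[1] * d[2]
      hist_e <- array(tabulate(flat, nbins = prod(d)), d)
      scale_e <- w_hist * eff * window_acceptance_prob(system, e, windows)
      mu_e <- voxel_volume(mu$values * mu_linear("water", e) /
                             mu_linear("water", .REF_ENERGY),
                           mu$spacing, mu$origin)
      src_chunks[[length(src_chunks) + 1]] <-
        list(vol = voxel_volume(hist_e * scale_e, activity$spacing,
                                activity$origin),
             mu = mu_e)
    }
    # scattered component: collision-estimator tally per Compton vertex
    if (scatter && max(mu$values) > 1e-4) {
      tally <- new.env(parent = emptyenv())
      tally$D <- array(0, d)
      transport_histories(em, mu, vertex_tally = function(vox, e_after) {
        wa <- window_acceptance_prob(system, e_after, windows)
        flat <- vox[, 1] + (vox[, 2] - 1) * d[1] + (vox[, 3] - 1) * d[1] * d[2]
        agg <- rowsum(wa, flat)
        idx <- as.integer(rownames(agg))
        tally$D[idx] <- tally$D[idx] + as.numeric(agg)
      })
      if (sum(tally$D) > 0) {
        src_chunks[[length(src_chunks) + 1]] <-
          list(vol = voxel_volume(tally$D * w_hist * eff, activity$spacing,
                                  activity$origin),
               mu = mu)
      }
    }
    for (ch in src_chunks) {
      if (sum(ch$vol$values) == 0) next
      for (a in seq_along(angles)) {
        frames[, , a] <- frames[, , a] +
          forward_project(ch$vol, ch$mu, angles[a], system, orbit_radius,
                          attenuation_on = TRUE, psf_on = TRUE)
      }
    }
    if (noise == "poisson") {
      frames <- array(rpois(length(frames), frames), dim(frames))
    }
    projection_set(frames, angles, orbit_radius, activity$spacing[2],
                   meta = list(generator = "mc", seed = seed, noise = noise,
                               scatter = scatter, windows = windows,
                               n_histories = n_histories))
  })
}

#' Simulate the raw projections of a lesion alone
#'
#' Convenience wrapper: Monte Carlo projections of the lesion's excess
#' activity through the full object attenuation, for projection-space
#' addition to a background acquisition.
#'
#' @param lesion_excess [voxel_volume] of excess activity (see
#'   [lesion_activity()]).
#' @inheritParams simulate_projections
#' @return a [projection_set].
#' @export
simulate_lesion_raw <- function(lesion_excess, mu, system, protocol,
                                n_histories, seed = 1,
                                noise = "poisson") {
  ps <- simulate_projections(lesion_excess, mu, system, protocol,
                             n_histories, seed, noise = noise)
  ps$meta$generator <- "mc-lesion"
  ps
}

#' Add two raw projection sets frame-wise
#'
#' @param background,lesion matching [projection_set]s.
#' @return a [projection_set] whose counts are the frame-wise sum; metadata
#'   records both provenances.
#' @export
add_raw <- function(background, lesion) {
  if (!isTRUE(all.equal(background$angles, lesion$angles)) ||
      !isTRUE(all.equal(background$orbit_radius, lesion$orbit_radius)) ||
      !identical(dim(background$frames), dim(lesion$frames))) {
    stop("projection geometries do not match")
  }
  projection_set(background$frames + lesion$frames, background$angles,
                 background$orbit_radius, background$pixel_size,
                 meta = list(background = background$meta,
                             lesion = lesion$meta))
}
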