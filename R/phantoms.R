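#' Phantom generators
#'
#' All inputs to the simulation/reconstruction pipeline are generated
#' internally: a triple-line resolution insert (in air, or inside a
#' water-filled Jaszczak-like cylinder) and a torso/liver phantom with an
#' insertable spherical lesion.
#'
#' @name phantoms
NULL

#' Run code with a temporary RNG seed, restoring global RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Line-source specification
#'
#' A thin cylindrical line source in the transverse plane, described by its
#' position relative to the center of rotation (CoR).
#'
#' @param label single character, e.g. "A".
#' @param center_xy length-2 numeric, transverse position (x = anteroposterior,
#'   y = left-right) in mm relative to the CoR.
#' @param diameter inner diameter in mm (> 0); may be sub-voxel.
#' @param axis_extent length of the line along the axial (z) direction, mm.
#' @return object of class `line_source_spec`.
#' @export
line_source_spec <- function(label, center_xy, diameter = 1.0, axis_extent = 120) {
  stopifnot(length(center_xy) == 2, diameter > 0, axis_extent > 0)
  structure(list(label = as.character(label), center_xy = as.numeric(center_xy),
                 diameter = diameter, axis_extent = axis_extent),
            class = "line_source_spec")
}

#' Default triple-line arrangement
#'
#' Three line sources at distinct radial distances from the CoR in a
#' triangular arrangement: line A anterior, 20 mm from the CoR along the
#' anteroposterior (x) axis — i.e. the CoR lies 2 cm posterior to ("below")
#' A in the transverse image — and lines B and C lateral at larger radii.
#' With this arrangement the reconstruction artifact that elongates sources
#' toward the CoR produces a left-right (y) elongation for the lateral
#' lines, while the near-CoR line A is elongated tangentially, which for A
#' is also the y axis. Positions are configurable; only A's 20 mm CoR
#' offset is treated as fixed geometry.
#'
#' @param axis_extent axial length of each line, mm.
#' @return list of three [line_source_spec] objects named A, B, C.
#' @export
triple_line_specs <- function(axis_extent = 120) {
  list(
    A = line_source_spec("A", c(20, 0), axis_extent = axis_extent),
    B = line_source_spec("B", c(-30, -52), axis_extent = axis_extent),
    C = line_source_spec("C", c(-25, 58), axis_extent = axis_extent)
  )
}

#' Cylindrical attenuation map
#'
#' Builds the attenuation map of a water- or air-filled cylinder (a
#' Jaszczak-like phantom body) centered on the CoR, on a regular voxel grid.
#' Voxels whose centers lie inside the cylinder (boundary inclusive) receive
#' the medium's linear attenuation at the requested photon energy; voxels
#' outside receive air.
#'
#' @param radius_mm,length_mm cylinder radius and axial length, mm.
#' @param spacing voxel size, mm (scalar or length 3).
#' @param medium `"water"` or `"air"`.
#' @param energy_keV photon energy for the attenuation values.
#' @param dim grid dimensions (length 3); default covers the cylinder with a
#'   small margin.
#' @return a [voxel_volume] of attenuation values in cm^-1.
#' @export
make_cylinder_attenuation <- function(radius_mm, length_mm, spacing,
                                      medium = c("water", "air"),
                                      energy_keV = 171, dim = NULL) {
  medium <- match.arg(medium)
  stopifnot(radius_mm > 0, length_mm > 0)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(dim)) {
    dim <- c(rep(ceiling(2 * radius_mm / spacing[1]) + 4L, 2L),
             ceiling(length_mm / spacing[3]) + 4L)
  }
  mu <- material_table(energy_keV)
  vol <- voxel_volume(array(mu[["air"]], dim), spacing)
  x <- voxel_coords(vol, 1); y <- voxel_coords(vol, 2); z <- voxel_coords(vol, 3)
  inside_t <- outer(x^2, y^2, "+") <= radius_mm^2
  inside_z <- abs(z) <= length_mm / 2
  v <- vol$values
  for (k in which(inside_z)) v[, , k][inside_t] <- mu[[medium]]
  vol$values <- v
  vol
}

# Per-slice axial coverage (mm) of an interval [z0, z1] by each voxel slab
.z_coverage <- function(zc, dz, z0, z1) {
  pmax(0, pmin(zc + dz / 2, z1) - pmax(zc - dz / 2, z0))
}

#' Rasterize line sources into an activity volume
#'
#' Each line is a disc of the given diameter in the transverse plane, constant
#' along its axial extent (centered axially on the grid). Discs are rasterized
#' with sub-voxel area weighting: a deterministic grid of sample points inside
#' the disc distributes the per-slice activity over the voxels it covers, so
#' total activity equals `activity_per_mm` times total line length exactly
#' (partial end slices included).
#'
#' @param specs list of [line_source_spec] objects.
#' @param activity_per_mm activity per mm of line length, relative units.
#' @param grid a [voxel_volume] defining the target grid (values ignored).
#' @param n_subsamples number of sample points across the disc diameter.
#' @return a [voxel_volume] of activity.
#' @export
make_triple_line_activity <- function(specs, activity_per_mm, grid,
                                      n_subsamples = 16) {
  stopifnot(length(specs) >= 1)
  if (inherits(specs, "line_source_spec")) specs <- list(specs)
  dims <- dim(grid$values)
  out <- array(0, dims)
  x <- voxel_coords(grid, 1); y <- voxel_coords(grid, 2); z <- voxel_coords(grid, 3)
  dz <- grid$spacing[3]
  for (sp in specs) {
    cx <- sp$center_xy[1]; cy <- sp$center_xy[2]
    if (cx < min(x) || cx > max(x) || cy < min(y) || cy > max(y)) {
      stop(sprintf("line %s center (%.1f, %.1f) outside grid", sp$label, cx, cy))
    }
    r <- sp$diameter / 2
    s <- seq(-r, r, length.out = n_subsamples)
    pts <- expand.grid(px = s, py = s)
    pts <- pts[pts$px^2 + pts$py^2 <= r^2, , drop = FALSE]
    ix <- pmin(pmax(round((cx + pts$px - grid$origin[1]) / grid$spacing[1]) + 1, 1), dims[1])
    iy <- pmin(pmax(round((cy + pts$py - grid$origin[2]) / grid$spacing[2]) + 1, 1), dims[2])
    w <- table(factor(paste(ix, iy), levels = unique(paste(ix, iy))))
    w <- w / nrow(pts) # transverse partial-volume fractions, sum to 1
    key <- do.call(rbind, strsplit(names(w), " "))
    ij <- cbind(as.integer(key[, 1]), as.integer(key[, 2]))
    cov <- .z_coverage(z, dz, -sp$axis_extent / 2, sp$axis_extent / 2)
    for (k in which(cov > 0)) {
      out[cbind(ij, k)] <- out[cbind(ij, k)] + activity_per_mm * cov[k] * as.numeric(w)
    }
  }
  voxel_volume(out, grid$spacing, grid$origin)
}

#' Torso/liver background phantom
#'
#' An elliptical-cylinder torso of water-equivalent attenuation containing an
#' ellipsoidal liver region at elevated activity concentration. A stand-in
#' for patient data: its purpose is to provide a realistic-scale attenuating
#' background for lesion-insertion experiments.
#'
#' @param grid a [voxel_volume] defining the target grid.
#' @param background_conc activity concentration of the torso background.
#' @param liver_conc activity concentration inside the liver (>= background).
#' @param torso_semiaxes length-2, transverse semi-axes of the torso, mm.
#' @param liver_center,liver_semiaxes liver ellipsoid center and semi-axes, mm.
#' @param energy_keV photon energy for the attenuation map.
#' @return list with elements `activity`, `mu` (both [voxel_volume]) and
#'   `liver_mask` (logical 3D array).
#' @export
make_liver_phantom <- function(grid, background_conc = 1, liver_conc = 3,
                               torso_semiaxes = c(100, 130),
                               liver_center = c(-15, 50, 0),
                               liver_semiaxes = c(55, 45, 45),
                               energy_keV = 171) {
  stopifnot(liver_conc >= background_conc, background_conc >= 0)
  dims <- dim(grid$values)
  x <- voxel_coords(grid, 1); y <- voxel_coords(grid, 2); z <- voxel_coords(grid, 3)
  X <- array(x, dims); Y <- array(rep(y, each = dims[1]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  torso <- (X / torso_semiaxes[1])^2 + (Y / torso_semiaxes[2])^2 <= 1
  liver <- ((X - liver_center[1]) / liver_semiaxes[1])^2 +
    ((Y - liver_center[2]) / liver_semiaxes[2])^2 +
    ((Z - liver_center[3]) / liver_semiaxes[3])^2 <= 1
  liver <- liver & torso
  mu <- material_table(energy_keV)
  muv <- array(mu[["air"]], dims); muv[torso] <- mu[["water"]]
  act <- array(0, dims); act[torso] <- background_conc; act[liver] <- liver_conc
  list(activity = voxel_volume(act, grid$spacing, grid$origin),
       mu = voxel_volume(muv, grid$spacing, grid$origin),
       liver_mask = liver)
}

#' Voxel set of a small spherical lesion
#'
#' The lesion of radius r voxels is the set of voxels whose center lies
#' within r voxel pitches (Euclidean, in voxel units) of the center voxel;
#' for r = 1 this is the 7-voxel 3D cross.
#'
#' @param center_voxel integer length-3 grid index.
#' @param radius_voxels integer >= 1.
#' @param dims grid dimensions.
#' @return integer matrix of voxel indices (one row per voxel).
#' @export
lesion_voxels <- function(center_voxel, radius_voxels, dims) {
  r <- radius_voxels
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2, , drop = FALSE]
  vox <- cbind(center_voxel[1] + off$dx, center_voxel[2] + off$dy,
               center_voxel[3] + off$dz)
  keep <- vox[, 1] >= 1 & vox[, 1] <= dims[1] & vox[, 2] >= 1 &
    vox[, 2] <= dims[2] & vox[, 3] >= 1 & vox[, 3] <= dims[3]
  vox[keep, , drop = FALSE]
}

#' Randomly place a spherical lesion inside a mask
#'
#' The center is sampled uniformly over mask voxels whose whole
#' radius-neighbourhood lies inside the mask, so the lesion never straddles
#' the organ boundary. Reproducible given the seed.
#'
#' @param liver_mask logical 3D array.
#' @param rng_seed integer seed (recorded in the returned spec).
#' @param radius_voxels lesion radius in voxels.
#' @param tnc_true true tumour-to-normal activity concentration ratio.
#' @return object of class `lesion_spec` with fields `center_voxel`,
#'   `radius_voxels`, `tnc_true`, `rng_seed`.
#' @export
place_lesion <- function(liver_mask, rng_seed, radius_voxels = 1, tnc_true = 8) {
  stopifnot(radius_voxels >= 1, tnc_true > 0)
  dims <- dim(liver_mask)
  cand <- which(liver_mask, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("empty mask")
  r <- radius_voxels
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- as.matrix(off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2, , drop = FALSE])
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    vox <- sweep(off, 2, cand[i, ], "+")
    all(vox >= 1) && all(vox[, 1] <= dims[1]) && all(vox[, 2] <= dims[2]) &&
      all(vox[, 3] <= dims[3]) && all(liver_mask[vox])
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) stop("no admissible lesion center inside mask")
  i <- with_seed(rng_seed, sample.int(nrow(cand), 1))
  structure(list(center_voxel = as.integer(cand[i, ]),
                 radius_voxels = as.integer(radius_voxels),
                 tnc_true = tnc_true, rng_seed = as.integer(rng_seed)),
            class = "lesion_spec")
}

#' Excess-activity volume realizing a lesion
#'
#' Returns the activity to ADD to the background so that the combined
#' concentration over the lesion voxels equals `tnc_true` times the
#' surrounding (normal-tissue) concentration: the excess is
#' `(tnc_true - 1) * background_conc` per lesion voxel.
#'
#' @param spec a `lesion_spec` from [place_lesion()].
#' @param background_conc normal-tissue activity concentration at the lesion
#'   site.
#' @param grid a [voxel_volume] defining the grid.
#' @return a [voxel_volume] of excess activity.
#' @export
lesion_activity <- function(spec, background_conc, grid) {
  dims <- dim(grid$values)
  out <- array(0, dims)
  vox <- lesion_voxels(spec$center_voxel, spec$radius_voxels, dims)
  out[vox] <- (spec$tnc_true - 1) * background_conc
  voxel_volume(out, grid$spacing, grid$origin)
}
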