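#' Voxelized scalar volume
#'
#' The basic 3D container of the package. `values` is a 3D array indexed
#' `[x, y, z]` where x is the anteroposterior axis, y the left-right axis
#' (together the transverse plane) and z the cranio-caudal axis. `spacing`
#' gives the per-axis voxel size in mm and `origin` the physical coordinate
#' (mm) of the center of voxel (1,1,1). Depending on use, values hold
#' activity (relative units), linear attenuation (cm^-1) or reconstructed
#' intensity.
#'
#' @param values 3D numeric array, all finite.
#' @param spacing numeric length-3 (or scalar, recycled), mm, all > 0.
#' @param origin numeric length-3, mm; default centers the grid on (0,0,0),
#'   the center of rotation.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("values must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (!all(spacing > 0)) stop("spacing entries must be > 0")
  if (is.null(origin)) {
    origin <- -(dim(values) - 1) / 2 * spacing
  }
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  value range [%.4g, %.4g], total %.4g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Physical voxel-center coordinates along one axis
#'
#' @param vol a [voxel_volume].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of coordinates in mm.
#' @export
voxel_coords <- function(vol, axis) {
  stopifnot(inherits(vol, "voxel_volume"), axis %in% 1:3)
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

#' Check that two volumes share grid geometry
#' @keywords internal
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Map a physical (mm) coordinate to the nearest voxel index
#' @keywords internal
nearest_voxel <- function(vol, xyz) {
  idx <- round((xyz - vol$origin) / vol$spacing) + 1
  as.integer(pmin(pmax(idx, 1), dim(vol$values)))
}
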