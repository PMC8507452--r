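#' Rotation-based analytic projector
#'
#' Deterministic forward/back projector used by the AC and ACRR OSEM variants
#' and as the PSF-corrected back projector of the MC variant. The volume is
#' rotated (bilinear, implemented as a sparse linear operator) so the detector
#' is axis-aligned; each depth plane is optionally convolved with the
#' distance-dependent Gaussian system PSF and weighted by the cumulative
#' attenuation to the detector, then summed along rays. The back projector
#' applies the exact transpose of the same discrete operator, so the
#' forward/back pair is adjoint by construction.
#'
#' @name projector
NULL

.proj_cache <- new.env(parent = emptyenv())

#' Stack of 2D projection frames
#'
#' @param frames 3D array `[nu, nv, n_angles]` of counts or expected counts.
#' @param angles degrees, one per frame.
#' @param orbit_radius mm.
#' @param pixel_size mm.
#' @param meta named list of provenance (energy windows, seed, generator).
#' @return object of class `projection_set`.
#' @export
projection_set <- function(frames, angles, orbit_radius, pixel_size,
                           meta = list()) {
  frames <- as.array(frames)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (dim(frames)[3] != length(angles)) {
    stop("frame count must equal angle count")
  }
  structure(list(frames = frames, angles = as.numeric(angles),
                 orbit_radius = orbit_radius, pixel_size = pixel_size,
                 meta = meta),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<projection_set> %d frames of %d x %d, pixel %.3g mm, total counts %.4g\n",
              d[3], d[1], d[2], x$pixel_size, sum(x$frames)))
  invisible(x)
}

# Sparse bilinear in-plane rotation operator aligning the detector at angle
# theta (degrees) with the +x axis. Acts on vec'd transverse planes
# (x fastest). Cached per (nx, ny, spacing, angle).
rotation_operator <- function(nx, ny, spacing_xy, angle_deg) {
  key <- sprintf("rot|%d|%d|%.6g|%.6g|%.10g", nx, ny,
                 spacing_xy[1], spacing_xy[2], angle_deg %% 360)
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])
  th <- angle_deg * pi / 180
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  # target rotated-frame pixel centers, in index units about the CoR
  gx <- (seq_len(nx) - cx); gy <- (seq_len(ny) - cy)
  xp <- rep(gx, times = ny); yp <- rep(gy, each = nx)
  # source (world) sampling point of each target pixel
  sx <- xp * cos(th) - yp * sin(th) + cx
  sy <- xp * sin(th) + yp * cos(th) + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  tgt <- seq_len(nx * ny)
  ii <- jj <- ww <- vector("list", 4)
  k <- 0
  for (dx in 0:1) for (dy in 0:1) {
    k <- k + 1
    xs <- x0 + dx; ys <- y0 + dy
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny & w > 0
    ii[[k]] <- tgt[ok]
    jj[[k]] <- xs[ok] + (ys[ok] - 1) * nx
    ww[[k]] <- w[ok]
  }
  R <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(nx * ny, nx * ny))
  .proj_cache[[key]] <- R
  R
}

# Gaussian blur matrix (dense n x n), kernel truncated at 4 sigma,
# normalized by the full kernel sum (interior rows sum to 1). Symmetric
# Toeplitz; dense so plane convolutions run through BLAS.
blur_matrix <- function(n, sigma_pix) {
  if (sigma_pix < 1e-3) return(diag(n))
  key <- sprintf("blur|%d|%.6g", n, sigma_pix)
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])
  hw <- min(n - 1, max(1L, ceiling(4 * sigma_pix)))
  off <- -hw:hw
  k <- dnorm(off, sd = sigma_pix); k <- k / sum(k)
  B <- matrix(0, n, n)
  idx <- seq_len(n)
  for (m in seq_along(off)) {
    d <- off[m]
    rows <- idx[idx + d >= 1 & idx + d <= n]
    B[cbind(rows, rows + d)] <- k[m]
  }
  .proj_cache[[key]] <- B
  B
}

# reverse (toward-detector) cumulative sums along x via triangular matmul
.revcumsum_x <- function(values) {
  d <- dim(values)
  key <- sprintf("tri|%d", d[1])
  U <- .proj_cache[[key]]
  if (is.null(U)) {
    U <- matrix(0, d[1], d[1]); U[upper.tri(U, diag = TRUE)] <- 1
    .proj_cache[[key]] <- U
  }
  array(U %*% matrix(values, d[1], d[2] * d[3]), d)
}

# rotate all z-planes of a volume array with operator R (or its transpose)
.rotate_vol <- function(values, R, transpose = FALSE) {
  d <- dim(values)
  m <- matrix(values, d[1] * d[2], d[3])
  out <- if (transpose) Matrix::crossprod(R, m) else R %*% m
  array(as.numeric(out), d)
}

# per-depth transmission factors exp(-integral mu dl) toward the detector at
# the +x side of the rotated frame; midpoint rule (half-voxel self term)
.transmission <- function(mur, dx_mm) {
  dxc <- dx_mm / 10 # cm
  cs <- .revcumsum_x(mur) # includes self; midpoint rule keeps half the self term
  exp(-dxc * (cs - 0.5 * mur))
}

# depth distances (mm) from each rotated x-plane to the collimator face
.depth_distances <- function(vol, orbit_radius) {
  orbit_radius - voxel_coords(vol, 1)
}

#' Forward projection of a volume at one angle
#'
#' @param volume activity [voxel_volume].
#' @param mu attenuation [voxel_volume] (cm^-1) on the same grid; may be
#'   `NULL` when `attenuation_on = FALSE`.
#' @param angle detector angle, degrees.
#' @param system a [system_model] (needed when `psf_on`).
#' @param orbit_radius CoR-to-collimator distance, mm.
#' @param attenuation_on,psf_on logical switches for the attenuation weighting
#'   and the distance-dependent PSF.
#' @return 2D matrix `[nu, nv]` of expected projection values (ray sums).
#' @export
forward_project <- function(volume, mu, angle, system = NULL,
                            orbit_radius = 250,
                            attenuation_on = TRUE, psf_on = FALSE) {
  d <- dim(volume$values)
  if (attenuation_on) {
    if (is.null(mu)) stop("mu required when attenuation_on")
    if (!same_grid(volume, mu)) stop("volume and mu grids differ")
  }
  if (psf_on && is.null(system)) stop("system required when psf_on")
  R <- rotation_operator(d[1], d[2], volume$spacing[1:2], angle)
  vr <- .rotate_vol(volume$values, R)
  if (attenuation_on) {
    mur <- .rotate_vol(mu$values, R)
    vr <- vr * .transmission(mur, volume$spacing[1])
  }
  if (psf_on) {
    dist <- .depth_distances(volume, orbit_radius)
    proj <- matrix(0, d[2], d[3])
    for (ix in seq_len(d[1])) {
      s <- sigma_at(system, max(dist[ix], 0))
      By <- blur_matrix(d[2], s / volume$spacing[2])
      Bz <- blur_matrix(d[3], s / volume$spacing[3])
      plane <- matrix(vr[ix, , ], d[2], d[3])
      proj <- proj + By %*% plane %*% t(Bz)
    }
    proj
  } else {
    colSums(vr)
  }
}

#' Back projection (exact adjoint of [forward_project])
#'
#' Applies the transpose of the discrete forward operator with the same
#' options: transposed PSF convolution per depth, the same attenuation
#' weighting, broadcast along rays, and the transposed rotation.
#'
#' @param frame 2D matrix `[nu, nv]` (one projection), or a [projection_set]
#'   whose frames are summed into one volume.
#' @inheritParams forward_project
#' @return a [voxel_volume] on the grid of `volume_template`.
#' @param volume_template [voxel_volume] defining the output grid.
#' @export
back_project <- function(frame, mu, angle, volume_template, system = NULL,
                         orbit_radius = 250,
                         attenuation_on = TRUE, psf_on = FALSE) {
  if (inherits(frame, "projection_set")) {
    acc <- NULL
    for (a in seq_along(frame$angles)) {
      bp <- back_project(frame$frames[, , a], mu, frame$angles[a],
                         volume_template, system, frame$orbit_radius,
                         attenuation_on, psf_on)
      acc <- if (is.null(acc)) bp$values else acc + bp$values
    }
    return(voxel_volume(acc, volume_template$spacing, volume_template$origin))
  }
  d <- dim(volume_template$values)
  if (psf_on && is.null(system)) stop("system required when psf_on")
  vb <- array(0, d)
  if (psf_on) {
    dist <- .depth_distances(volume_template, orbit_radius)
    for (ix in seq_len(d[1])) {
      s <- sigma_at(system, max(dist[ix], 0))
      By <- blur_matrix(d[2], s / volume_template$spacing[2])
      Bz <- blur_matrix(d[3], s / volume_template$spacing[3])
      vb[ix, , ] <- crossprod(By, as.matrix(frame)) %*% Bz
    }
  } else {
    for (ix in seq_len(d[1])) vb[ix, , ] <- frame
  }
  if (attenuation_on) {
    if (is.null(mu)) stop("mu required when attenuation_on")
    R <- rotation_operator(d[1], d[2], volume_template$spacing[1:2], angle)
    mur <- .rotate_vol(mu$values, R)
    vb <- vb * .transmission(mur, volume_template$spacing[1])
    vb <- .rotate_vol(vb, R, transpose = TRUE)
  } else {
    R <- rotation_operator(d[1], d[2], volume_template$spacing[1:2], angle)
    vb <- .rotate_vol(vb, R, transpose = TRUE)
  }
  voxel_volume(vb, volume_template$spacing, volume_template$origin)
}

#' Expected projections of a volume at many angles
#'
#' Convenience wrapper applying [forward_project] per angle.
#'
#' @inheritParams forward_project
#' @param angles degrees.
#' @return a [projection_set] of expected values.
#' @export
forward_project_set <- function(volume, mu, angles, system = NULL,
                                orbit_radius = 250,
                                attenuation_on = TRUE, psf_on = FALSE) {
  d <- dim(volume$values)
  frames <- array(0, c(d[2], d[3], length(angles)))
  for (a in seq_along(angles)) {
    frames[, , a] <- forward_project(volume, mu, angles[a], system,
                                     orbit_radius, attenuation_on, psf_on)
  }
  projection_set(frames, angles, orbit_radius, volume$spacing[2],
                 meta = list(generator = "analytic"))
}
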