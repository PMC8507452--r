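#' Spatial-resolution and contrast measurement
#'
#' Measurement layer applied to reconstructed volumes: 1D line profiles
#' through line sources with Gaussian fits (FWHM), 2D elliptical-Gaussian
#' fits quantifying the CoR-directed elongation artifact, and
#' tumour-to-normal contrast (TNC) from fixed voxel VOIs.
#'
#' @name resolution_eval
NULL

#' Extract a 1D profile through a line source
#'
#' Locates the local intensity peak within `search_radius` mm of the nominal
#' transverse center (on the average of `slice_range` axial slices), then
#' samples the single-voxel-wide profile through the peak along the requested
#' axis. Peak localization precedes profiling so the measured FWHM is not
#' biased by center mis-specification.
#'
#' @param volume reconstructed [voxel_volume].
#' @param nominal_center length-2, transverse position (mm) of the line.
#' @param direction `"x"` (anteroposterior) or `"y"` (left-right).
#' @param slice_range axial voxel indices to average; default the central 5.
#' @param search_radius mm.
#' @param profile_halfwidth half-length of the sampled profile, mm; limits
#'   the fit to the neighbourhood of the line so other sources and the
#'   phantom boundary do not enter.
#' @return object of class `line_profile`: list with `positions` (mm),
#'   `values`, `direction`, `peak_voxel`.
#' @export
extract_line_profile <- function(volume, nominal_center,
                                 direction = c("x", "y"),
                                 slice_range = NULL, search_radius = 15,
                                 profile_halfwidth = 35) {
  direction <- match.arg(direction)
  d <- dim(volume$values)
  if (is.null(slice_range)) {
    mid <- ceiling(d[3] / 2)
    slice_range <- max(1, mid - 2):min(d[3], mid + 2)
  }
  slab <- apply(volume$values[, , slice_range, drop = FALSE], c(1, 2), mean)
  xs <- voxel_coords(volume, 1); ys <- voxel_coords(volume, 2)
  within <- outer((xs - nominal_center[1])^2, (ys - nominal_center[2])^2, "+") <=
    search_radius^2
  if (!any(within)) stop("nominal center outside volume / search region empty")
  masked <- slab
  masked[!within] <- -Inf
  pk <- arrayInd(which.max(masked), d[1:2])
  if (!is.finite(masked[pk]) || masked[pk] <= 0) {
    stop("no local peak above background near the nominal center")
  }
  if (direction == "x") {
    vals <- slab[, pk[2]]
    pos <- xs
    ctr <- xs[pk[1]]
  } else {
    vals <- slab[pk[1], ]
    pos <- ys
    ctr <- ys[pk[2]]
  }
  keep <- abs(pos - ctr) <= profile_halfwidth
  if (sum(keep) >= 7) { vals <- vals[keep]; pos <- pos[keep] }
  structure(list(positions = pos, values = vals, direction = direction,
                 peak_voxel = as.integer(pk), slice_range = slice_range),
            class = "line_profile")
}

#' Gaussian fit of a 1D profile and its FWHM
#'
#' Least-squares fit of `amplitude * exp(-(x - center)^2 / (2 sigma^2)) +
#' offset` (Levenberg-Marquardt), initialized from profile moments.
#' `fwhm = 2 sqrt(2 ln 2) * sigma`.
#'
#' @param profile a `line_profile`, or a list with `positions` and `values`.
#' @return object of class `gaussian_fit`: `amplitude`, `center`, `sigma`,
#'   `offset`, `fwhm` (all mm where applicable) and `fit_rmse`.
#' @export
fit_gaussian_fwhm <- function(profile) {
  x <- profile$positions; yv <- profile$values
  stopifnot(length(x) >= 7, all(diff(x) > 0))
  off0 <- min(yv)
  amp0 <- max(yv) - off0
  if (amp0 <= 0) stop("profile has no discernible peak")
  w <- pmax(yv - off0, 0)
  c0 <- sum(x * w) / sum(w)
  s0 <- sqrt(sum((x - c0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 10
  resid_fun <- function(p) {
    p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4] - yv
  }
  fit <- minpack.lm::nls.lm(
    par = c(A = amp0, m = c0, s = s0, b = off0), fn = resid_fun,
    lower = c(0, min(x), 1e-6, -Inf),
    upper = c(Inf, max(x), diff(range(x)), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400, maxfev = 4000))
  if (!fit$info %in% 1:4) {
    stop("Gaussian fit did not converge (", fit$message, ")")
  }
  cf <- fit$par
  if (cf[["s"]] >= diff(range(x))) {
    stop(sprintf("fitted sigma (%.2f mm) exceeds the profile span", cf[["s"]]))
  }
  structure(list(amplitude = cf[["A"]], center = cf[["m"]], sigma = cf[["s"]],
                 offset = cf[["b"]], fwhm = cf[["s"]] / FWHM_TO_SIGMA,
                 fit_rmse = sqrt(mean(fit$fvec^2))),
            class = "gaussian_fit")
}

#' FWHM table over volumes, lines and directions
#'
#' One Gaussian-fit FWHM per (line, direction) for each reconstructed volume.
#'
#' @param volumes named list of [voxel_volume]s (one per camera/seed x
#'   variant realization). Names of the form `"<realization>.<variant>"` are
#'   split into columns; other names go to `realization` with variant `NA`.
#' @param line_specs list of [line_source_spec].
#' @param ... passed to [extract_line_profile].
#' @return data.frame with columns `realization`, `variant`, `line`,
#'   `direction`, `fwhm_mm`.
#' @export
fwhm_table <- function(volumes, line_specs, ...) {
  rows <- list()
  for (nm in names(volumes)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    realiz <- parts[1]
    variant <- if (length(parts) > 1) paste(parts[-1], collapse = ".") else NA
    for (sp in line_specs) {
      for (dirn in c("x", "y")) {
        pr <- extract_line_profile(volumes[[nm]], sp$center_xy, dirn, ...)
        ft <- fit_gaussian_fwhm(pr)
        rows[[length(rows) + 1]] <- data.frame(
          realization = realiz, variant = variant, line = sp$label,
          direction = dirn, fwhm_mm = ft$fwhm)
      }
    }
  }
  do.call(rbind, rows)
}

#' Elliptical-Gaussian fit of a transverse blob
#'
#' Fits a 2D elliptical Gaussian (amplitude, center, two principal sigmas,
#' orientation, offset) to a transverse slice around a line source, and
#' reports the orientation of the major axis together with its angular
#' misalignment from the source-to-CoR direction (the direction along which
#' the reconstruction artifact elongates line sources).
#'
#' @param volume a [voxel_volume]; the central slices are averaged.
#' @param nominal_center transverse position of the blob, mm.
#' @param cor_xy transverse position of the center of rotation, mm.
#' @param slice_range axial voxel indices to average.
#' @param fit_radius mm; pixels within this radius of the peak enter the fit.
#' @return object of class `ellipse_fit`: `center`, `major_fwhm`,
#'   `minor_fwhm` (mm), `orientation` (degrees in [0, 180)),
#'   `radial_misalignment` (degrees, `NA` if degenerate), `degenerate`.
#' @export
fit_ellipse_orientation <- function(volume, nominal_center, cor_xy = c(0, 0),
                                    slice_range = NULL, fit_radius = 25) {
  d <- dim(volume$values)
  if (is.null(slice_range)) {
    mid <- ceiling(d[3] / 2)
    slice_range <- max(1, mid - 2):min(d[3], mid + 2)
  }
  slab <- apply(volume$values[, , slice_range, drop = FALSE], c(1, 2), mean)
  xs <- voxel_coords(volume, 1); ys <- voxel_coords(volume, 2)
  r2 <- outer((xs - nominal_center[1])^2, (ys - nominal_center[2])^2, "+")
  masked <- slab; masked[r2 > fit_radius^2] <- -Inf
  pk <- arrayInd(which.max(masked), d[1:2])
  if (!is.finite(masked[pk])) stop("no resolvable peak")
  sel <- which(r2 <= fit_radius^2, arr.ind = TRUE)
  df <- data.frame(px = xs[sel[, 1]], py = ys[sel[, 2]],
                   z = slab[sel])
  off0 <- quantile(df$z, 0.1); amp0 <- max(df$z) - off0
  # moment initialization
  w <- pmax(df$z - off0, 0)
  mx <- sum(df$px * w) / sum(w); my <- sum(df$py * w) / sum(w)
  cxx <- sum((df$px - mx)^2 * w) / sum(w)
  cyy <- sum((df$py - my)^2 * w) / sum(w)
  cxy <- sum((df$px - mx) * (df$py - my) * w) / sum(w)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2))
  s10 <- sqrt(max(ev$values[1], 1e-2)); s20 <- sqrt(max(ev$values[2], 1e-2))
  th0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  resid_fun <- function(p) {
    ct <- cos(p[6]); st <- sin(p[6])
    u <- (df$px - p[2]) * ct + (df$py - p[3]) * st
    v <- -(df$px - p[2]) * st + (df$py - p[3]) * ct
    p[1] * exp(-u^2 / (2 * p[4]^2) - v^2 / (2 * p[5]^2)) + p[7] - df$z
  }
  fit <- minpack.lm::nls.lm(
    par = c(A = amp0, m1 = mx, m2 = my, s1 = s10, s2 = s20, th = th0,
            b = off0),
    fn = resid_fun,
    lower = c(0, mx - 20, my - 20, 0.3, 0.3, -2 * pi, -Inf),
    upper = c(Inf, mx + 20, my + 20, fit_radius, fit_radius, 2 * pi, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  if (fit$info %in% 1:4) {
    cf <- fit$par
    s1 <- cf[["s1"]]; s2 <- cf[["s2"]]; th <- cf[["th"]]
    ctr <- c(cf[["m1"]], cf[["m2"]])
  } else {
    s1 <- s10; s2 <- s20; th <- th0; ctr <- c(mx, my)
  }
  if (s2 > s1) { tmp <- s1; s1 <- s2; s2 <- tmp; th <- th + pi / 2 }
  orientation <- (th * 180 / pi) %% 180
  degenerate <- (s1 / s2) < 1.05
  # source -> CoR direction as an axis (mod 180)
  radial <- atan2(cor_xy[2] - ctr[2], cor_xy[1] - ctr[1]) * 180 / pi
  mis <- abs(((orientation - radial) %% 180))
  mis <- min(mis, 180 - mis)
  structure(list(center = ctr, major_fwhm = s1 / FWHM_TO_SIGMA,
                 minor_fwhm = s2 / FWHM_TO_SIGMA,
                 orientation = orientation,
                 radial_misalignment = if (degenerate) NA_real_ else mis,
                 degenerate = degenerate),
            class = "ellipse_fit")
}

#' Default tumour and background VOIs around a lesion center
#'
#' The tumour VOI is the 4 highest-intensity voxels among the 19 non-corner
#' voxels of the 3x3x3 neighbourhood of the lesion center (a compact 4-voxel
#' VOI following the measured activity); the background VOI is the remaining
#' 15 non-corner voxels of the same 3x3x3 box. Both are explicit voxel lists.
#'
#' @param volume reconstructed [voxel_volume].
#' @param lesion_center integer length-3 voxel index.
#' @return list with integer index matrices `tumour` (4 rows) and
#'   `background` (15 rows).
#' @export
default_tnc_vois <- function(volume, lesion_center) {
  d <- dim(volume$values)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  corner <- rowSums(abs(off)) == 3
  off <- off[!corner, , drop = FALSE] # 19 voxels
  vox <- sweep(off, 2, lesion_center, "+")
  if (any(vox < 1) || any(vox[, 1] > d[1]) || any(vox[, 2] > d[2]) ||
      any(vox[, 3] > d[3])) {
    stop("lesion neighbourhood extends outside the volume")
  }
  vals <- volume$values[vox]
  top4 <- order(vals, decreasing = TRUE)[1:4]
  list(tumour = vox[top4, , drop = FALSE],
       background = vox[-top4, , drop = FALSE])
}

#' Tumour-to-normal contrast from voxel VOIs
#'
#' Ratio of the mean counts in the tumour VOI to the mean counts in the
#' background VOI. With `tumour_voi`/`background_voi` omitted, the default
#' VOIs of [default_tnc_vois()] are used.
#'
#' @param volume reconstructed [voxel_volume].
#' @param lesion_center integer voxel index (center of the inserted lesion).
#' @param tumour_voi,background_voi integer index matrices (n x 3); must be
#'   disjoint and non-empty.
#' @return object of class `tnc_result`: `tumour_mean`, `background_mean`,
#'   `ratio`, plus the voxel lists for auditability.
#' @export
measure_tnc <- function(volume, lesion_center, tumour_voi = NULL,
                        background_voi = NULL) {
  if (is.null(tumour_voi) || is.null(background_voi)) {
    vois <- default_tnc_vois(volume, lesion_center)
    if (is.null(tumour_voi)) tumour_voi <- vois$tumour
    if (is.null(background_voi)) background_voi <- vois$background
  }
  if (nrow(tumour_voi) == 0 || nrow(background_voi) == 0) stop("empty VOI")
  keyt <- apply(tumour_voi, 1, paste, collapse = ",")
  keyb <- apply(background_voi, 1, paste, collapse = ",")
  if (length(intersect(keyt, keyb))) stop("VOIs must be disjoint")
  tm <- mean(volume$values[tumour_voi])
  bm <- mean(volume$values[background_voi])
  structure(list(tumour_mean = tm, background_mean = bm, ratio = tm / bm,
                 tumour_voi = tumour_voi, background_voi = background_voi),
            class = "tnc_result")
}
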