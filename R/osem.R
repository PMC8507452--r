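#' Ordered-subset expectation maximization reconstruction
#'
#' Multiplicative OSEM with pluggable forward models:
#' \describe{
#'   \item{AC}{analytic forward/back projector with attenuation weighting,
#'     no PSF; 2 iterations x 10 subsets by default.}
#'   \item{ACRR}{AC plus distance-dependent Gaussian PSF modelling in both
#'     forward and back projection (resolution recovery); 2 x 10.}
#'   \item{MC}{Monte Carlo forward projection (sampled emissions, photon
#'     transport with Compton scatter) and analytic attenuation + PSF
#'     back projection; 5 iterations x 10 subsets by default.}
#' }
#' Setting `attenuation = FALSE` yields the non-corrected variants (NC,
#' NCRR, MC-NC) used for phantoms in air.
#'
#' @name osem
NULL

#' Reconstruction configuration
#'
#' @param variant `"AC"`, `"ACRR"` or `"MC"`.
#' @param n_iterations full passes over all subsets; defaults 2 (AC/ACRR)
#'   or 5 (MC).
#' @param n_subsets must divide the number of projections.
#' @param attenuation logical; `FALSE` gives the non-corrected variant.
#' @param psf_forward,psf_backward PSF switches; defaults follow the variant.
#' @param mc_histories_per_subset photon budget of each MC forward step.
#' @param seed master seed for the MC forward substreams.
#' @param postfilter `NULL` or `list(type = "butterworth", order, fc)` with
#'   `fc` in cycles/cm.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(variant = c("AC", "ACRR", "MC"),
                         n_iterations = NULL, n_subsets = 10,
                         attenuation = TRUE,
                         psf_forward = NULL, psf_backward = NULL,
                         mc_histories_per_subset = 2e5, seed = 1,
                         postfilter = NULL) {
  variant <- match.arg(variant)
  if (is.null(n_iterations)) n_iterations <- if (variant == "MC") 5L else 2L
  if (is.null(psf_forward)) psf_forward <- variant %in% c("ACRR", "MC")
  if (is.null(psf_backward)) psf_backward <- variant %in% c("ACRR", "MC")
  stopifnot(n_iterations >= 1, n_subsets >= 1)
  structure(list(variant = variant, n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets), attenuation = attenuation,
                 psf_forward = psf_forward, psf_backward = psf_backward,
                 mc_histories_per_subset = mc_histories_per_subset,
                 seed = as.integer(seed), postfilter = postfilter),
            class = "recon_config")
}

#' Partition projection angles into ordered subsets
#'
#' Interleaved subsets (subset k takes angles k, k + n_subsets, ...),
#' processed in a maximal-angular-separation order chosen greedily, so
#' successive updates use views as far apart as possible.
#'
#' @param angles projection angles, degrees.
#' @param n_subsets must divide `length(angles)`.
#' @return list of integer index vectors into `angles`, in processing order.
#' @export
make_subsets <- function(angles, n_subsets) {
  n <- length(angles)
  if (n %% n_subsets != 0) stop("n_subsets must divide the number of angles")
  groups <- lapply(seq_len(n_subsets), function(k) seq(k, n, by = n_subsets))
  if (n_subsets == 1) return(groups)
  # greedy max-min separation over subset lead angles
  lead <- angles[vapply(groups, `[`, numeric(1), 1)]
  circ <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
  order_idx <- 1L
  remaining <- setdiff(seq_len(n_subsets), order_idx)
  while (length(remaining)) {
    score <- vapply(remaining, function(r) {
      min(circ(lead[r], lead[order_idx]))
    }, numeric(1))
    nxt <- remaining[which.max(score)]
    order_idx <- c(order_idx, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  groups[order_idx]
}

#' Butterworth post filter
#'
#' 3D frequency-domain low-pass filter with gain
#' `H(f) = (1 + (f/fc)^(2 order))^(-1/2)` where `f` is the radial spatial
#' frequency in cycles/cm. DC gain is exactly 1.
#'
#' @param volume a [voxel_volume].
#' @param order filter order (>= 1).
#' @param critical_frequency cycles/cm (> 0).
#' @return filtered [voxel_volume].
#' @export
#' @examples
#' butterworth_gain(0.48, order = 10, fc = 0.48) # 1/sqrt(2)
butterworth_filter <- function(volume, order = 10, critical_frequency = 0.48) {
  if (critical_frequency <= 0) stop("critical frequency must be > 0")
  stopifnot(order >= 1)
  d <- dim(volume$values)
  fr <- lapply(1:3, function(ax) {
    n <- d[ax]
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    k / (n * volume$spacing[ax]) * 10 # cycles/cm
  })
  f2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  H <- butterworth_gain(sqrt(f2), order, critical_frequency)
  filt <- Re(fft(fft(volume$values) * H, inverse = TRUE)) / prod(d)
  voxel_volume(filt, volume$spacing, volume$origin)
}

#' @rdname butterworth_filter
#' @param f radial frequency, cycles/cm.
#' @param fc critical frequency, cycles/cm.
#' @export
butterworth_gain <- function(f, order, fc) {
  1 / sqrt(1 + (f / fc)^(2 * order))
}

#' OSEM reconstruction
#'
#' Starts from a uniform positive volume on the attenuation support and
#' applies the multiplicative update
#' `x <- x * Abp_s( y_s / (Afp_s x + eps) ) / Abp_s(1)` over ordered subsets,
#' where `Afp_s` is the configured variant's forward model over the subset's
#' angles and `Abp_s` its back projector. Nonnegativity is preserved by
#' construction. An optional Butterworth post filter is applied at the end.
#'
#' @param projections a [projection_set] of measured counts.
#' @param mu attenuation [voxel_volume] at the photopeak energy (may be
#'   `NULL` when `config$attenuation` is `FALSE` and variant is not MC).
#' @param system a [system_model].
#' @param config a [recon_config].
#' @param grid [voxel_volume] defining the reconstruction grid; defaults to
#'   the grid of `mu`.
#' @param protocol an [acquisition_protocol]; required for the MC variant
#'   (emission lines, windows, frame duration).
#' @return reconstructed [voxel_volume].
#' @export
osem_reconstruct <- function(projections, mu, system, config, grid = NULL,
                             protocol = NULL) {
  if (is.null(grid)) grid <- mu
  if (is.null(grid)) stop("grid or mu must be supplied")
  d <- dim(grid$values)
  y <- projections$frames
  if (any(y < 0)) stop("projections must be nonnegative")
  orbit <- projections$orbit_radius
  angles <- projections$angles
  subsets <- make_subsets(angles, config$n_subsets)
  eps <- 1e-10
  att <- config$attenuation
  if (att && is.null(mu)) stop("mu required for attenuation-corrected variants")
  if (config$variant == "MC" && is.null(protocol)) {
    stop("protocol required for the MC variant")
  }
  # initial estimate: uniform on the attenuation support (or the inscribed
  # transverse cylinder when no attenuation map applies)
  if (att) {
    support <- mu$values > 0.5 * max(mu$values)
    if (!any(support)) support <- array(TRUE, d)
  } else {
    x1 <- voxel_coords(grid, 1); y1 <- voxel_coords(grid, 2)
    rmax <- min(max(abs(x1)), max(abs(y1)))
    support <- array(outer(x1^2, y1^2, "+") <= rmax^2, d)
  }
  x <- array(0, d); x[support] <- 1
  xvol <- voxel_volume(x, grid$spacing, grid$origin)
  if (sum(y) == 0) {
    warning("all-zero projections: returning uniform zero-information volume")
    return(xvol)
  }

  fwd_fun <- function(xv, idx, it, s) {
    if (config$variant == "MC") {
      sub_seed <- (config$seed + 7919L * it + 104729L * s) %% .Machine$integer.max
      ps <- simulate_projections(xv, mu, system, protocol,
                                 n_histories = config$mc_histories_per_subset,
                                 seed = sub_seed, noise = "expected",
                                 angles = angles[idx], orbit_radius = orbit)
      ps$frames
    } else {
      fr <- array(0, c(d[2], d[3], length(idx)))
      for (j in seq_along(idx)) {
        fr[, , j] <- forward_project(xv, mu, angles[idx[j]], system,
                                     orbit, attenuation_on = att,
                                     psf_on = config$psf_forward)
      }
      fr
    }
  }

  bp_fun <- function(frames, idx) {
    acc <- array(0, d)
    for (j in seq_along(idx)) {
      bp <- back_project(frames[, , j], mu, angles[idx[j]], grid, system,
                         orbit, attenuation_on = att,
                         psf_on = config$psf_backward)
      acc <- acc + bp$values
    }
    acc
  }

  sens <- lapply(subsets, function(idx) {
    ones <- array(1, c(d[2], d[3], length(idx)))
    bp_fun(ones, idx)
  })

  for (it in seq_len(config$n_iterations)) {
    for (s in seq_along(subsets)) {
      idx <- subsets[[s]]
      fp <- fwd_fun(xvol, idx, it, s)
      ratio <- y[, , idx, drop = FALSE] / (fp + eps)
      # pixels with both zero measured and zero expected contribute factor 1
      ratio[y[, , idx, drop = FALSE] == 0 & fp <= eps] <- 1
      bp <- bp_fun(ratio, idx)
      upd <- array(0, d)
      pos <- sens[[s]] > 0
      upd[pos] <- bp[pos] / sens[[s]][pos]
      xvol$values <- xvol$values * upd
    }
  }
  if (!is.null(config$postfilter) &&
      identical(config$postfilter$type, "butterworth")) {
    xvol <- butterworth_filter(xvol, config$postfilter$order,
                               config$postfilter$fc)
  }
  xvol
}
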