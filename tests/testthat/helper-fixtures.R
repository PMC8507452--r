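# shared small fixtures and a cache for the expensive simulation studies

small_grid <- function(n = 16, nz = n, spacing = 4) {
  voxel_volume(array(0, c(n, n, nz)), spacing)
}

random_volume <- function(n = 16, nz = n, spacing = 4) {
  voxel_volume(array(runif(n * n * nz), c(n, n, nz)), spacing)
}

# gaussian blob volume for fit tests
blob_volume <- function(n = 33, spacing = 2, sigma = c(4, 4), center = c(0, 0),
                        theta = 0, amplitude = 1, offset = 0, nz = 9) {
  g <- small_grid(n, nz, spacing)
  xs <- voxel_coords(g, 1); ys <- voxel_coords(g, 2)
  ct <- cos(theta); st <- sin(theta)
  X <- outer(xs - center[1], rep(1, n)); Y <- outer(rep(1, n), ys - center[2])
  U <- X * ct + Y * st; V <- -X * st + Y * ct
  plane <- amplitude * exp(-U^2 / (2 * sigma[1]^2) - V^2 / (2 * sigma[2]^2)) + offset
  g$values <- array(rep(plane, nz), c(n, n, nz))
  g
}

# memoized heavy experiment runs shared between acceptance tests
.study_cache <- new.env(parent = emptyenv())

cached_resolution_runs <- function(seeds = 1:3) {
  key <- paste0("res_", paste(seeds, collapse = "_"))
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- lapply(seeds, function(s) {
      run_resolution_experiment(seed = s)
    })
  }
  .study_cache[[key]]
}

cached_lesion_runs <- function(seeds = 1:3) {
  key <- paste0("les_", paste(seeds, collapse = "_"))
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- lapply(seeds, function(s) {
      run_lesion_experiment(seed = s)
    })
  }
  .study_cache[[key]]
}
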