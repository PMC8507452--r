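#' Volume and projection I/O
#'
#' Volumes are stored as NIfTI (`.nii` / `.nii.gz`) with spacing in mm;
#' projection sets as a NIfTI frame stack plus a JSON sidecar holding angles,
#' orbit radius, pixel size and provenance metadata. Round trips preserve
#' values and spacing exactly (counts are stored losslessly).
#'
#' @name io
NULL

#' Write / read a voxel volume as NIfTI
#'
#' @param vol a [voxel_volume].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns a [voxel_volume]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("volume files must use the .nii or .nii.gz extension")
  }
  arr <- vol$values
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  # exact geometry in a json sidecar (the NIfTI header stores pixdim as
  # float32 and the qform encodes the origin only approximately)
  jsonlite::write_json(list(origin = vol$origin, spacing = vol$spacing),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("volume files must use the .nii or .nii.gz extension")
  }
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    geom <- jsonlite::read_json(sc, simplifyVector = TRUE)
    origin <- as.numeric(geom$origin)
    if (!is.null(geom$spacing)) spacing <- as.numeric(geom$spacing)
  }
  voxel_volume(array(as.numeric(img), dim(img)[1:3]), spacing, origin)
}

#' Write / read a projection set (NIfTI stack + JSON sidecar)
#'
#' @param ps a [projection_set].
#' @param path base path ending in `.nii` or `.nii.gz`; the sidecar is
#'   `<path>.json`.
#' @export
write_projections <- function(ps, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("projection files must use the .nii or .nii.gz extension")
  }
  arr <- ps$frames
  attr(arr, "pixdim") <- c(ps$pixel_size, ps$pixel_size, 1)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(angles = ps$angles, orbit_radius = ps$orbit_radius,
         pixel_size = ps$pixel_size, meta = ps$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  img <- RNifti::readNifti(path)
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) stop("missing projection sidecar: ", sc)
  md <- jsonlite::read_json(sc, simplifyVector = TRUE)
  frames <- array(as.numeric(img), dim(img))
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1)
  if (dim(frames)[3] != length(md$angles)) {
    stop("frame count does not match sidecar angle count")
  }
  projection_set(frames, md$angles, md$orbit_radius, md$pixel_size,
                 meta = as.list(md$meta))
}

#' Read / write an experiment configuration (YAML)
#'
#' An experiment configuration is a named list with fields `experiment`
#' (`"resolution"` or `"lesion"`), `seed`, and optional overrides for the
#' setup (`n_transverse`, `n_axial`, `spacing`, `n_projections`,
#' `orbit_radius`), the simulation (`n_histories`, `medium`, concentrations)
#' and the reconstruction (`variants`, `mc_histories_per_subset`). It
#' round-trips losslessly through YAML.
#'
#' @param config named list.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run a full experiment from a configuration
#'
#' Dispatches to [run_resolution_experiment()] or [run_lesion_experiment()]
#' with the configured setup, writes the outputs (reconstructions, FWHM or
#' TNC tables, report JSON, resolved config) under `out_dir`, and returns
#' the experiment result invisibly.
#'
#' @param config named list (see [write_experiment_config()]) or path to a
#'   YAML file.
#' @param out_dir output directory, created if missing; `NULL` writes
#'   nothing.
#' @param seed optional override of `config$seed`.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  setup_args <- config[intersect(names(config),
                                 names(formals(study_setup)))]
  setup <- do.call(study_setup, setup_args)
  kind <- match.arg(config$experiment, c("resolution", "lesion"))
  if (kind == "resolution") {
    args <- config[intersect(names(config),
                             setdiff(names(formals(run_resolution_experiment)),
                                     "setup"))]
    args$setup <- setup
    res <- do.call(run_resolution_experiment, args)
    report <- build_report(stats::setNames(
      res$fwhm, sub("^realization$", "camera", names(res$fwhm))))
  } else {
    args <- config[intersect(names(config),
                             setdiff(names(formals(run_lesion_experiment)),
                                     "setup"))]
    args$setup <- setup
    res <- do.call(run_lesion_experiment, args)
    report <- list(tnc = as.list(res$tnc))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$recons)) {
      write_volume(res$recons[[nm]],
                   file.path(out_dir, paste0("recon_", nm, ".nii.gz")))
    }
    if (!is.null(res$fwhm)) {
      utils::write.csv(res$fwhm, file.path(out_dir, "fwhm.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
  }
  invisible(res)
}
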