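#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (numeric array) and `affine` (4x4 voxel-to-world
#'   matrix).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write an array to NIfTI
#'
#' Data are stored as float32 (compressed NIfTI-1); computation elsewhere
#' stays in double precision.
#'
#' @param data Numeric 3-D or 4-D array.
#' @param path Output path (`.nii.gz` recommended).
#' @param affine 4x4 voxel-to-world matrix.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4)) {
  vd <- sqrt(colSums(affine[1:3, 1:3]^2))
  nd <- length(dim(data))
  pd <- if (nd >= 4) c(vd, rep(1, nd - 3)) else vd
  img <- RNifti::asNifti(data, datatype = "float", pixdim = pd)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a multi-echo volume (4-D NIfTI)
#' @param volume A `multiecho_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiecho <- function(volume, path) {
  write_nifti(volume$data, path, volume$affine)
}

#' Write per-echo slice stacks with a JSON sidecar
#'
#' Each echo's slices are written as one NIfTI volume (x, y, slice, dynamic)
#' plus a shared JSON sidecar holding the per-slice rigid transforms,
#' dynamic indices, geometry and echo times.
#'
#' @param stacks List of `slice_stack` objects (one per echo).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_slice_stacks <- function(stacks, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- stacks[[1]]$geometry
  files <- character(0)
  for (e in seq_along(stacks)) {
    f <- file.path(dir, sprintf("%s_echo%d.nii.gz", prefix, e))
    aff <- diag(c(geom$in_plane, geom$in_plane, geom$thickness, 1))
    aff[1:3, 4] <- c(geom$x[1], geom$y[1], geom$z[1])
    write_nifti(stacks[[e]]$data, f, aff)
    files <- c(files, f)
  }
  sidecar <- list(echo_times = vapply(stacks, `[[`, numeric(1), "echo_time"),
                  in_plane_resolution = geom$in_plane,
                  slice_thickness = geom$thickness,
                  n_slices = geom$n_slices,
                  extent = geom$extent,
                  source_voxel_size = stacks[[1]]$source_voxel_size,
                  transforms = stacks[[1]]$transforms)
  sf <- file.path(dir, paste0(prefix, "_sidecar.json"))
  jsonlite::write_json(sidecar, sf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sf))
}

#' Read slice stacks written by [write_slice_stacks()]
#' @param dir Directory containing the stack files.
#' @param prefix File name prefix used at write time.
#' @return List of `slice_stack` objects.
#' @export
read_slice_stacks <- function(dir, prefix = "stack") {
  sf <- file.path(dir, paste0(prefix, "_sidecar.json"))
  if (!file.exists(sf)) stop("sidecar not found: ", sf)
  meta <- jsonlite::read_json(sf, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_echo\\d+\\.nii\\.gz$"),
                           full.names = TRUE))
  acq <- acquisition_spec(echo_times = meta$echo_times,
                          in_plane_resolution = meta$in_plane_resolution,
                          slice_thickness = meta$slice_thickness,
                          n_dynamics = max(meta$transforms$dynamic))
  dim_src <- round(meta$extent / meta$source_voxel_size)
  geom <- slice_geometry(dim_src, meta$source_voxel_size, acq)
  lapply(seq_along(files), function(e) {
    dat <- read_nifti(files[e])$data
    if (length(dim(dat)) == 3) dim(dat) <- c(dim(dat), 1)
    structure(list(data = dat, transforms = meta$transforms, geometry = geom,
                   echo = e, echo_time = meta$echo_times[e],
                   source_voxel_size = meta$source_voxel_size),
              class = "slice_stack")
  })
}

#' Write a label volume to NIfTI
#' @param labels A `label_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write_nifti(labels$labels, path, labels$affine)
}

# ---------------------------------------------------------------------------
# pipeline configuration

.config_template <- function() {
  list(
    seed = 1L,
    phantom = list(gestational_age = 30, grid_shape = c(64, 64, 64),
                   voxel_size = 1.2, noise_sigma = 0,
                   motion_amplitude = c(0, 0), heterogeneity = 0),
    acquisition = list(echo_times = c(42, 107, 172),
                       in_plane_resolution = 3, slice_thickness = 3,
                       n_dynamics = 15, field_of_view = 400,
                       repetition_time = 10420),
    reconstruction = list(mode = "svr", target_resolution = 1.2,
                          n_outer_iterations = 3, similarity_threshold = 0.8,
                          regularization_weight = 0.01, n_cg_iterations = 12,
                          reference_echo = 3),
    fit = list(method = "loglinear", t2_min = 1, t2_max = 1000,
               min_first_echo_signal = 0),
    normative = list(degree = 2, edges = seq(20, 40, 2)),
    scans = list(gestational_ages = 30)
  )
}

#' Build a validated pipeline configuration
#'
#' Nested sections mirror the phantom, acquisition, reconstruction, fitting
#' and normative settings, plus a global seed. Unknown keys are rejected so
#' typos cannot silently fall back to defaults. The configuration
#' round-trips losslessly through YAML.
#'
#' @param ... Named overrides of the template sections (lists) or of the
#'   top-level `seed` / `scans` entries.
#' @param file Optional YAML file to load before applying `...`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- .config_template()
  apply_over <- function(cfg, over, path = "") {
    for (nm in names(over)) {
      full <- paste0(path, nm)
      if (!nm %in% names(cfg)) stop("unknown configuration key: ", full)
      if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
        cfg[[nm]] <- apply_over(cfg[[nm]], over[[nm]], paste0(full, "$"))
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  over <- list(...)
  if (length(over) > 0) cfg <- apply_over(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
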