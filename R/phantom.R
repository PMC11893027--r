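#' Multi-echo gradient-echo acquisition specification
#'
#' Geometry and timing of the dynamic multi-echo gradient-echo EPI
#' acquisition that the simulator emulates: three echoes per excitation,
#' 3 mm isotropic voxels, 15--30 whole-volume repeats (dynamics).
#' Repetition time and field of view are carried as metadata only.
#'
#' @param echo_times Echo times in ms, strictly increasing, all positive.
#' @param in_plane_resolution In-plane pixel size in mm.
#' @param slice_thickness Slice thickness in mm (also the Gaussian slice
#'   profile FWHM used by the forward model).
#' @param n_dynamics Number of whole-volume repeats, at least 1.
#' @param field_of_view Field of view in mm (metadata).
#' @param repetition_time TR in ms (metadata).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(echo_times = c(42, 107, 172),
                             in_plane_resolution = 3,
                             slice_thickness = 3,
                             n_dynamics = 15,
                             field_of_view = 400,
                             repetition_time = 10420) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1 || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    stop("echo_times must be strictly increasing and positive")
  }
  if (n_dynamics < 1) stop("n_dynamics must be >= 1")
  if (in_plane_resolution <= 0 || slice_thickness <= 0) {
    stop("resolutions must be positive")
  }
  structure(list(echo_times = echo_times,
                 in_plane_resolution = in_plane_resolution,
                 slice_thickness = slice_thickness,
                 n_dynamics = as.integer(n_dynamics),
                 field_of_view = field_of_view,
                 repetition_time = repetition_time),
            class = "acquisition_spec")
}

#' Digital fetal-brain phantom specification
#'
#' Parameters of the gestational-age-parameterised phantom: grid, ground
#' truth resolution (default 1.2 mm isotropic, matching the reconstruction
#' target), noise level, per-slice motion amplitude and the seed fixing all
#' stochastic output.
#'
#' @param gestational_age Gestational age in decimal weeks, in `[20, 40]`.
#' @param grid_shape Integer length 3, voxels per axis (>= 48 each at the
#'   default resolution so all seven regions fit).
#' @param voxel_size Isotropic voxel size in mm.
#' @param noise_sigma Rician noise sigma in signal units (0 = noiseless).
#' @param motion_amplitude Numeric length 2: maximum rotation (degrees) and
#'   translation (mm) of the uniform per-slice motion draws.
#' @param heterogeneity Fractional within-region T2* gradient along the
#'   slice axis (0 = homogeneous regions, the default).
#' @param seed Integer seed fixing all stochastic output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(gestational_age,
                         grid_shape = c(64, 64, 64),
                         voxel_size = 1.2,
                         noise_sigma = 0,
                         motion_amplitude = c(0, 0),
                         heterogeneity = 0,
                         seed = 1L) {
  if (gestational_age < 20 || gestational_age > 40) {
    stop("gestational_age must lie in [20, 40] weeks")
  }
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(motion_amplitude < 0)) stop("motion amplitudes must be >= 0")
  structure(list(gestational_age = gestational_age,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 noise_sigma = noise_sigma,
                 motion_amplitude = as.numeric(motion_amplitude),
                 heterogeneity = heterogeneity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre world coordinates (mm), centred on the grid
.grid_axes <- function(dim, voxel_size) {
  lapply(1:3, function(i) (seq_len(dim[i]) - (dim[i] + 1) / 2) * voxel_size)
}

.volume_affine <- function(dim, voxel_size) {
  origin <- -(dim - 1) / 2 * voxel_size
  rbind(cbind(diag(voxel_size, 3), origin), c(0, 0, 0, 1))
}

#' Build the seven-region phantom label volume
#'
#' Deterministic nested/offset-ellipsoid geometry: an outer eCSF shell, a
#' cortical gray-matter band, a white-matter core, a central deep
#' gray-matter body, paired ventricles, a posterior-inferior cerebellum and
#' an inferior brainstem. All semi-axes scale with a linear gestational-age
#' factor so total brain volume grows monotonically over 20--40 weeks. The
#' geometry is deliberately schematic: regional quantification depends on
#' label bookkeeping, not anatomical realism.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_volume`: list with `labels` (3-D integer array, values
#'   0..7), `affine` (4x4 voxel-to-world), `voxel_size`, and `label_names`.
#' @export
#' @examples
#' lv <- build_label_volume(phantom_spec(30, grid_shape = 48))
#' table(lv$labels)
build_label_volume <- function(spec) {
  d <- spec$grid_shape
  vs <- spec$voxel_size
  if (any(d * vs < 48 * 1.2)) {
    stop("grid too small: all seven regions need at least a 57.6 mm extent")
  }
  ax <- .grid_axes(d, vs)
  half <- d * vs / 2
  s <- 0.60 + 0.40 * (spec$gestational_age - 20) / 20
  A <- s * c(0.92, 0.80, 0.76) * half  # outer ellipsoid semi-axes (mm)

  ell <- function(center, semi) {
    # normalized squared radius <= 1 membership, vectorized via outer sums
    rx <- ((ax[[1]] - center[1]) / semi[1])^2
    ry <- ((ax[[2]] - center[2]) / semi[2])^2
    rz <- ((ax[[3]] - center[3]) / semi[3])^2
    outer(outer(rx, ry, `+`), rz, `+`) <= 1
  }

  inE0 <- ell(c(0, 0, 0), A)
  lab <- array(0L, dim = d)
  lab[inE0] <- 1L                                   # eCSF
  lab[ell(c(0, 0, 0), 0.87 * A)] <- 2L              # cortical gray matter
  lab[ell(c(0, 0, 0), 0.60 * A)] <- 3L              # white matter
  lab[ell(c(0, 0.02 * A[2], 0.05 * A[3]),
          c(0.26, 0.30, 0.26) * A)] <- 4L           # deep gray matter
  for (sgn in c(-1, 1)) {
    lab[ell(c(sgn * 0.40 * A[1], 0.08 * A[2], 0.10 * A[3]),
            c(0.14, 0.28, 0.18) * A)] <- 5L         # ventricles (paired)
  }
  cb <- ell(c(0, -0.62 * A[2], -0.50 * A[3]),
            c(0.40, 0.28, 0.26) * A) & inE0
  lab[cb] <- 6L                                     # cerebellum + vermis
  bs <- ell(c(0, -0.12 * A[2], -0.48 * A[3]),
            c(0.22, 0.22, 0.42) * A) & inE0
  lab[bs] <- 7L                                     # brainstem

  nm <- region_names()
  counts <- tabulate(lab, nbins = 7)
  if (any(counts == 0)) {
    stop(sprintf("grid too small to host region(s): %s",
                 paste(nm[counts == 0], collapse = ", ")))
  }
  structure(list(labels = lab, affine = .volume_affine(d, vs),
                 voxel_size = vs, label_names = nm),
            class = "label_volume")
}

#' Tissue parameters (T2*, S0) for the seven regions
#'
#' Per-region T2* values come from the normative reference table
#' interpolated at the requested gestational age; proton-density-like S0
#' values are fixed package conventions (fluid high, parenchyma lower) in
#' arbitrary signal units.
#'
#' @param ga Gestational age in decimal weeks.
#' @param s0_scale Global multiplier applied to all S0 values.
#' @return A data frame with columns `label`, `region`, `t2star`, `s0`.
#' @export
tissue_params <- function(ga, s0_scale = 1) {
  nm <- region_names()
  s0 <- c(eCSF = 1000, gray_matter = 850, white_matter = 800,
          deep_gray_matter = 820, ventricles = 1000, cerebellum = 850,
          brainstem = 800)
  data.frame(label = as.integer(names(nm)), region = unname(nm),
             t2star = vapply(unname(nm), lookup_reference_t2star,
                             numeric(1), ga = ga),
             s0 = unname(s0[unname(nm)]) * s0_scale,
             stringsAsFactors = FALSE)
}

#' Mono-exponential gradient-echo signal
#'
#' `S(TE) = S0 exp(-TE / T2*)`, evaluated exactly and noise-free.
#'
#' @param s0 Signal at TE = 0 (>= 0).
#' @param t2star Effective transverse relaxation time in ms (> 0).
#' @param echo_times Echo times in ms.
#' @return Numeric vector, one signal per echo time.
#' @export
#' @examples
#' simulate_signal(1000, 250, c(42, 107, 172))
simulate_signal <- function(s0, t2star, echo_times) {
  if (any(s0 < 0)) stop("s0 must be >= 0")
  if (any(t2star <= 0)) stop("t2star must be > 0")
  s0 * exp(-echo_times / t2star)
}

#' Add Rician noise to magnitude data
#'
#' Replaces each value `v` by `sqrt((v + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma` -- the
#' magnitude-image noise model of MRI. `sigma = 0` returns the input
#' unchanged; output is deterministic given `seed`.
#'
#' @param x Numeric vector or array of magnitude values.
#' @param sigma Noise standard deviation in signal units (>= 0).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Object of the same shape as `x`.
#' @export
add_rician_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  with_seed(seed, {
    n <- length(x)
    y <- sqrt((as.numeric(x) + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    if (!is.null(dim(x))) dim(y) <- dim(x)
    y
  })
}

#' Gaussian noise counterpart of [add_rician_noise()]
#'
#' Available for estimator comparisons; not the default acquisition model.
#' @inheritParams add_rician_noise
#' @return Object of the same shape as `x`.
#' @export
add_gaussian_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  with_seed(seed, {
    y <- as.numeric(x) + rnorm(length(x), 0, sigma)
    if (!is.null(dim(x))) dim(y) <- dim(x)
    y
  })
}

#' Render a noise-free multi-echo volume from labels and tissue parameters
#'
#' Voxelwise application of the mono-exponential signal model over the label
#' grid; background voxels are zero at all echoes. An optional smooth
#' within-region T2* gradient along the slice axis can be enabled through
#' `heterogeneity` (fractional modulation at the grid edges).
#'
#' @param labels A `label_volume`.
#' @param tissue A data frame as returned by [tissue_params()].
#' @param acq An [acquisition_spec()] (provides the echo times).
#' @param heterogeneity Fractional linear T2* modulation along z (default 0).
#' @return A `multiecho_volume`: list with `data` (4-D array, x-y-z-echo),
#'   `echo_times`, `affine`, `voxel_size`.
#' @export
render_multiecho <- function(labels, tissue, acq, heterogeneity = 0) {
  lab <- labels$labels
  present <- sort(unique(as.integer(lab[lab > 0])))
  missing <- setdiff(present, tissue$label)
  if (length(missing) > 0) {
    stop(sprintf("no tissue parameters for label(s): %s",
                 paste(missing, collapse = ", ")))
  }
  d <- dim(lab)
  te <- acq$echo_times
  out <- array(0, dim = c(d, length(te)))
  grad <- 1
  if (heterogeneity != 0) {
    z <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
    grad <- array(rep(1 + heterogeneity * z, each = d[1] * d[2]), dim = d)
  }
  for (l in present) {
    idx <- which(lab == l)
    row <- tissue[tissue$label == l, ]
    t2 <- if (is.array(grad)) row$t2star * grad[idx] else row$t2star
    for (e in seq_along(te)) {
      plane <- out[, , , e]
      plane[idx] <- row$s0 * exp(-te[e] / t2)
      out[, , , e] <- plane
    }
  }
  structure(list(data = out, echo_times = te, affine = labels$affine,
                 voxel_size = labels$voxel_size),
            class = "multiecho_volume")
}

#' Build a complete phantom (labels + multi-echo ground truth)
#'
#' Convenience wrapper combining [build_label_volume()], [tissue_params()]
#' and [render_multiecho()].
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acquisition_spec()].
#' @return List with elements `labels`, `tissue`, `volume`.
#' @export
build_phantom <- function(spec, acq = acquisition_spec()) {
  labels <- build_label_volume(spec)
  tissue <- tissue_params(spec$gestational_age)
  volume <- render_multiecho(labels, tissue, acq,
                             heterogeneity = spec$heterogeneity)
  list(labels = labels, tissue = tissue, volume = volume)
}
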