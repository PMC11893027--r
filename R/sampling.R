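# Slice-acquisition geometry and the shared slice forward model.
#
# A stack acquires axial (third-axis) slices of the world-space volume:
# in-plane pixel grid at the acquisition resolution, slice centres spaced by
# the slice thickness. Each pixel value is the volume integrated through a
# Gaussian slice profile (FWHM = slice thickness, 3-point Gauss-Hermite
# quadrature) and box-averaged in plane (2 x 2 subsamples). The same model
# is used by the simulator and by the reconstruction forward operator.

slice_geometry <- function(dim, voxel_size, acq) {
  extent <- dim * voxel_size
  r <- acq$in_plane_resolution
  th <- acq$slice_thickness
  nx <- as.integer(ceiling(extent[1] / r))
  ny <- as.integer(ceiling(extent[2] / r))
  ns <- as.integer(ceiling(extent[3] / th))
  list(nx = nx, ny = ny, n_slices = ns,
       in_plane = r, thickness = th, extent = extent,
       x = (seq_len(nx) - (nx + 1) / 2) * r,
       y = (seq_len(ny) - (ny + 1) / 2) * r,
       z = (seq_len(ns) - (ns + 1) / 2) * th)
}

# sample offsets (K x 3) and quadrature weights (K) for one pixel:
# 2 x 2 in-plane box subsamples crossed with 3-point Gauss-Hermite nodes of
# the Gaussian slice profile.
slice_offsets <- function(geom) {
  q <- geom$in_plane / 4
  ip <- expand.grid(du = c(-q, q), dv = c(-q, q))
  sigma <- geom$thickness / (2 * sqrt(2 * log(2)))
  gh_nodes <- c(-sqrt(3), 0, sqrt(3)) * sigma
  gh_w <- c(1 / 6, 2 / 3, 1 / 6)
  off <- cbind(du = rep(ip$du, times = 3),
               dv = rep(ip$dv, times = 3),
               dw = rep(gh_nodes, each = 4))
  list(offsets = unname(as.matrix(off)),
       weights = rep(gh_w, each = 4) / 4)
}

# Untransformed sample coordinates for slice k: (npx * K) x 3, ordered with
# all pixels of offset 1 first, then offset 2, ... (offset-major blocks).
slice_sample_points <- function(geom, k, off) {
  px <- cbind(rep(geom$x, times = geom$ny),
              rep(geom$y, each = geom$nx),
              geom$z[k])
  K <- nrow(off$offsets)
  npx <- nrow(px)
  pts <- matrix(0, npx * K, 3)
  for (j in seq_len(K)) {
    rows <- ((j - 1) * npx + 1):(j * npx)
    pts[rows, 1] <- px[, 1] + off$offsets[j, 1]
    pts[rows, 2] <- px[, 2] + off$offsets[j, 2]
    pts[rows, 3] <- px[, 3] + off$offsets[j, 3]
  }
  pts
}

# world -> continuous 0-based voxel coordinates
world_to_voxel <- function(pts, dim, voxel_size) {
  origin <- -(dim - 1) / 2 * voxel_size
  cbind((pts[, 1] - origin[1]) / voxel_size,
        (pts[, 2] - origin[2]) / voxel_size,
        (pts[, 3] - origin[3]) / voxel_size)
}

# Simulate one slice from a 3-D volume under a rigid transform: returns the
# npx pixel vector. `pts` are the untransformed sample points of the slice.
project_slice <- function(vol, voxel_size, pts, weights, tf = NULL) {
  if (!is.null(tf)) pts <- apply_rigid(tf, pts)
  vc <- world_to_voxel(pts, dim(vol), voxel_size)
  v <- .trilinear_sample(vol, vc)
  npx <- length(v) / length(weights)
  as.numeric(matrix(v, npx, length(weights)) %*% weights)
}

#' Sample motion-corrupted multi-echo slice stacks from a phantom volume
#'
#' Emulates the dynamic multi-echo EPI acquisition: for each dynamic and
#' slice position one rigid transform is drawn (rotations uniform within
#' +/- `motion_amplitude[1]` degrees, translations within
#' +/- `motion_amplitude[2]` mm, about the volume centroid), the sampling
#' plane is moved by it, the signal is integrated through a Gaussian slice
#' profile (FWHM = slice thickness) and box-averaged in plane to the
#' acquisition resolution. The *same* transform is applied to all echoes of
#' a given (slice, dynamic) -- echoes of one excitation share the fetal
#' position, the premise of multichannel reconstruction. Deterministic given
#' `seed`.
#'
#' @param volume A `multiecho_volume` (the ground-truth phantom signal).
#' @param acq An [acquisition_spec()].
#' @param motion_amplitude Numeric length 2: max rotation (deg), max
#'   translation (mm).
#' @param seed Integer seed for the motion draws, or `NULL`.
#' @param noise_sigma Rician noise sigma applied to the sampled slice
#'   magnitudes (0 = noiseless).
#' @return A list of `slice_stack` objects, one per echo. Each holds `data`
#'   (array nx x ny x n_slices x n_dynamics), the shared `transforms` data
#'   frame (slice, dynamic, rx, ry, rz, tx, ty, tz), `geometry`, `echo`,
#'   `echo_time`, and `source_voxel_size`.
#' @export
sample_slice_stack <- function(volume, acq, motion_amplitude = c(0, 0),
                               seed = NULL, noise_sigma = 0) {
  if (any(motion_amplitude < 0)) stop("motion amplitude must be >= 0")
  if (acq$in_plane_resolution < volume$voxel_size) {
    stop("acquisition resolution must be coarser than or equal to the phantom resolution")
  }
  d <- dim(volume$data)[1:3]
  ne <- dim(volume$data)[4]
  geom <- slice_geometry(d, volume$voxel_size, acq)
  off <- slice_offsets(geom)
  nd <- acq$n_dynamics

  tf_table <- expand.grid(slice = seq_len(geom$n_slices),
                          dynamic = seq_len(nd))
  draws <- with_seed(seed, {
    n <- nrow(tf_table)
    cbind(rx = runif(n, -1, 1) * motion_amplitude[1],
          ry = runif(n, -1, 1) * motion_amplitude[1],
          rz = runif(n, -1, 1) * motion_amplitude[1],
          tx = runif(n, -1, 1) * motion_amplitude[2],
          ty = runif(n, -1, 1) * motion_amplitude[2],
          tz = runif(n, -1, 1) * motion_amplitude[2])
  })
  transforms <- cbind(tf_table, as.data.frame(draws))

  pts_by_slice <- lapply(seq_len(geom$n_slices), function(k) {
    slice_sample_points(geom, k, off)
  })

  stacks <- vector("list", ne)
  for (e in seq_len(ne)) {
    vol_e <- volume$data[, , , e]
    dat <- array(0, dim = c(geom$nx, geom$ny, geom$n_slices, nd))
    for (i in seq_len(nrow(transforms))) {
      k <- transforms$slice[i]
      t_i <- transforms$dynamic[i]
      tf <- rigid_transform(c(transforms$rx[i], transforms$ry[i],
                              transforms$rz[i]),
                            c(transforms$tx[i], transforms$ty[i],
                              transforms$tz[i]))
      dat[, , k, t_i] <- project_slice(vol_e, volume$voxel_size,
                                       pts_by_slice[[k]], off$weights, tf)
    }
    if (noise_sigma > 0) {
      noise_seed <- if (is.null(seed)) NULL else seed + 1000L * e
      dat <- add_rician_noise(dat, noise_sigma, seed = noise_seed)
    }
    stacks[[e]] <- structure(list(data = dat, transforms = transforms,
                                  geometry = geom, echo = e,
                                  echo_time = volume$echo_times[e],
                                  source_voxel_size = volume$voxel_size),
                             class = "slice_stack")
  }
  stacks
}

#' Simulate a complete scan (phantom + motion-corrupted stacks)
#'
#' Builds the phantom for `spec`, then samples noisy, motion-corrupted
#' slice stacks per [sample_slice_stack()].
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acquisition_spec()].
#' @return List with `labels`, `tissue`, `volume` (ground truth), `stacks`.
#' @export
simulate_scan <- function(spec, acq = acquisition_spec()) {
  ph <- build_phantom(spec, acq)
  ph$stacks <- sample_slice_stack(ph$volume, acq,
                                  motion_amplitude = spec$motion_amplitude,
                                  seed = spec$seed,
                                  noise_sigma = spec$noise_sigma)
  ph
}
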