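#' Reconstruction configuration
#'
#' Settings of the simplified multichannel rigid slice-to-volume
#' super-resolution reconstruction.
#'
#' @param target_resolution Isotropic target voxel size in mm (default 1.2).
#' @param n_outer_iterations Outer loops of (registration, outlier
#'   rejection, volume update). 0 returns the initialisation.
#' @param psf_fwhm Gaussian slice-profile FWHM in mm; defaults to the slice
#'   thickness of the input stacks.
#' @param similarity_threshold Normalised cross-correlation below which a
#'   slice is excluded, in `[-1, 1]`.
#' @param regularization_weight First-order Tikhonov weight of the volume
#'   update, per dynamic (scaled internally by the number of included
#'   dynamics). `NULL` (the default) selects it adaptively from the noise
#'   level estimated in the stack background: the squared noise-to-signal
#'   ratio, floored at 2e-4 for numerical conditioning -- so noiseless data
#'   are inverted deeply while noisy data are smoothed in proportion to
#'   their noise power.
#' @param n_cg_iterations Conjugate-gradient iterations per volume update.
#' @param reference_echo Echo used to drive registration (default 3: the
#'   tissue contrast is strongest in the last echo).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(target_resolution = 1.2,
                         n_outer_iterations = 3,
                         psf_fwhm = NULL,
                         similarity_threshold = 0.8,
                         regularization_weight = NULL,
                         n_cg_iterations = 20,
                         reference_echo = 3) {
  if (target_resolution <= 0) stop("target_resolution must be > 0")
  if (similarity_threshold < -1 || similarity_threshold > 1) {
    stop("similarity_threshold must lie in [-1, 1]")
  }
  structure(list(target_resolution = target_resolution,
                 n_outer_iterations = as.integer(n_outer_iterations),
                 psf_fwhm = psf_fwhm,
                 similarity_threshold = similarity_threshold,
                 regularization_weight = regularization_weight,
                 n_cg_iterations = as.integer(n_cg_iterations),
                 reference_echo = as.integer(reference_echo)),
            class = "recon_config")
}

ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) * length(a) / (length(a) - 1)
}

# target grid helpers -------------------------------------------------------

target_grid <- function(geom, config) {
  dim <- as.integer(round(geom$extent / config$target_resolution))
  list(dim = dim, voxel_size = config$target_resolution,
       affine = .volume_affine(dim, config$target_resolution))
}

transforms_to_rigid <- function(row) {
  rigid_transform(c(row$rx, row$ry, row$rz), c(row$tx, row$ty, row$tz))
}

identity_transforms <- function(geom, n_dynamics) {
  tab <- expand.grid(slice = seq_len(geom$n_slices),
                     dynamic = seq_len(n_dynamics))
  tab$rx <- 0; tab$ry <- 0; tab$rz <- 0
  tab$tx <- 0; tab$ty <- 0; tab$tz <- 0
  tab
}

# 3-D Neumann negative Laplacian (D'D for forward differences); the
# first-order Tikhonov operator of the volume update.
neumann_laplacian <- function(x) {
  d <- dim(x)
  out <- 6 * x
  out <- out - x[c(1, seq_len(d[1] - 1)), , ] - x[c(seq_len(d[1] - 1) + 1, d[1]), , ]
  out <- out - x[, c(1, seq_len(d[2] - 1)), ] - x[, c(seq_len(d[2] - 1) + 1, d[2]), ]
  out <- out - x[, , c(1, seq_len(d[3] - 1))] - x[, , c(seq_len(d[3] - 1) + 1, d[3])]
  out
}

# Rayleigh-based noise estimate from the in-plane FOV corners of the
# stacks, which the inscribed brain never reaches: for pure background
# magnitude data E[v^2] = 2 sigma^2.
estimate_stack_noise <- function(stacks, margin = 3) {
  vals <- unlist(lapply(stacks, function(st) {
    d <- dim(st$data)
    ix <- c(seq_len(margin), d[1] - seq_len(margin) + 1)
    iy <- c(seq_len(margin), d[2] - seq_len(margin) + 1)
    as.numeric(st$data[ix, iy, , ])
  }))
  sqrt(mean(vals^2) / 2)
}

# adaptive Tikhonov weight: squared noise-to-signal ratio with a
# conditioning floor
auto_regularization <- function(stacks, floor = 2e-4) {
  sigma <- estimate_stack_noise(stacks)
  if (sigma <= 0) return(floor)
  v <- unlist(lapply(stacks, function(st) as.numeric(st$data)))
  fg <- v[v > 5 * sigma]
  if (length(fg) < 10) return(floor)
  max(floor, (sigma / mean(fg))^2)
}

# Per-slice sampling system: untransformed sample points per slice position,
# shared across dynamics and echoes.
recon_sampling <- function(geom) {
  off <- slice_offsets(geom)
  pts <- lapply(seq_len(geom$n_slices), function(k) {
    slice_sample_points(geom, k, off)
  })
  list(off = off, pts = pts)
}

# transformed sample coordinates (voxel units of the target grid) for every
# included (slice, dynamic); returns a list parallel to the rows of `rows`.
system_coords <- function(rows, samp, grid) {
  lapply(seq_len(nrow(rows)), function(i) {
    tf <- transforms_to_rigid(rows[i, ])
    world_to_voxel(apply_rigid(tf, samp$pts[[rows$slice[i]]]),
                   grid$dim, grid$voxel_size)
  })
}

#' Initialise a reconstruction volume by PSF-weighted scatter averaging
#'
#' Splats every slice sample onto the target grid at its nominal
#' (identity-motion) position with its quadrature weight and normalises by
#' the accumulated weight. Voxels receiving zero weight are flagged invalid.
#'
#' @param stacks List of `slice_stack` objects (one per echo), as produced
#'   by [sample_slice_stack()].
#' @param config A [recon_config()].
#' @return A `multiecho_volume` with an additional `valid` mask and the
#'   accumulated `weight` array.
#' @export
initialize_volume <- function(stacks, config = recon_config()) {
  if (length(stacks) == 0) stop("no slice stacks supplied")
  geom <- stacks[[1]]$geometry
  grid <- target_grid(geom, config)
  samp <- recon_sampling(geom)
  nd <- dim(stacks[[1]]$data)[4]
  rows <- identity_transforms(geom, nd)
  init <- .scatter_average(stacks, rows, samp, grid)
  structure(list(data = init$data,
                 echo_times = vapply(stacks, `[[`, numeric(1), "echo_time"),
                 affine = grid$affine, voxel_size = grid$voxel_size,
                 valid = init$valid, weight = init$weight),
            class = "multiecho_volume")
}

# PSF-weighted scatter average of the given (slice, dynamic) rows onto the
# target grid; rows carry the transforms to use.
.scatter_average <- function(stacks, rows, samp, grid) {
  coords <- system_coords(rows, samp, grid)
  geom <- stacks[[1]]$geometry
  npx <- geom$nx * geom$ny
  wacc <- array(0, dim = grid$dim)
  wvals <- rep(samp$off$weights, each = npx)
  for (i in seq_len(nrow(rows))) {
    .trilinear_splat(wacc, coords[[i]], wvals)
  }
  if (all(wacc == 0)) stop("no slice intersects the target grid")
  ne <- length(stacks)
  data <- array(0, dim = c(grid$dim, ne))
  ok <- wacc > 1e-8
  for (e in seq_len(ne)) {
    acc <- array(0, dim = grid$dim)
    for (i in seq_len(nrow(rows))) {
      b <- as.numeric(stacks[[e]]$data[, , rows$slice[i], rows$dynamic[i]])
      .trilinear_splat(acc, coords[[i]], as.vector(b %o% samp$off$weights))
    }
    v <- array(0, dim = grid$dim)
    v[ok] <- acc[ok] / wacc[ok]
    data[, , , e] <- v
  }
  list(data = data, valid = ok, weight = wacc)
}

#' Register one slice to a volume
#'
#' Finds the rigid transform maximising the normalised cross-correlation
#' between the observed slice and the slice-profile projection of the
#' volume, by multi-start Nelder-Mead refinement from `init`. The
#' similarity at the returned transform is never below the similarity at
#' `init`. A constant (degenerate) slice is returned unchanged with an
#' undefined score.
#'
#' @param slice_pixels Numeric vector of observed slice pixel values.
#' @param volume 3-D array (one echo of the current reconstruction).
#' @param voxel_size Voxel size of `volume` in mm.
#' @param pts Untransformed sample points of the slice (from the stack
#'   geometry).
#' @param weights Quadrature weights matching `pts`.
#' @param init Numeric length 6 initial parameters
#'   (rx, ry, rz, tx, ty, tz) in degrees / mm.
#' @param multi_start Number of perturbed restarts (>= 1).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param mask Optional logical vector over the slice pixels restricting the
#'   similarity to object-containing pixels; background-dominated NCC is
#'   uninformative, so callers normally pass a signal mask.
#' @return List with `par` (length 6) and `score` (NCC, `NA` if undefined).
#' @export
register_slice_to_volume <- function(slice_pixels, volume, voxel_size,
                                     pts, weights, init = rep(0, 6),
                                     multi_start = 5, maxit = 150,
                                     mask = NULL) {
  b <- as.numeric(slice_pixels)
  if (is.null(mask)) mask <- rep(TRUE, length(b))
  if (sum(mask) < 8 || sd(b[mask]) == 0) {
    return(list(par = init, score = NA_real_))
  }
  bm <- b[mask]
  obj <- function(par) {
    tf <- rigid_transform(par[1:3], par[4:6])
    s <- project_slice(volume, voxel_size, pts, weights, tf)
    v <- ncc(s[mask], bm)
    if (is.na(v)) -1 else v
  }
  s0 <- obj(init)
  if (s0 > 0.9995) return(list(par = init, score = s0))
  deltas <- rbind(rep(0, 6),
                  c( 2,  2,  2, 0, 0, 0), c(-2, -2, -2, 0, 0, 0),
                  c( 0,  0,  0, 2, 2, 2), c( 0,  0,  0, -2, -2, -2),
                  c( 2, -2,  2, -2, 2, -2), c(-2, 2, -2, 2, -2, 2))
  n_starts <- min(multi_start, nrow(deltas))
  best <- list(par = init, score = s0)
  for (j in seq_len(n_starts)) {
    fit <- optim(init + deltas[j, ], obj, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = maxit,
                                reltol = 1e-7))
    if (fit$value > best$score) best <- list(par = fit$par, score = fit$value)
  }
  best$par[1:3] <- wrap_angle(best$par[1:3])
  best
}

#' Share motion estimates across echoes
#'
#' Transforms are estimated once on the reference echo and applied to every
#' echo; each echo receives an independent copy.
#'
#' @param reference_transforms Data frame of per-(slice, dynamic) transform
#'   parameters estimated on the reference echo.
#' @param n_echoes Number of echoes.
#' @return List of `n_echoes` copies of the transform table.
#' @export
share_transforms <- function(reference_transforms, n_echoes = 3) {
  lapply(seq_len(n_echoes), function(e) reference_transforms)
}

#' Exclude motion-corrupted slices and dynamics
#'
#' A slice is excluded iff its post-registration NCC against the current
#' reconstruction falls below `threshold`; a whole dynamic is excluded iff
#' more than half of its slices are excluded. Slices with undefined scores
#' (constant data, typically pure background) are kept.
#'
#' @param scores Data frame with columns `slice`, `dynamic`, `score`.
#' @param threshold NCC threshold in `[-1, 1]`.
#' @return The input with a logical `include` column added.
#' @export
reject_outliers <- function(scores, threshold = 0.8) {
  if (threshold < -1 || threshold > 1) {
    stop("threshold must lie in [-1, 1]")
  }
  include <- is.na(scores$score) | scores$score >= threshold
  for (d in unique(scores$dynamic)) {
    rows <- scores$dynamic == d
    if (mean(!include[rows]) > 0.5) include[rows] <- FALSE
  }
  scores$include <- include
  scores
}

# regularised least-squares volume update under the slice forward model:
# minimises ||A x - b||^2 + lambda ||grad x||^2 by conjugate gradients,
# warm-started from x0. `coords` holds per-included-slice sample
# coordinates in target voxel units; `bs` the matching pixel vectors.
solve_volume_cg <- function(x0, coords, bs, weights, lambda, n_iter) {
  dimv <- dim(x0)
  K <- length(weights)
  npx <- length(bs[[1]])
  wrep <- rep(weights, each = npx)

  A <- function(x) {
    lapply(coords, function(vc) {
      as.numeric(matrix(.trilinear_sample(x, vc), npx, K) %*% weights)
    })
  }
  At <- function(rs) {
    acc <- array(0, dim = dimv)
    for (i in seq_along(coords)) {
      .trilinear_splat(acc, coords[[i]], as.vector(rs[[i]] %o% weights))
    }
    acc
  }
  Nop <- function(x) At(A(x)) + lambda * neumann_laplacian(x)

  rhs <- At(bs)
  x <- x0
  r <- rhs - Nop(x)
  p <- r
  rs_old <- sum(r * r)
  if (rs_old == 0) return(x)
  for (it in seq_len(n_iter)) {
    Np <- Nop(p)
    denom <- sum(p * Np)
    if (!is.finite(denom) || denom <= 0) break
    alpha <- rs_old / denom
    x <- x + alpha * p
    r <- r - alpha * Np
    rs_new <- sum(r * r)
    if (rs_new < 1e-12 * rs_old) break
    p <- r + (rs_new / rs_old) * p
    rs_old <- rs_new
  }
  x
}

#' Multichannel rigid slice-to-volume super-resolution reconstruction
#'
#' Alternates (a) per-slice rigid registration of the reference echo to the
#' current reconstruction, (b) NCC-based slice/dynamic outlier rejection,
#' and (c) a regularised least-squares volume update under the Gaussian
#' slice-profile forward model, for `n_outer_iterations` outer loops. Motion
#' is estimated once per (slice, dynamic) and shared across echoes; all
#' echoes are reconstructed on the common 1.2 mm target grid. With
#' `n_outer_iterations = 0` the PSF-weighted initialisation is returned.
#'
#' @param stacks List of `slice_stack` objects, one per echo.
#' @param config A [recon_config()].
#' @param true_transforms Optional data frame of ground-truth transforms;
#'   when supplied, registration is skipped and these are used directly
#'   (for oracle experiments).
#' @return A `multiecho_volume` with fields `valid` (coverage mask) and
#'   `provenance` (list: per-iteration mean NCC, exclusions, convergence
#'   flag, config echo).
#' @export
super_resolve <- function(stacks, config = recon_config(),
                          true_transforms = NULL) {
  ne <- length(stacks)
  geom <- stacks[[1]]$geometry
  grid <- target_grid(geom, config)
  samp <- recon_sampling(geom)
  nd <- dim(stacks[[1]]$data)[4]
  ref <- min(config$reference_echo, ne)

  lambda0 <- config$regularization_weight
  sigma_hat <- estimate_stack_noise(stacks)
  if (is.null(lambda0)) lambda0 <- auto_regularization(stacks)
  # NCC of a noisy slice against its noise-free projection is attenuated by
  # sqrt(1 - sigma^2 / var(b)); correct the score so the exclusion
  # threshold measures motion mismatch, not noise level
  correct_ncc <- function(score, b) {
    if (is.na(score) || sigma_hat == 0) return(score)
    v <- var(as.numeric(b))
    if (v <= sigma_hat^2 * 1.05) return(NA_real_)  # noise-dominated slice
    min(1, score / sqrt(1 - sigma_hat^2 / v))
  }

  init <- initialize_volume(stacks, config)
  vols <- lapply(seq_len(ne), function(e) init$data[, , , e])
  est <- identity_transforms(geom, nd)
  est$score <- NA_real_
  prov <- list(mean_ncc = numeric(0), n_excluded = integer(0),
               converged = TRUE, lambda = lambda0)

  if (config$n_outer_iterations >= 1) {
    for (it in seq_len(config$n_outer_iterations)) {
      # (a) registration on the reference echo (or oracle transforms)
      if (is.null(true_transforms)) {
        ms <- if (it == 1) 5 else 1
        mi <- if (it == 1) 150 else 80
        for (i in seq_len(nrow(est))) {
          b <- stacks[[ref]]$data[, , est$slice[i], est$dynamic[i]]
          fit <- register_slice_to_volume(
            b, vols[[ref]], grid$voxel_size,
            samp$pts[[est$slice[i]]], samp$off$weights,
            init = as.numeric(est[i, c("rx", "ry", "rz", "tx", "ty", "tz")]),
            multi_start = ms, maxit = mi)
          est[i, c("rx", "ry", "rz", "tx", "ty", "tz")] <- fit$par
          est$score[i] <- correct_ncc(fit$score, b)
        }
      } else {
        est[, c("rx", "ry", "rz", "tx", "ty", "tz")] <-
          true_transforms[, c("rx", "ry", "rz", "tx", "ty", "tz")]
        for (i in seq_len(nrow(est))) {
          b <- as.numeric(stacks[[ref]]$data[, , est$slice[i], est$dynamic[i]])
          if (sd(b) == 0) { est$score[i] <- NA_real_; next }
          tf <- transforms_to_rigid(est[i, ])
          s <- project_slice(vols[[ref]], grid$voxel_size,
                             samp$pts[[est$slice[i]]], samp$off$weights, tf)
          est$score[i] <- correct_ncc(ncc(s, b), b)
        }
      }

      # (b) outlier rejection
      mask <- reject_outliers(est[, c("slice", "dynamic", "score")],
                              config$similarity_threshold)
      keep <- which(mask$include)
      n_dyn_inc <- length(unique(est$dynamic[keep]))

      # (c) shared-transform volume update, all echoes
      # one transform set, shared verbatim by every echo's forward model
      coords <- system_coords(est[keep, ], samp, grid)
      lambda <- lambda0 * max(1, n_dyn_inc)
      if (it == 1) {
        # restart from a motion-compensated scatter average of the included
        # slices only: excluded slices then have zero influence on the
        # result, and the volume update starts from registered geometry
        clean <- .scatter_average(stacks, est[keep, ], samp, grid)
        vols <- lapply(seq_len(ne), function(e) clean$data[, , , e])
      }
      prev <- vols
      for (e in seq_len(ne)) {
        bs <- lapply(keep, function(i) {
          as.numeric(stacks[[e]]$data[, , est$slice[i], est$dynamic[i]])
        })
        vols[[e]] <- solve_volume_cg(vols[[e]], coords, bs,
                                     samp$off$weights, lambda,
                                     config$n_cg_iterations)
      }
      prov$mean_ncc <- c(prov$mean_ncc,
                         mean(est$score[keep], na.rm = TRUE))
      prov$n_excluded <- c(prov$n_excluded, sum(!mask$include))
      rel <- sqrt(sum((vols[[ref]] - prev[[ref]])^2)) /
        max(sqrt(sum(prev[[ref]]^2)), 1e-12)
      prov$final_relative_update <- rel
    }
    if (isTRUE(prov$final_relative_update > 0.1)) {
      prov$converged <- FALSE
      warning("reconstruction did not converge: relative volume update ",
              sprintf("%.1f%%", 100 * prov$final_relative_update),
              " after the final iteration")
    }
    prov$transforms <- est
    prov$exclusions <- mask[!mask$include, c("slice", "dynamic", "score")]
  } else {
    prov$transforms <- est
    prov$exclusions <- est[0, c("slice", "dynamic")]
  }

  data <- array(0, dim = c(grid$dim, ne))
  for (e in seq_len(ne)) data[, , , e] <- vols[[e]]
  structure(list(data = data, echo_times = init$echo_times,
                 affine = grid$affine, voxel_size = grid$voxel_size,
                 valid = init$valid, provenance = prov),
            class = "multiecho_volume")
}
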