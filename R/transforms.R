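#' Rigid world-space transform
#'
#' A 6-parameter rigid transform acting on world coordinates (mm) about a
#' fixed centre: `T(x) = R (x - c) + c + t`, with `R` the ZYX Euler rotation
#' built from `rotations` (degrees, applied as Rz Ry Rx) and `t` the
#' translation in mm. Rotation angles are wrapped to `(-180, 180]`.
#'
#' @param rotations Numeric length 3, rotations about x, y, z in degrees.
#' @param translations Numeric length 3, translation in mm.
#' @param center Numeric length 3, world-space centre of rotation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0),
                            translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3, length(translations) == 3,
            length(center) == 3)
  structure(list(rotations = wrap_angle(as.numeric(rotations)),
                 translations = as.numeric(translations),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm\n",
              x$rotations[1], x$rotations[2], x$rotations[3],
              x$translations[1], x$translations[2], x$translations[3]))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' ZYX Euler convention: `R = Rz(rz) Ry(ry) Rx(rx)`, angles in degrees.
#'
#' @param rotations Numeric length 3 (degrees).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(rotations) {
  r <- rotations * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (ZYX, degrees) from a rotation matrix; the standard
# extraction, stable away from the ry = +-90 deg gimbal lock.
euler_from_matrix <- function(R) {
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param tf A [rigid_transform()].
#' @param pts Numeric matrix, n x 3, world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_rigid <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  R <- rotation_matrix(tf$rotations)
  shift <- tf$center + tf$translations - as.numeric(R %*% tf$center)
  out <- pts %*% t(R)
  out[, 1] <- out[, 1] + shift[1]
  out[, 2] <- out[, 2] + shift[2]
  out[, 3] <- out[, 3] + shift[3]
  out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`(a %then% b)(x) = a(b(x))`), expressed about the centre of `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_rigid <- function(a, b) {
  Ra <- rotation_matrix(a$rotations)
  Rb <- rotation_matrix(b$rotations)
  R <- Ra %*% Rb
  # total affine offset: a(b(x)) = R x + d
  da <- a$center + a$translations - as.numeric(Ra %*% a$center)
  db <- b$center + b$translations - as.numeric(Rb %*% b$center)
  d <- as.numeric(Ra %*% db) + da
  # re-express about a's centre: t = d - c + R c
  t <- d - a$center + as.numeric(R %*% a$center)
  rigid_transform(euler_from_matrix(R), t, a$center)
}

#' Invert a rigid transform
#'
#' @param tf A [rigid_transform()].
#' @return The inverse transform, about the same centre.
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(tf$rotations)
  Ri <- t(R)
  # affine form T(x) = R x + d; inverse is Ri y - Ri d, re-expressed about
  # the same centre c: translation t' = Ri (c - d) - c
  d <- tf$center + tf$translations - as.numeric(R %*% tf$center)
  t_inv <- as.numeric(Ri %*% (tf$center - d)) - tf$center
  rigid_transform(euler_from_matrix(Ri), t_inv, tf$center)
}

# identity check helper used in tests
is_identity_rigid <- function(tf, tol = 1e-6) {
  max(abs(tf$rotations)) < tol && max(abs(tf$translations)) < tol
}
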