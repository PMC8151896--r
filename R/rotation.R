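#' Rotation utilities
#'
#' Rotations are stored as 3x3 orthonormal matrices with determinant +1.
#' Throughout the package a *set* of n rotations is an n x 9 numeric matrix
#' whose rows are the row-major entries (R11, R12, R13, R21, ..., R33); a
#' single rotation may be given either as a 3x3 matrix or a length-9
#' vector. Axis-angle vectors encode the rotation axis as the vector
#' direction and the rotation angle (radians) as its norm.
#'
#' @name rotations
NULL

ROT_TOL <- 1e-9

as_rot9 <- function(r) {
  if (is.matrix(r) && all(dim(r) == c(3L, 3L))) {
    matrix(as.numeric(t(r)), nrow = 1L)
  } else if (is.numeric(r) && length(r) == 9L) {
    matrix(as.numeric(r), nrow = 1L)
  } else if (is.matrix(r) && ncol(r) == 9L) {
    r
  } else {
    stop("rotation must be a 3x3 matrix, a length-9 vector, or an n x 9 matrix")
  }
}

rot9_to_mat <- function(r9, i = 1L) matrix(r9[i, ], 3L, 3L, byrow = TRUE)

#' @describeIn rotations Check orthonormality and determinant of rotations.
#'   Returns a logical vector, one entry per rotation.
#' @param r rotations (3x3 matrix, length-9 vector, or n x 9 matrix)
#' @param tol numerical tolerance for orthonormality and determinant
#' @export
rot_valid <- function(r, tol = 1e-9) {
  r9 <- as_rot9(r)
  ok <- logical(nrow(r9))
  for (i in seq_len(nrow(r9))) {
    m <- rot9_to_mat(r9, i)
    ok[i] <- all(is.finite(m)) &&
      max(abs(crossprod(m) - diag(3))) <= tol &&
      abs(det(m) - 1) <= tol
  }
  ok
}

assert_rotation <- function(r, what = "rotation", tol = 1e-9) {
  if (!all(rot_valid(r, tol))) {
    stop(sprintf("%s is not a valid rotation matrix (orthonormal, det +1 within %g)",
                 what, tol), call. = FALSE)
  }
  invisible(r)
}

#' @describeIn rotations Project arbitrary 3x3 matrices onto the nearest
#'   rotation (polar projection via SVD); used to repair file-loaded
#'   matrices.
#' @export
rot_project <- function(r) {
  r9 <- as_rot9(r)
  out <- r9
  for (i in seq_len(nrow(r9))) {
    s <- svd(rot9_to_mat(r9, i))
    m <- s$u %*% t(s$v)
    if (det(m) < 0) m <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
    out[i, ] <- as.numeric(t(m))
  }
  if (is.matrix(r) && all(dim(r) == c(3L, 3L))) rot9_to_mat(out) else out
}

# rowwise composition of n x 9 rotation sets: C = A %*% B per row
rot9_compose <- function(a, b) {
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  out <- matrix(0, nrow(a), 9L)
  # row-major layout: entry (i,j) of the product at column 3*(i-1)+j
  for (i in 1:3) for (j in 1:3) {
    ai <- 3L * (i - 1L)
    out[, ai + j] <- a[, ai + 1L] * b[, j] + a[, ai + 2L] * b[, 3L + j] +
      a[, ai + 3L] * b[, 6L + j]
  }
  out
}

rot9_transpose <- function(a) {
  a[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE]
}

# rowwise rotate 3-vectors: out_i = R_i %*% v_i  (v: n x 3)
rot9_apply <- function(r9, v) {
  if (nrow(r9) == 1L && nrow(v) > 1L) r9 <- r9[rep(1L, nrow(v)), , drop = FALSE]
  cbind(
    r9[, 1L] * v[, 1L] + r9[, 2L] * v[, 2L] + r9[, 3L] * v[, 3L],
    r9[, 4L] * v[, 1L] + r9[, 5L] * v[, 2L] + r9[, 6L] * v[, 3L],
    r9[, 7L] * v[, 1L] + r9[, 8L] * v[, 2L] + r9[, 9L] * v[, 3L]
  )
}

#' @describeIn rotations Convert axis-angle vectors (n x 3, angle = norm,
#'   radians) to rotations (n x 9, row-major). The zero vector maps to the
#'   identity.
#' @param v axis-angle vectors, n x 3 matrix or length-3 vector
#' @export
axis_angle_to_rotation <- function(v) {
  single <- !is.matrix(v)
  if (single) v <- matrix(v, nrow = 1L)
  stopifnot(ncol(v) == 3L)
  th <- sqrt(rowSums(v^2))
  # unit axis; arbitrary for zero angle (rotation is identity anyway)
  safe <- pmax(th, .Machine$double.eps)
  kx <- v[, 1L] / safe; ky <- v[, 2L] / safe; kz <- v[, 3L] / safe
  c1 <- cos(th); s1 <- sin(th); ic <- 1 - c1
  out <- cbind(
    c1 + kx * kx * ic,      kx * ky * ic - kz * s1, kx * kz * ic + ky * s1,
    ky * kx * ic + kz * s1, c1 + ky * ky * ic,      ky * kz * ic - kx * s1,
    kz * kx * ic - ky * s1, kz * ky * ic + kx * s1, c1 + kz * kz * ic
  )
  out[th == 0, ] <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = sum(th == 0))
  if (single) rot9_to_mat(out) else out
}

#' @describeIn rotations Convert rotations to axis-angle vectors. Angles
#'   near pi use the stable largest-diagonal-element branch.
#' @export
rotation_to_axis_angle <- function(r) {
  single <- is.matrix(r) && all(dim(r) == c(3L, 3L)) || (!is.matrix(r) && length(r) == 9L)
  r9 <- as_rot9(r)
  tr <- r9[, 1L] + r9[, 5L] + r9[, 9L]
  cth <- pmin(pmax((tr - 1) / 2, -1), 1)
  th <- acos(cth)
  out <- matrix(0, nrow(r9), 3L)
  # generic branch: axis from the skew part
  sx <- r9[, 8L] - r9[, 6L]
  sy <- r9[, 3L] - r9[, 7L]
  sz <- r9[, 4L] - r9[, 2L]
  generic <- th > 1e-7 & th < pi - 1e-4
  if (any(generic)) {
    f <- th[generic] / (2 * sin(th[generic]))
    out[generic, ] <- cbind(sx[generic] * f, sy[generic] * f, sz[generic] * f)
  }
  near_pi <- th >= pi - 1e-4
  for (i in which(near_pi)) {
    m <- rot9_to_mat(r9, i)
    # axis from the largest diagonal of (R + I)/2 = kk^T near theta = pi
    b <- (m + diag(3)) / 2
    j <- which.max(diag(b))
    ax <- b[, j] / sqrt(max(b[j, j], .Machine$double.eps))
    ax <- ax / sqrt(sum(ax^2))
    # fix sign using the skew part where it is not degenerate
    sk <- c(sx[i], sy[i], sz[i])
    if (sum(ax * sk) < 0) ax <- -ax
    out[i, ] <- ax * th[i]
  }
  small <- th <= 1e-7
  if (any(small)) {
    # first-order: R ~ I + [v]_x
    out[small, ] <- cbind(sx[small] / 2, sy[small] / 2, sz[small] / 2)
  }
  if (single) as.numeric(out[1L, ]) else out
}

#' Sensor-to-bone calibration
#'
#' During calibration the subject holds a known static pose; the worn
#' sensor reports its world orientation `world_sensor` while the bone's
#' world orientation `known_bone` is known from the pose. The fixed
#' sensor-to-bone rotation `SBR` satisfying
#' `known_bone = world_sensor %*% SBR` is recovered as
#' `t(world_sensor) %*% known_bone`.
#'
#' @param world_sensor 3x3 world orientation of the sensor
#' @param known_bone 3x3 world orientation of the bone in the calibration pose
#' @return the 3x3 sensor-to-bone rotation
#' @export
#' @examples
#' R <- axis_angle_to_rotation(c(0, 0, pi / 4))
#' calibrate_sensor(R, R)  # identity: sensor frame coincides with bone frame
calibrate_sensor <- function(world_sensor, known_bone) {
  assert_rotation(world_sensor, "world_sensor")
  assert_rotation(known_bone, "known_bone")
  ws <- if (is.matrix(world_sensor)) world_sensor else rot9_to_mat(as_rot9(world_sensor))
  kb <- if (is.matrix(known_bone)) known_bone else rot9_to_mat(as_rot9(known_bone))
  t(ws) %*% kb
}

#' Angular error between rotations
#'
#' The posture-reconstruction error metric: the angle (degrees, in
#' [0, 180]) of the relative rotation `t(predicted) %*% actual`, computed
#' from its trace as `acos((trace - 1) / 2)` with the trace argument
#' clamped to [-1, 1].
#'
#' @param predicted,actual rotations: 3x3 matrices or n x 9 row-major sets
#' @return numeric vector of angles in degrees
#' @export
#' @examples
#' angular_error(diag(3), axis_angle_to_rotation(c(0, 0, pi / 6)))  # 30
angular_error <- function(predicted, actual) {
  p <- as_rot9(predicted); a <- as_rot9(actual)
  if (nrow(p) == 1L && nrow(a) > 1L) p <- p[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) == 1L && nrow(p) > 1L) a <- a[rep(1L, nrow(p)), , drop = FALSE]
  # trace(t(P) A) = sum of elementwise products
  tr <- rowSums(p * a)
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}
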