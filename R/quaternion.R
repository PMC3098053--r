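# Unit-quaternion rotations. Quaternions are length-4 numeric vectors
# (w, x, y, z); q and -q denote the same rotation (double cover).

#' Create a unit-quaternion rotation
#'
#' @param q Numeric vector of length 4 `(w, x, y, z)`. It is normalized to
#'   unit length; the zero quaternion is rejected.
#' @return An object of class `"rotation"`: a unit quaternion.
#' @examples
#' rotation(c(1, 0, 0, 0))            # identity
#' rotation_axis_angle(c(0, 0, 1), 90)  # 90 degrees about z
#' @export
rotation <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L || any(!is.finite(q))) {
    stop("a rotation quaternion must be 4 finite numbers", call. = FALSE)
  }
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion does not define a rotation", call. = FALSE)
  structure(q / n, class = "rotation")
}

#' @export
print.rotation <- function(x, ...) {
  aa <- rotation_to_axis_angle(x)
  cat(sprintf("<rotation> q = (% .4f, % .4f, % .4f, % .4f)  |  %.2f deg about (%.3f, %.3f, %.3f)\n",
              x[1], x[2], x[3], x[4], aa$angle, aa$axis[1], aa$axis[2], aa$axis[3]))
  invisible(x)
}

#' Identity rotation
#' @return The identity `rotation`.
#' @export
rotation_identity <- function() rotation(c(1, 0, 0, 0))

#' Rotation from axis and angle
#'
#' @param axis Numeric length-3 axis (need not be normalized).
#' @param angle_deg Rotation angle in degrees.
#' @return A `rotation`.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  half <- angle_deg * pi / 360
  rotation(c(cos(half), sin(half) * axis / n))
}

#' Convert a rotation to its axis-angle form
#' @param r A `rotation`.
#' @return List with `axis` (unit 3-vector) and `angle` (degrees in \[0, 180\]).
#' @export
rotation_to_axis_angle <- function(r) {
  q <- unclass(r)
  if (q[1] < 0) q <- -q  # canonical hemisphere: angle in [0, 180]
  ang <- 2 * acos(min(1, max(-1, q[1])))
  s <- sqrt(max(0, 1 - q[1]^2))
  axis <- if (s < 1e-12) c(0, 0, 1) else q[2:4] / s
  list(axis = axis, angle = ang * 180 / pi)
}

#' Rotation matrix of a unit quaternion
#' @param r A `rotation` (or length-4 numeric).
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(r) {
  q <- as.numeric(r) / sqrt(sum(as.numeric(r)^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotation from a (proper) rotation matrix
#' @param R 3x3 rotation matrix.
#' @return A `rotation`.
#' @export
rotation_from_matrix <- function(R) {
  # Shepperd's method: pick the largest of the four candidate pivots.
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  rotation(q)
}

#' Compose two rotations
#' @param r1,r2 Rotations; the result applies `r2` first, then `r1`.
#' @return A `rotation`.
#' @export
rotation_compose <- function(r1, r2) {
  a <- as.numeric(r1); b <- as.numeric(r2)
  rotation(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ))
}

#' Inverse rotation
#' @param r A `rotation`.
#' @return The inverse `rotation`.
#' @export
rotation_inverse <- function(r) {
  q <- as.numeric(r)
  rotation(c(q[1], -q[2:4]))
}

#' Angular distance between two rotations
#'
#' Angle of the relative rotation `r1^-1 r2`, invariant under quaternion
#' sign flips. Used to decide whether two local minima of the match score
#' are genuinely different orientations.
#'
#' @param r1,r2 Rotations (unit quaternions).
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_separation <- function(r1, r2) {
  d <- abs(sum(as.numeric(r1) * as.numeric(r2)))
  2 * acos(min(1, d)) * 180 / pi
}

#' Uniform (Haar) random rotations
#'
#' Draws unit quaternions as normalized 4D standard Gaussians, which is
#' exactly uniform on the rotation group.
#'
#' @param n Number of rotations.
#' @return An `n x 4` matrix of unit quaternions (rows).
#' @export
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q / sqrt(rowSums(q^2))
}
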