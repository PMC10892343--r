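#' Construct a quaternion
#'
#' Quaternions are stored scalar-first as numeric vectors \code{c(w, x, y, z)}.
#' A unit quaternion \code{q} represents the rotation taking sensor-frame
#' vectors into the Earth (ENU) frame through the sandwich product
#' \code{q (0,v) q*}; the conjugate maps Earth to sensor.  \code{q} and
#' \code{-q} represent the same rotation.
#'
#' @param w,x,y,z components (scalar part first).
#' @return numeric vector of length 4 with class \code{"quaternion"}.
#' @export
#' @examples
#' quat(1, 0, 0, 0)            # identity rotation
#' quat_from_axis_angle(c(1, 0, 0), pi / 2)
quat <- function(w = 1, x = 0, y = 0, z = 0) {
  q <- c(w, x, y, z)
  if (length(q) != 4L || !all(is.finite(q)))
    stop("quaternion needs 4 finite components")
  structure(q, class = "quaternion")
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("<quaternion w=%.6g x=%.6g y=%.6g z=%.6g>\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

as_quat <- function(q) {
  if (inherits(q, "quaternion")) return(q)
  quat(q[1], q[2], q[3], q[4])
}

#' Quaternion norm
#' @param q quaternion (length-4 numeric, scalar first).
#' @return Euclidean norm of the 4 components.
#' @export
quat_norm <- function(q) sqrt(sum(q^2))

#' Normalize a quaternion to unit norm
#'
#' @param q quaternion.
#' @return unit quaternion; errors on (near-)zero norm.
#' @export
quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (n < 1e-12) stop("cannot normalize a zero-norm quaternion")
  structure(q / n, class = "quaternion")
}

#' Quaternion conjugate
#' @param q quaternion.
#' @return \code{c(w, -x, -y, -z)}.
#' @export
quat_conjugate <- function(q) structure(c(q[1], -q[2], -q[3], -q[4]),
                                        class = "quaternion")

#' Hamilton product of two quaternions
#'
#' Right-handed Hamilton convention: \code{quat_multiply(a, b)} is the
#' rotation \code{b} followed by \code{a}.  The product norm is the product
#' of the norms.
#'
#' @param a,b quaternions (scalar-first).
#' @return quaternion \code{a %*% b} in the Hamilton sense.
#' @export
quat_multiply <- function(a, b) {
  structure(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ), class = "quaternion")
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes the vector part of \code{q (0,v) q*}, i.e. applies the rotation
#' that \code{q} represents (sensor frame to Earth frame under the package
#' convention).  Preserves the Euclidean norm.
#'
#' @param q unit quaternion.
#' @param v numeric length-3 vector.
#' @param tol tolerance on \code{|norm(q) - 1|}.
#' @return rotated length-3 vector.
#' @export
quat_rotate <- function(q, v, tol = 1e-6) {
  if (abs(quat_norm(q) - 1) > tol)
    stop("quat_rotate requires a unit quaternion")
  w <- q[1]; u <- q[2:4]
  (w^2 - sum(u * u)) * v + 2 * sum(u * v) * u + 2 * w * cross3(u, v)
}

# inverse rotation (Earth -> sensor), vector part of q* (0,v) q
quat_rotate_inv <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  (w^2 - sum(u * u)) * v + 2 * sum(u * v) * u - 2 * w * cross3(u, v)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' Used internally to rotate whole sample series at once; the matrix acts on
#' column vectors the same way \code{\link{quat_rotate}} does.
#'
#' @param q unit quaternion.
#' @return 3x3 orthonormal matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Axis-angle construction of a unit quaternion
#' @param axis length-3 rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("axis must be nonzero")
  u <- axis / n
  quat(cos(angle / 2), u[1] * sin(angle / 2),
       u[2] * sin(angle / 2), u[3] * sin(angle / 2))
}

#' Angular distance between two rotations
#'
#' Smallest rotation angle taking one orientation into the other; insensitive
#' to the sign ambiguity (q vs -q).
#'
#' @param a,b unit quaternions.
#' @return angle in radians in [0, pi].
#' @export
quat_angle <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d))
}

#' Quaternion to Tait-Bryan (roll, pitch, yaw) angles
#'
#' Intrinsic Z-Y-X decomposition: yaw about the Earth z-axis, then pitch
#' about the intermediate y-axis, then roll about the body x-axis.  Output
#' ranges are roll in [-180, 180], pitch in [-90, 90], yaw in [-180, 180]
#' degrees.  At gimbal lock (|pitch| = 90 deg) only the sum/difference of
#' roll and yaw is defined; the convention here reports roll = 0 and folds
#' the full rotation into yaw.
#'
#' @param q unit quaternion.
#' @return named numeric vector \code{c(roll, pitch, yaw)} in degrees.
#' @export
#' @examples
#' quat_to_euler(quat(1, 0, 0, 0))                        # 0 0 0
#' quat_to_euler(quat_from_axis_angle(c(0, 0, 1), pi / 2)) # yaw 90
quat_to_euler <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  sinp <- 2 * (w * y - z * x)
  r2d <- 180 / pi
  if (abs(sinp) >= 1 - 1e-9) {
    # gimbal lock: roll set to 0 by convention, yaw carries the z-rotation
    pitch <- 90 * sign(sinp)
    roll <- 0
    yaw <- 2 * atan2(z, w) * r2d
    yaw <- wrap_angle(yaw)
  } else {
    roll  <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)) * r2d
    pitch <- asin(sinp) * r2d
    yaw   <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)) * r2d
  }
  c(roll = roll, pitch = pitch, yaw = yaw)
}

#' Tait-Bryan angles to quaternion
#'
#' Inverse of \code{\link{quat_to_euler}} (intrinsic Z-Y-X).
#'
#' @param roll,pitch,yaw angles in degrees.
#' @return unit quaternion.
#' @export
euler_to_quat <- function(roll, pitch, yaw) {
  d2r <- pi / 180
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw * d2r)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch * d2r)
  qx <- quat_from_axis_angle(c(1, 0, 0), roll * d2r)
  quat_normalize(quat_multiply(quat_multiply(qz, qy), qx))
}

#' Wrap an angle in degrees into (-180, 180]
#' @param x angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- 180   # map the seam to +180 so the interval is (-180, 180]
  y
}

#' Unit quaternion from a 3x3 rotation matrix
#'
#' Shepperd's method (largest-pivot branch) for numerical robustness.
#'
#' @param R 3x3 rotation matrix.
#' @return unit quaternion with non-negative scalar part.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(diag(R))) {
    w <- sqrt(1 + tr) / 2
    q <- c(w, (R[3, 2] - R[2, 3]) / (4 * w), (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else {
    k <- which.max(diag(R))
    i <- k; j <- i %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(1 + R[i, i] - R[j, j] - R[l, l])
    v <- numeric(3)
    v[i] <- s / 2
    v[j] <- (R[i, j] + R[j, i]) / (2 * s)
    v[l] <- (R[i, l] + R[l, i]) / (2 * s)
    w <- (R[l, j] - R[j, l]) / (2 * s)
    q <- c(w, v)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Convert a quaternion series to Tait-Bryan angles row by row
#' @param qmat n x 4 matrix of unit quaternions (scalar first).
#' @return n x 3 matrix with columns roll, pitch, yaw (degrees).
#' @export
quat_series_to_euler <- function(qmat) {
  out <- t(apply(qmat, 1, quat_to_euler))
  colnames(out) <- c("roll", "pitch", "yaw")
  out
}
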