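#' @useDynLib gazevents, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median predict quantile rnorm runif sd splinefun
#' @importFrom utils head read.csv tail write.csv
NULL

DEG <- 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Azimuth/elevation of a head-centered gaze direction
#'
#' The head (camera) frame has x pointing right, y down and z forward.
#' Azimuth is positive rightward, elevation positive upward; both in degrees.
#'
#' @param v unit 3-vector or n x 3 matrix of gaze directions.
#' @return list with numeric `az` and `el` (degrees).
#' @export
azel_from_dir <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  list(az = atan2(v[, 1], v[, 3]) * DEG,
       el = atan2(-v[, 2], sqrt(v[, 1]^2 + v[, 3]^2)) * DEG)
}

#' Gaze direction from azimuth/elevation
#'
#' Inverse of [azel_from_dir()]; angles in degrees.
#'
#' @param az azimuth (deg, rightward positive).
#' @param el elevation (deg, upward positive).
#' @return n x 3 matrix of unit vectors.
#' @export
dir_from_azel <- function(az, el) {
  az <- az / DEG; el <- el / DEG
  cbind(cos(el) * sin(az), -sin(el), cos(el) * cos(az))
}

wrap360 <- function(a) {
  a <- a %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

wrap180 <- function(a) {
  ((a + 180) %% 360) - 180
}

# Unwrap a sequence of angles in degrees so consecutive jumps are < 180.
unwrap_deg <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  adj <- cumsum(c(0, -360 * round(d / 360)))
  a + adj
}

# Elementary rotations (right-handed, camera frame x right / y down / z fwd).
rot_x <- function(deg) {
  a <- deg / DEG
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg / DEG
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg / DEG
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis by `deg` degrees (Rodrigues).
rot_axis <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg / DEG
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Returns (w, x, y, z) canonicalized to w >= 0.
#'
#' @param R 3 x 3 rotation matrix.
#' @return numeric length-4 unit quaternion.
#' @export
quat_from_rotmat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length-4 quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
rotmat_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Rotation angle of a quaternion in degrees
#'
#' @param q quaternion (w, x, y, z), need not be canonical.
#' @return non-negative angle in degrees.
#' @export
quat_angle_deg <- function(q) {
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * DEG
}

# Angle between two rotation matrices, degrees.
rotmat_angle_deg <- function(Ra, Rb = diag(3)) {
  R <- crossprod(Rb, Ra)
  cosang <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, cosang))) * DEG
}

# Normalize rows of a matrix to unit length.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

stop_gz <- function(class, fmt, ...) {
  stop(structure(class = c(class, "gazevents_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
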