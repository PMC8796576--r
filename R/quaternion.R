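# Quaternion helpers. Convention: Hamilton product, scalar-first (w, x, y, z).
# A quaternion q represents the rotation taking sensor-frame vectors into the
# world frame: v_world = q (0, v_sensor) q*. The world frame is the initial
# gravity-aligned frame (z up); yaw is relative to the starting heading.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) return(quat_identity())
  q / n
}

# Hamilton product q * p
quat_mult <- function(q, p) {
  c(q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

# Exact exponential map: unit quaternion for a rotation of `angle` radians
# about unit `axis`.
quat_from_axis_angle <- function(axis, angle) {
  if (angle == 0) return(quat_identity())
  h <- angle / 2
  c(cos(h), sin(h) * axis)
}

# Rotate a sensor-frame vector into the world frame:
# v' = v + 2 u x (u x v + w v), u = vector part of q.
quat_rotate <- function(q, v) {
  u <- q[2:4]
  t1 <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1]) + q[1] * v
  v + 2 * c(u[2] * t1[3] - u[3] * t1[2],
            u[3] * t1[1] - u[1] * t1[3],
            u[1] * t1[2] - u[2] * t1[1])
}

# Rotation matrix (sensor -> world) from a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3, byrow = TRUE)
}

# ZYX (yaw-pitch-roll) rotation matrix, sensor -> world.
euler_to_matrix <- function(roll, pitch, yaw) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  matrix(c(
    cy * cp, cy * sp * sr - sy * cr, cy * sp * cr + sy * sr,
    sy * cp, sy * sp * sr + cy * cr, sy * sp * cr - cy * sr,
    -sp,     cp * sr,                cp * cr),
    nrow = 3, byrow = TRUE)
}

#' Extract pitch and roll angles from an orientation series
#'
#' Uses the ZYX (yaw-pitch-roll) Euler decomposition of the sensor-to-world
#' rotation. Yaw is deliberately not returned for feature use: without a
#' magnetometer it is unobservable and drifts.
#'
#' @param quat Numeric matrix `n x 4` of unit quaternions (scalar first).
#' @return Matrix `n x 2` with columns `pitch`, `roll`, in degrees.
#' @export
orientation_angles <- function(quat) {
  quat <- rbind(quat)
  w <- quat[, 1]; x <- quat[, 2]; y <- quat[, 3]; z <- quat[, 4]
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x * x + y * y)
  pitch <- asin(pmax(-1, pmin(1, -r31))) * 180 / pi
  roll <- atan2(r32, r33) * 180 / pi
  cbind(pitch = pitch, roll = roll)
}
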