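# Signal pre-processing: bias removal, angular-velocity scaling, and
# magnetometer-free orientation estimation (strap-down quaternion
# integration with accelerometer tilt correction).

#' Estimate sensor biases from an initial static window
#'
#' The protocol starts with quiet sitting, so a short window at the start of
#' the recording is (near-)static. Gyroscope bias is the per-channel mean
#' over that window and is subtracted everywhere. For the accelerometer only
#' the deviation of the static mean from the gravity magnitude is removed:
#' the bias estimate is `mean - 9.81 * mean/||mean||` per sensor, so gravity
#' itself is retained for the orientation filter.
#'
#' @param log A `signal_log`.
#' @param calibration_window Numeric `c(t0, t1)` in seconds, at least 0.5 s
#'   long, inside a static segment.
#' @param gyro_sd_max Guard threshold (rad/s): if any gyro channel's SD in
#'   the window exceeds this, the window caught movement and an error is
#'   raised rather than returning a corrupted bias.
#' @return Object of class `preprocess_params` with `gyro_bias` and
#'   `accel_bias` (named 9-vectors) and the window used.
#' @export
estimate_bias <- function(log, calibration_window = c(0, 2), gyro_sd_max = 0.1) {
  t0 <- calibration_window[1]; t1 <- calibration_window[2]
  if (t1 - t0 < 0.5) stop("calibration window shorter than 0.5 s (unstable mean)")
  sel <- log$t >= t0 & log$t < t1
  if (sum(sel) < 2) stop("calibration window contains too few samples")
  gch <- gyro_channels()
  gsd <- vapply(gch, function(ch) stats::sd(log[[ch]][sel]), numeric(1))
  if (any(gsd > gyro_sd_max)) {
    stop("calibration window is not static (gyro SD ",
         sprintf("%.3f", max(gsd)), " rad/s exceeds ", gyro_sd_max, ")")
  }
  gyro_bias <- vapply(gch, function(ch) mean(log[[ch]][sel]), numeric(1))
  accel_bias <- numeric(0)
  for (s in names(sensor_names())) {
    ach <- paste0(s, "_", c("ax", "ay", "az"))
    m <- vapply(ach, function(ch) mean(log[[ch]][sel]), numeric(1))
    nrm <- sqrt(sum(m^2))
    b <- if (nrm > 0) m - 9.81 * m / nrm else m * 0
    accel_bias <- c(accel_bias, b)
  }
  names(accel_bias) <- accel_channels()
  structure(list(gyro_bias = gyro_bias, accel_bias = accel_bias,
                 calibration_window = calibration_window),
            class = "preprocess_params")
}

#' Subtract estimated biases from a signal log
#'
#' @param log A `signal_log`.
#' @param params A `preprocess_params` from [estimate_bias()].
#' @return The bias-corrected log.
#' @export
apply_bias <- function(log, params) {
  for (ch in names(params$gyro_bias)) log[[ch]] <- log[[ch]] - params$gyro_bias[[ch]]
  for (ch in names(params$accel_bias)) log[[ch]] <- log[[ch]] - params$accel_bias[[ch]]
  log
}

#' Fit per-channel angular-velocity scale factors on training data
#'
#' The scale for each gyro channel is the maximum absolute value observed
#' over the training recordings, so scaled training values lie in [-1, 1].
#' The fitted scale is frozen: at inference the stored divisor is applied
#' and out-of-range values are deliberately not clipped (clipping would
#' destroy onset-magnitude information).
#'
#' @param logs A list of bias-corrected `signal_log`s (or one log).
#' @return Named positive numeric vector over the 9 gyro channels.
#' @export
fit_gyro_scale <- function(logs) {
  if (inherits(logs, "signal_log")) logs <- list(logs)
  if (length(logs) == 0) stop("cannot fit gyro scale on an empty training set")
  sc <- vapply(gyro_channels(), function(ch) {
    max(vapply(logs, function(l) max(abs(l[[ch]])), numeric(1)))
  }, numeric(1))
  zero <- sc == 0
  if (any(zero)) {
    warning("all-zero gyro channel(s) ", paste(names(sc)[zero], collapse = ", "),
            "; scale set to 1")
    sc[zero] <- 1
  }
  sc
}

#' Apply stored angular-velocity scale factors
#'
#' @param log A `signal_log`.
#' @param scale Named vector from [fit_gyro_scale()].
#' @return Log with gyro channels divided by their scale (no clipping).
#' @export
apply_gyro_scale <- function(log, scale) {
  for (ch in gyro_channels()) log[[ch]] <- log[[ch]] / scale[[ch]]
  log
}

# One filter step, shared verbatim by the batch estimator and the streaming
# engine so that both produce bit-identical orientation sequences.
# q: current unit quaternion (sensor -> world); gyro, accel: one sample.
fuse_step <- function(q, gyro, accel, gain, dt) {
  # strap-down prediction: exact axis-angle exponential of the rate increment
  w <- sqrt(sum(gyro * gyro))
  if (w > 0) {
    q <- quat_mult(q, quat_from_axis_angle(gyro / w, w * dt))
  }
  # accelerometer tilt correction: rotate the measured gravity direction into
  # the world frame and pull it a fraction `gain` of the way onto +z
  if (gain > 0) {
    an <- sqrt(sum(accel * accel))
    if (an > 0) {
      gw <- quat_rotate(q, accel / an)
      axis <- c(gw[2], -gw[1], 0)            # gw x e_z (horizontal: tilt only)
      s <- sqrt(sum(axis * axis))
      if (s > 0) {
        ang <- atan2(s, gw[3])
        q <- quat_mult(quat_from_axis_angle(axis / s, gain * ang), q)
      }
    }
  }
  quat_normalize(q)
}

# initial orientation: tilt-align the first accelerometer sample with +z
fuse_init <- function(accel) {
  an <- sqrt(sum(accel * accel))
  if (an == 0) return(quat_identity())
  v <- accel / an
  axis <- c(v[2], -v[1], 0)                  # v x e_z
  s <- sqrt(sum(axis * axis))
  if (s == 0) {
    if (v[3] > 0) return(quat_identity())
    return(c(0, 1, 0, 0))                    # upside down: 180 deg about x
  }
  quat_from_axis_angle(axis / s, atan2(s, v[3]))
}

#' Quaternion orientation estimate for one sensor
#'
#' Complementary filter: each step propagates the quaternion by the exact
#' axis-angle exponential of the gyro increment, then corrects tilt toward
#' the accelerometer's gravity direction by a spherical interpolation with
#' weight `gain`. With `gain = 0` this is pure strap-down integration.
#' Heading (yaw) is pure integration either way: without a magnetometer it
#' is unobservable and drifts; tilt stays bounded under constant gyro bias
#' (steady-state error about `bias / (gain * fs)` radians).
#'
#' @param gyro n x 3 matrix, bias-corrected angular rate in rad/s.
#' @param accel n x 3 matrix, specific force in m/s^2 (unscaled).
#' @param fusion_gain Correction weight per step, in [0, 1]; default 0.02.
#' @param fs Sampling rate, Hz.
#' @param q0 Optional initial quaternion; default aligns tilt with the first
#'   accelerometer sample.
#' @return n x 4 matrix of unit quaternions (scalar first).
#' @export
estimate_orientation <- function(gyro, accel, fusion_gain = 0.02, fs = 100,
                                 q0 = NULL) {
  stopifnot(fusion_gain >= 0, fusion_gain <= 1)
  n <- nrow(gyro)
  out <- matrix(0, n, 4)
  q <- if (is.null(q0)) fuse_init(accel[1, ]) else quat_normalize(q0)
  dt <- 1 / fs
  out[1, ] <- q
  if (n > 1) {
    for (i in 2:n) {
      q <- fuse_step(q, gyro[i, ], accel[i, ], fusion_gain, dt)
      out[i, ] <- q
    }
  }
  out
}

#' Orientation series for all three sensors of a log
#'
#' @param log Bias-corrected `signal_log` (unscaled gyro, rad/s).
#' @param fusion_gain Tilt-correction weight per step.
#' @param fs Sampling rate, Hz.
#' @return Named list (`s1`, `s2`, `s3`) of n x 4 quaternion matrices.
#' @export
fuse_log <- function(log, fusion_gain = 0.02, fs = 100) {
  out <- lapply(names(sensor_names()), function(s) {
    g <- as.matrix(log[paste0(s, "_", c("gx", "gy", "gz"))])
    a <- as.matrix(log[paste0(s, "_", c("ax", "ay", "az"))])
    estimate_orientation(g, a, fusion_gain, fs)
  })
  names(out) <- names(sensor_names())
  out
}
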