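# Synthetic labelled IMU recordings for the chair-rise / walk / U-turn
# protocol. The generator stands in for non-public study recordings: three
# sensors (sternum, both outer thighs), 3-axis accelerometer + gyroscope at
# 100 Hz, with per-participant pace/amplitude variability, gyroscope bias,
# sensor noise and mounting misalignment.

#' Participant profile for the synthetic generator
#'
#' Collects the per-participant parameters that shape a synthetic recording.
#' All randomness in the generated signals flows from `seed`.
#'
#' @param participant_id Identifier string, unique within a cohort.
#' @param stature_scale Dimensionless body-size multiplier (~0.9-1.1); scales
#'   vertical excursions during chair transfers.
#' @param pace_scale Multiplier on all activity durations (> 0). 1 is a
#'   typical unimpaired pace; simulated impairment uses 1.2-2.0 (slower).
#' @param trunk_lean_amplitude Peak forward trunk lean during chair
#'   transfers, degrees.
#' @param thigh_swing_amplitude Peak thigh pitch excursion during gait,
#'   degrees.
#' @param gyro_bias 3 x 3 numeric matrix (sensor x axis) of constant
#'   gyroscope offsets, rad/s. A scalar/vector is recycled.
#' @param accel_noise_sd Accelerometer white-noise SD, m/s^2.
#' @param gyro_noise_sd Gyroscope white-noise SD, rad/s.
#' @param mounting_misalignment 3 x 3 matrix (sensor x roll/pitch/yaw) of
#'   fixed mounting-rotation angles, degrees; each sensor's rotation angle
#'   must stay small (<= 15 degrees per axis).
#' @param impaired Logical flag carried into the cohort manifest.
#' @param crutch_artifacts Logical; when `TRUE`, brief extra sternum-roll
#'   bursts are injected around chair transfers, mimicking handling of
#'   walking aids.
#' @param seed Integer RNG seed for this participant's recording.
#' @return Object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id = "P01",
                                stature_scale = 1,
                                pace_scale = 1,
                                trunk_lean_amplitude = 30,
                                thigh_swing_amplitude = 20,
                                gyro_bias = 0,
                                accel_noise_sd = 0.05,
                                gyro_noise_sd = 0.005,
                                mounting_misalignment = 0,
                                impaired = FALSE,
                                crutch_artifacts = FALSE,
                                seed = 1L) {
  stopifnot(pace_scale > 0, accel_noise_sd >= 0, gyro_noise_sd >= 0,
            stature_scale > 0)
  gb <- matrix(gyro_bias, nrow = 3, ncol = 3)
  mm <- matrix(mounting_misalignment, nrow = 3, ncol = 3)
  if (any(abs(mm) > 15)) {
    stop("mounting_misalignment angles must be <= 15 degrees")
  }
  structure(list(
    participant_id = participant_id,
    stature_scale = stature_scale,
    pace_scale = pace_scale,
    trunk_lean_amplitude = trunk_lean_amplitude,
    thigh_swing_amplitude = thigh_swing_amplitude,
    gyro_bias = gb,
    accel_noise_sd = accel_noise_sd,
    gyro_noise_sd = gyro_noise_sd,
    mounting_misalignment = mm,
    impaired = impaired,
    crutch_artifacts = crutch_artifacts,
    seed = as.integer(seed)
  ), class = "participant_profile")
}

#' Default measurement protocol
#'
#' Encodes the study sequence: quiet sitting, two full chair cycles
#' (stand up, settle, stand, sit down, settle, sit), a third stand-up
#' followed by the walking block (walk, U-turn, walk back, U-turn), quiet
#' standing, and a final sit-down — all repeated twice. Per participant this
#' yields 6 sit-to-stand, 6 stand-to-sit, 4 walking and 4 turning segments
#' and a nominal total of 80 s at pace 1.
#'
#' @param repetitions Number of times the sequence is repeated (default 2).
#' @return Object of class `protocol_script`: a data frame of
#'   `(activity, nominal_duration)` plus a `repetitions` attribute.
#' @export
default_protocol <- function(repetitions = 2) {
  chair <- function() data.frame(
    activity = c("sit_to_stand", "m_standing", "standing",
                 "stand_to_sit", "m_sitting", "sitting"),
    nominal_duration = c(1.5, 0.5, 2.0, 1.5, 0.5, 2.5))
  seg <- rbind(
    data.frame(activity = "sitting", nominal_duration = 2.5),
    chair(), chair(),
    data.frame(activity = c("sit_to_stand", "m_standing", "standing"),
               nominal_duration = c(1.5, 0.5, 2.0)),
    data.frame(activity = c("walking", "turning", "walking", "turning"),
               nominal_duration = c(3.5, 1.5, 3.5, 1.5)),
    data.frame(activity = c("standing", "stand_to_sit", "m_sitting", "sitting"),
               nominal_duration = c(2.0, 1.5, 0.5, 2.5)))
  structure(seg, repetitions = repetitions, class = c("protocol_script", "data.frame"))
}

# --- smooth motion primitives (all analytic: value + first derivative) -----

# minimum-jerk interpolation 0 -> 1 on u in [0, 1]
mj <- function(u) u^3 * (10 - 15 * u + 6 * u^2)
mj_d <- function(u) 30 * u^2 - 60 * u^3 + 30 * u^4
mj_dd <- function(u) 60 * u - 180 * u^2 + 120 * u^3

# smooth ramp a0 -> a1 over [t0, t1]; returns value and rate
prim_ramp <- function(t, t0, t1, a0, a1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  inside <- t >= t0 & t <= t1
  list(v = a0 + (a1 - a0) * mj(u),
       d = ifelse(inside, (a1 - a0) * mj_d(u) / (t1 - t0), 0))
}

# smooth bump 0 -> A -> 0 over [t0, t1] (sin^2 profile)
prim_bump <- function(t, t0, t1, A) {
  u <- (t - t0) / (t1 - t0)
  inside <- t >= t0 & t <= t1
  u <- pmin(pmax(u, 0), 1)
  list(v = ifelse(inside, A * sin(pi * u)^2, 0),
       d = ifelse(inside, A * pi * sin(2 * pi * u) / (t1 - t0), 0))
}

# oscillation with zero value/rate at both segment ends:
# A sin^2(pi t / d) sin(2 pi f t)
prim_wobble <- function(t, d, A, f) {
  e <- sin(pi * t / d)^2
  ed <- pi / d * sin(2 * pi * t / d)
  s <- sin(2 * pi * f * t)
  sd <- 2 * pi * f * cos(2 * pi * f * t)
  list(v = A * e * s, d = A * (ed * s + e * sd))
}

# gait envelope: smooth ramp-in/ramp-out of length r at both ends
prim_envelope <- function(t, d, r) {
  u1 <- pmin(pmax(t / r, 0), 1)
  u2 <- pmin(pmax((d - t) / r, 0), 1)
  e1 <- mj(u1); e2 <- mj(u2)
  d1 <- ifelse(t > 0 & t < r, mj_d(u1) / r, 0)
  d2 <- ifelse(t > d - r & t < d, -mj_d(u2) / r, 0)
  list(v = e1 * e2, d = d1 * e2 + e1 * d2)
}

zero_traj <- function(n) {
  z <- numeric(n)
  data.frame(roll = z, pitch = z, yaw = z,
             droll = z, dpitch = z, dyaw = z,
             lx = z, ly = z, lz = z)
}

deg <- pi / 180

#' Per-sensor orientation trajectories for one activity segment
#'
#' Produces smooth (C1) roll/pitch/yaw trajectories plus their analytic
#' angular rates and world-frame linear accelerations for each of the three
#' sensors, following the kinematic signature of the activity: chair
#' transfers start with a forward trunk lean before the thighs rotate,
#' walking has antiphase thigh-pitch oscillation, turning a sustained yaw
#' rate on all sensors, and the postural classes are (near-)static.
#'
#' @param activity One of `activity_classes()`.
#' @param duration Segment duration in seconds (> 0).
#' @param profile A [participant_profile()].
#' @param fs Sampling rate, Hz.
#' @param yaw0 Entry heading in radians (carried across segments).
#' @param turn_dir +1 or -1, direction of a U-turn.
#' @return List with one data frame per sensor (`sternum`, `thigh_L`,
#'   `thigh_R`), columns `roll, pitch, yaw` (rad), `droll, dpitch, dyaw`
#'   (rad/s) and world-frame linear acceleration `lx, ly, lz` (m/s^2), plus
#'   the exit heading as attribute `yaw_end`.
#' @export
activity_kinematics <- function(activity, duration, profile, fs = 100,
                                yaw0 = 0, turn_dir = 1) {
  stopifnot(duration > 0)
  activity <- match.arg(activity, activity_classes())
  n <- max(2L, round(duration * fs))
  d <- n / fs
  t <- (seq_len(n) - 1) / fs
  lean <- profile$trunk_lean_amplitude * deg
  swing <- profile$thigh_swing_amplitude * deg
  sitp <- 90 * deg
  f_str <- 1 / profile$pace_scale       # stride frequency, Hz
  st <- zero_traj(n); tl <- zero_traj(n); tr <- zero_traj(n)
  yaw_end <- yaw0

  set_pitch <- function(tr_df, p) { tr_df$pitch <- p$v; tr_df$dpitch <- p$d; tr_df }

  if (activity == "sitting" || activity == "m_sitting") {
    tl$pitch <- rep(sitp, n); tr$pitch <- rep(sitp, n)
    if (activity == "m_sitting") {
      w1 <- prim_wobble(t, d, 6 * deg, 2.5)
      w2 <- prim_wobble(t, d, 3 * deg, 2.5)
      st <- set_pitch(st, w1)
      tl$pitch <- tl$pitch + w2$v; tl$dpitch <- w2$d
      tr$pitch <- tr$pitch - w2$v; tr$dpitch <- -w2$d
    }
  } else if (activity == "standing" || activity == "m_standing") {
    if (activity == "m_standing") {
      w1 <- prim_wobble(t, d, 6 * deg, 2.5)
      w2 <- prim_wobble(t, d, 3 * deg, 2.5)
      st <- set_pitch(st, w1)
      tl <- set_pitch(tl, w2)
      tr$pitch <- -w2$v; tr$dpitch <- -w2$d
    }
  } else if (activity == "sit_to_stand" || activity == "stand_to_sit") {
    up <- activity == "sit_to_stand"
    b <- prim_bump(t, 0, 0.8 * d, lean)
    st <- set_pitch(st, b)
    r <- if (up) prim_ramp(t, 0.2 * d, d, sitp, 0) else
      prim_ramp(t, 0.2 * d, d, 0, sitp)
    tl <- set_pitch(tl, r); tr <- set_pitch(tr, r)
    # vertical excursion of the trunk/thighs during the transfer
    u <- pmin(pmax((t - 0.2 * d) / (0.8 * d), 0), 1)
    az <- mj_dd(u) / (0.8 * d)^2 * (if (up) 1 else -1)
    st$lz <- 0.25 * profile$stature_scale * az
    tl$lz <- 0.12 * profile$stature_scale * az
    tr$lz <- tl$lz
    if (isTRUE(profile$crutch_artifacts)) {
      cb <- prim_bump(t, 0, min(0.4, d), 8 * deg)
      st$roll <- st$roll + cb$v; st$droll <- st$droll + cb$d
    }
  } else if (activity == "walking") {
    env <- prim_envelope(t, d, min(0.4, d / 4))
    s <- sin(2 * pi * f_str * t); sd <- 2 * pi * f_str * cos(2 * pi * f_str * t)
    tl$pitch <- swing * env$v * s
    tl$dpitch <- swing * (env$d * s + env$v * sd)
    tr$pitch <- -tl$pitch; tr$dpitch <- -tl$dpitch
    s2 <- sin(4 * pi * f_str * t); s2d <- 4 * pi * f_str * cos(4 * pi * f_str * t)
    st$pitch <- 3 * deg * env$v * s2
    st$dpitch <- 3 * deg * (env$d * s2 + env$v * s2d)
    # vertical bob at twice the stride frequency + fore-aft thigh accelerations
    st$lz <- 0.8 * env$v * s2
    ax <- 1.5 * env$v * cos(2 * pi * f_str * t)
    tl$lx <- ax * cos(yaw0); tl$ly <- ax * sin(yaw0)
    tr$lx <- -tl$lx; tr$ly <- -tl$ly
    tl$lz <- 0.5 * env$v * s2; tr$lz <- tl$lz
  } else if (activity == "turning") {
    yawr <- prim_ramp(t, 0, d, 0, turn_dir * pi)
    for (nm in c("st", "tl", "tr")) {
      tmp <- get(nm)
      tmp$yaw <- yawr$v; tmp$dyaw <- yawr$d
      assign(nm, tmp)
    }
    env <- prim_envelope(t, d, min(0.3, d / 4))
    s <- sin(2 * pi * f_str * t); sd <- 2 * pi * f_str * cos(2 * pi * f_str * t)
    tl$pitch <- 0.5 * swing * env$v * s
    tl$dpitch <- 0.5 * swing * (env$d * s + env$v * sd)
    tr$pitch <- -tl$pitch; tr$dpitch <- -tl$dpitch
    yaw_end <- yaw0 + turn_dir * pi
  }

  for (nm in c("st", "tl", "tr")) {
    tmp <- get(nm)
    tmp$yaw <- tmp$yaw + yaw0
    assign(nm, tmp)
  }
  structure(list(sternum = st, thigh_L = tl, thigh_R = tr),
            yaw_end = yaw_end, n = n)
}

#' Convert an orientation trajectory into IMU channels for one sensor
#'
#' The gyroscope output is the exact body-frame angular rate implied by the
#' Euler-angle trajectory plus the profile's constant bias and white noise;
#' the accelerometer output is the specific force (gravity plus world-frame
#' linear acceleration rotated into the sensor frame) plus white noise. A
#' fixed mounting-misalignment rotation is applied to both. The caller owns
#' the RNG state: results are deterministic given the seed set beforehand.
#'
#' @param traj One sensor's data frame from [activity_kinematics()] (or
#'   several row-bound together).
#' @param profile A [participant_profile()].
#' @param sensor_index 1 (sternum), 2 (left thigh) or 3 (right thigh).
#' @param noise Logical; set `FALSE` for noise- and bias-free output.
#' @return List with matrices `accel` (n x 3, m/s^2) and `gyro` (n x 3, rad/s).
#' @export
kinematics_to_imu <- function(traj, profile, sensor_index = 1, noise = TRUE) {
  n <- nrow(traj)
  cr <- cos(traj$roll); sr <- sin(traj$roll)
  cp <- cos(traj$pitch); sp <- sin(traj$pitch)
  cy <- cos(traj$yaw); sy <- sin(traj$yaw)
  # body rates from ZYX Euler-angle rates
  wx <- traj$droll - traj$dyaw * sp
  wy <- traj$dpitch * cr + traj$dyaw * cp * sr
  wz <- -traj$dpitch * sr + traj$dyaw * cp * cr
  # specific force f = R_ws^T (a_world + g e_z), g up so static reading is +g
  v1 <- traj$lx; v2 <- traj$ly; v3 <- traj$lz + 9.81
  fx <- cy * cp * v1 + sy * cp * v2 - sp * v3
  fy <- (cy * sp * sr - sy * cr) * v1 + (sy * sp * sr + cy * cr) * v2 + cp * sr * v3
  fz <- (cy * sp * cr + sy * sr) * v1 + (sy * sp * cr - cy * sr) * v2 + cp * cr * v3
  gyro <- cbind(wx, wy, wz, deparse.level = 0)
  accel <- cbind(fx, fy, fz, deparse.level = 0)
  mis <- profile$mounting_misalignment[sensor_index, ] * deg
  if (any(mis != 0)) {
    M <- euler_to_matrix(mis[1], mis[2], mis[3])
    gyro <- gyro %*% M          # = t(t(M) %*% t(gyro)) : sensor-frame remap
    accel <- accel %*% M
  }
  if (noise) {
    gyro <- gyro + matrix(profile$gyro_bias[sensor_index, ], n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, 0, profile$gyro_noise_sd), n, 3)
    accel <- accel + matrix(stats::rnorm(3 * n, 0, profile$accel_noise_sd), n, 3)
  }
  list(accel = accel, gyro = gyro)
}

#' Generate one labelled participant recording
#'
#' Realises the protocol script for a participant: per-segment durations are
#' jittered (+/-10%), scaled by the participant's pace, and floored at
#' 200 ms (the shortest activity the classifier must resolve); the activity
#' kinematics are stitched together with heading continuity across U-turns
#' and converted to noisy IMU channels. Bit-identical output for identical
#' profiles (the seed drives every random draw).
#'
#' @param profile A [participant_profile()].
#' @param script A [default_protocol()]-style script.
#' @param fs Sampling rate, Hz.
#' @return List with elements `log` (a `signal_log` data frame: `t` plus 18
#'   channels), `labels` (a `label_track` data frame `t_start,t_end,class`)
#'   and `profile`.
#' @export
generate_participant <- function(profile, script = default_protocol(), fs = 100) {
  reps <- attr(script, "repetitions")
  if (is.null(reps)) reps <- 1
  seg <- do.call(rbind, replicate(reps, as.data.frame(script), simplify = FALSE))
  k <- nrow(seg)
  set.seed(profile$seed)
  jitter <- stats::runif(k, 0.9, 1.1)
  turn_dirs <- sample(c(-1, 1), k, replace = TRUE)
  n_base <- round(jitter * seg$nominal_duration * fs)
  n_seg <- pmax(round(profile$pace_scale * n_base), round(0.2 * fs))

  yaw <- 0
  trajs <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- activity_kinematics(seg$activity[i], n_seg[i] / fs, profile, fs,
                              yaw0 = yaw, turn_dir = turn_dirs[i])
    # realized sample count may round; keep the ledgered one
    n_seg[i] <- attr(tr, "n")
    yaw <- attr(tr, "yaw_end")
    trajs[[i]] <- tr
  }
  full <- lapply(c("sternum", "thigh_L", "thigh_R"), function(s) {
    do.call(rbind, lapply(trajs, `[[`, s))
  })
  names(full) <- c("sternum", "thigh_L", "thigh_R")
  n <- sum(n_seg)

  cols <- vector("list", 3)
  for (s in 1:3) {
    imu <- kinematics_to_imu(full[[s]], profile, s)
    m <- cbind(imu$accel, imu$gyro)
    colnames(m) <- paste0(names(sensor_names())[s], "_",
                          c("ax", "ay", "az", "gx", "gy", "gz"))
    cols[[s]] <- m
  }
  log <- data.frame(t = (seq_len(n) - 1) / fs, cols[[1]], cols[[2]], cols[[3]])
  class(log) <- c("signal_log", "data.frame")
  attr(log, "participant_id") <- profile$participant_id
  attr(log, "fs") <- fs

  bounds <- c(0, cumsum(n_seg)) / fs
  labels <- data.frame(t_start = bounds[-(k + 1)], t_end = bounds[-1],
                       class = seg$activity)
  class(labels) <- c("label_track", "data.frame")
  attr(labels, "participant_id") <- profile$participant_id
  list(log = log, labels = labels, profile = profile)
}

#' Generate a synthetic cohort
#'
#' Draws participant profiles from fixed distributions (controls: pace
#' ~ U(0.9, 1.1); impaired: pace ~ U(1.3, 1.8) with doubled movement noise)
#' and generates one labelled recording each. Controls come first, impaired
#' participants last.
#'
#' @param n_controls Number of unimpaired participants.
#' @param n_impaired Number of participants with simulated impairment
#'   (slow pace, extra noise).
#' @param master_seed Integer; drives profile draws and every per-participant
#'   recording seed.
#' @param script Protocol script (default [default_protocol()]).
#' @param crutch_artifacts Logical, passed to impaired profiles.
#' @return Object of class `imu_cohort`: list of
#'   `list(log, labels, profile)` entries with unique participant ids.
#' @export
generate_cohort <- function(n_controls, n_impaired = 0, master_seed = 1,
                            script = default_protocol(),
                            crutch_artifacts = FALSE) {
  n <- n_controls + n_impaired
  if (n < 1) stop("empty cohort: n_controls + n_impaired must be >= 1")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    imp <- i > n_controls
    prof <- participant_profile(
      participant_id = sprintf("P%02d", i),
      stature_scale = stats::runif(1, 0.92, 1.08),
      pace_scale = if (imp) stats::runif(1, 1.3, 1.8) else stats::runif(1, 0.9, 1.1),
      trunk_lean_amplitude = stats::runif(1, 25, 35),
      thigh_swing_amplitude = stats::runif(1, 15, 25),
      gyro_bias = matrix(stats::rnorm(9, 0, 0.01), 3, 3),
      accel_noise_sd = if (imp) 0.10 else 0.05,
      gyro_noise_sd = if (imp) 0.010 else 0.005,
      mounting_misalignment = matrix(stats::runif(9, -3, 3), 3, 3),
      impaired = imp,
      crutch_artifacts = imp && crutch_artifacts,
      seed = seeds[i])
    out[[i]] <- generate_participant(prof, script)
  }
  structure(out, class = "imu_cohort")
}
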