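# Bias estimation, gyro scaling, and orientation fusion.

test_that("gyro bias is recovered exactly from a noise-free static log", {
  prof <- noiseless_profile()
  prof$gyro_bias <- matrix(c(0.02, -0.01, 0.005), 3, 3, byrow = FALSE)
  p <- generate_participant(prof)
  pp <- estimate_bias(p$log, c(0, 2))
  want <- as.vector(t(prof$gyro_bias))
  names(want) <- gyro_channels()
  expect_equal(pp$gyro_bias, want, tolerance = 1e-12)
  # applying removes it
  logc <- apply_bias(p$log, pp)
  sel <- logc$t < 2
  expect_lt(max(abs(colMeans(as.matrix(logc[sel, gyro_channels()])))), 1e-12)
})

test_that("bias estimate of a noisy zero-bias log is within the standard error", {
  prof <- participant_profile(gyro_bias = 0, gyro_noise_sd = 0.01,
                              accel_noise_sd = 0.05, seed = 5)
  p <- generate_participant(prof)
  pp <- estimate_bias(p$log, c(0, 2))
  n <- sum(p$log$t < 2)
  expect_true(all(abs(pp$gyro_bias) < 4 * 0.01 / sqrt(n)))
})

test_that("bias estimation guards against short or moving windows", {
  p <- generate_participant(noiseless_profile())
  expect_error(estimate_bias(p$log, c(0, 0.3)), "0.5 s")
  # a window over the first chair rise is not static
  t0 <- p$labels$t_start[p$labels$class == "sit_to_stand"][1]
  expect_error(estimate_bias(p$log, c(t0, t0 + 1)), "not static")
})

test_that("accelerometer bias removal keeps gravity", {
  prof <- noiseless_profile()
  p <- generate_participant(prof)
  pp <- estimate_bias(p$log, c(0, 2))
  logc <- apply_bias(p$log, pp)
  sel <- logc$t < 2
  for (s in c("s1", "s2", "s3")) {
    m <- colMeans(as.matrix(logc[sel, paste0(s, "_", c("ax", "ay", "az"))]))
    expect_equal(sqrt(sum(m^2)), 9.81, tolerance = 1e-6)
  }
})

test_that("gyro scaling maps the training maximum to 1 and does not clip", {
  log <- data.frame(t = (0:99) / 100)
  for (ch in gaitonset:::signal_channels()) log[[ch]] <- 0
  log$s1_gx <- seq(-4, 4, length.out = 100)
  class(log) <- c("signal_log", "data.frame")
  expect_warning(sc <- fit_gyro_scale(log), "all-zero")
  expect_identical(unname(sc["s1_gx"]), 4)
  expect_identical(unname(sc["s2_gy"]), 1)   # zero channel fallback
  scaled <- apply_gyro_scale(log, sc)
  expect_equal(max(abs(scaled$s1_gx)), 1)
  # unseen values beyond the training range are not clipped
  log2 <- log; log2$s1_gx <- rep(6, 100)
  expect_equal(apply_gyro_scale(log2, sc)$s1_gx[1], 1.5)
})

test_that("pure strap-down integration recovers a known constant rotation", {
  # 90 deg/s about the sensor y axis for 1 s, gain 0
  fs <- 100
  n <- fs + 1
  gyro <- cbind(0, rep(pi / 2, n), 0)
  accel <- matrix(0, n, 3)
  q <- estimate_orientation(gyro, accel, fusion_gain = 0, fs = fs,
                            q0 = c(1, 0, 0, 0))
  ang <- 2 * acos(pmin(1, abs(q[n, 1]))) * 180 / pi
  expect_lt(abs(ang - 90), 0.01)
  # and the axis is y
  expect_gt(abs(q[n, 3]) / sqrt(sum(q[n, 2:4]^2)), 1 - 1e-9)
})

test_that("identity input keeps the identity quaternion; norms stay unit", {
  n <- 200
  gyro <- matrix(0, n, 3)
  accel <- cbind(0, 0, rep(9.81, n))
  q <- estimate_orientation(gyro, accel, fusion_gain = 0.02)
  expect_equal(q, matrix(rep(c(1, 0, 0, 0), each = n), n, 4))
  # norms stay within 1e-9 even with motion
  set.seed(8)
  gyro2 <- matrix(rnorm(3 * n, 0, 1), n, 3)
  q2 <- estimate_orientation(gyro2, accel, fusion_gain = 0.02)
  expect_lt(max(abs(sqrt(rowSums(q2^2)) - 1)), 1e-9)
})

test_that("tilt error under constant gyro bias stays below the filter bound", {
  # static pose, bias 1 deg/s about y, gain 0.02: steady-state tilt error
  # <= bias / (gain * fs) radians
  fs <- 100; n <- 3000
  bias <- 1 * pi / 180
  gyro <- cbind(0, rep(bias, n), 0)
  accel <- cbind(0, 0, rep(9.81, n))
  gain <- 0.02
  q <- estimate_orientation(gyro, accel, fusion_gain = gain, fs = fs)
  ang <- orientation_angles(q)
  tilt_err <- abs(ang[n, "pitch"]) * pi / 180
  expect_lt(tilt_err, bias / (gain * fs) + 1e-6)
  # while with gain 0 the same bias drifts without bound (linear growth)
  q0 <- estimate_orientation(gyro, accel, fusion_gain = 0, fs = fs)
  drift <- abs(orientation_angles(q0)[n, "pitch"]) * pi / 180
  expect_gt(drift, 10 * tilt_err)
})

test_that("fusion recovers the generator's static postures", {
  p <- generate_participant(noiseless_profile())
  pp <- estimate_bias(p$log, c(0, 2))
  quats <- fuse_log(apply_bias(p$log, pp))
  ang_thigh <- orientation_angles(quats$s2)
  ang_stern <- orientation_angles(quats$s1)
  sel <- p$log$t < 2                      # initial quiet sitting
  expect_lt(max(abs(ang_stern[sel, "pitch"])), 1)
  expect_gt(min(ang_thigh[sel, "pitch"]), 85)
  # late standing segment: thigh back near vertical
  stand <- p$labels[p$labels$class == "standing", ]
  sel2 <- p$log$t >= stand$t_start[2] & p$log$t < stand$t_end[2]
  expect_lt(max(abs(ang_thigh[sel2, "pitch"])), 10)
})
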