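# The synthetic cohort generator: protocol fidelity, kinematic signatures,
# IMU conversion, determinism.

test_that("default protocol yields the study's repetition counts and duration", {
  p <- generate_participant(participant_profile(seed = 3))
  counts <- table(p$labels$class)
  expect_identical(unname(counts["sit_to_stand"]), 6L)
  expect_identical(unname(counts["stand_to_sit"]), 6L)
  expect_identical(unname(counts["walking"]), 4L)
  expect_identical(unname(counts["turning"]), 4L)
  total <- p$labels$t_end[nrow(p$labels)]
  expect_gt(total, 70)
  expect_lt(total, 90)
})

test_that("label track partitions the recording with one class per sample", {
  p <- generate_participant(participant_profile(seed = 9))
  lab <- p$labels
  expect_identical(lab$t_start[1], 0)
  expect_equal(lab$t_start[-1], lab$t_end[-nrow(lab)])
  expect_true(all(lab$t_end > lab$t_start))
  expect_equal(lab$t_end[nrow(lab)], nrow(p$log) / 100)
  cls <- sample_labels(p$log, lab)
  expect_identical(length(cls), nrow(p$log))
  expect_false(anyNA(cls))
  # per-class sample counts equal interval lengths x fs
  want <- round(tapply(lab$t_end - lab$t_start, lab$class, sum) * 100)
  got <- table(cls)[names(want)]
  expect_equal(as.vector(got), as.vector(want))
})

test_that("static postures and turning have the stated kinematic signatures", {
  prof <- noiseless_profile()
  # sitting: thigh pitch 90 deg, sternum level, zero rates
  k <- activity_kinematics("sitting", 5, prof)
  expect_equal(unique(k$thigh_L$pitch), pi / 2)
  expect_equal(unique(k$sternum$pitch), 0)
  expect_true(all(abs(c(k$sternum$dpitch, k$thigh_L$dpitch)) < 1e-12))
  # turning: integrated yaw = 180 deg
  k2 <- activity_kinematics("turning", 2, prof, turn_dir = 1)
  yaw_total <- (k2$sternum$yaw[nrow(k2$sternum)] - k2$sternum$yaw[1]) * 180 / pi
  expect_lt(abs(yaw_total - 180), 5)
  expect_equal(attr(k2, "yaw_end"), pi)
  # walking at 1 Hz stride: thigh pitches are antiphase
  k3 <- activity_kinematics("walking", 4, prof)
  expect_lt(cor(k3$thigh_L$pitch, k3$thigh_R$pitch), 0)
  expect_error(activity_kinematics("jogging", 2, prof), "arg")
})

test_that("sit-to-stand leads with the sternum before the thighs move", {
  k <- activity_kinematics("sit_to_stand", 1.5, noiseless_profile())
  first_stern <- which(abs(k$sternum$dpitch) > 1e-6)[1]
  first_thigh <- which(abs(k$thigh_L$dpitch) > 1e-6)[1]
  expect_lt(first_stern, first_thigh)
})

test_that("IMU conversion reproduces gravity, rates and bias by construction", {
  prof <- noiseless_profile()
  # static posture, zero noise: ||accel|| = 9.81 everywhere, gyro = 0
  k <- activity_kinematics("standing", 2, prof)
  imu <- kinematics_to_imu(k$sternum, prof, 1, noise = FALSE)
  expect_equal(sqrt(rowSums(imu$accel^2)), rep(9.81, nrow(k$sternum)),
               tolerance = 1e-12)
  expect_true(all(imu$gyro == 0))
  # constant pitch rate about y appears exactly on gyro y
  n <- 101
  traj <- data.frame(roll = 0, pitch = seq(0, 1, length.out = n),
                     yaw = 0, droll = 0, dpitch = 1, dyaw = 0,
                     lx = 0, ly = 0, lz = 0)
  imu2 <- kinematics_to_imu(traj, prof, 1, noise = FALSE)
  expect_equal(imu2$gyro[, 2], rep(1, n), tolerance = 1e-12)
  expect_true(all(abs(imu2$gyro[, c(1, 3)]) < 1e-12))
  # injected bias appears as the long-run mean of a static gyro
  prof2 <- noiseless_profile()
  prof2$gyro_bias <- matrix(0.02, 3, 3)
  prof2$gyro_noise_sd <- 0.005
  set.seed(1)
  imu3 <- kinematics_to_imu(activity_kinematics("sitting", 60, prof2)$sternum,
                            prof2, 1, noise = TRUE)
  n3 <- nrow(imu3$gyro)
  expect_lt(max(abs(colMeans(imu3$gyro) - 0.02)), 4 * 0.005 / sqrt(n3))
})

test_that("class signatures separate by a wide margin relative to noise", {
  prof <- participant_profile(seed = 4)
  p <- generate_participant(prof)
  cls <- sample_labels(p$log, p$labels)
  rate_sts <- mean(abs(p$log$s1_gy[cls == "sit_to_stand"]))
  rate_sit <- mean(abs(p$log$s1_gy[cls == "sitting"]))
  expect_gt(rate_sts - rate_sit, 5 * prof$gyro_noise_sd)
})

test_that("pace scaling doubles every interval with the same seed", {
  p1 <- generate_participant(participant_profile(seed = 12, pace_scale = 1))
  p2 <- generate_participant(participant_profile(seed = 12, pace_scale = 2))
  d1 <- p1$labels$t_end - p1$labels$t_start
  d2 <- p2$labels$t_end - p2$labels$t_start
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("cohort generation is seeded, flags impairment, and rejects emptiness", {
  coh <- generate_cohort(3, 2, master_seed = 5)
  expect_length(coh, 5)
  ids <- vapply(coh, function(p) p$profile$participant_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  imp <- vapply(coh, function(p) p$profile$impaired, logical(1))
  expect_identical(sum(imp), 2L)
  expect_true(all(vapply(coh[imp], function(p) p$profile$pace_scale, numeric(1)) > 1.2))
  # determinism: same seed, bit-identical logs
  coh2 <- generate_cohort(3, 2, master_seed = 5)
  expect_identical(coh[[1]]$log, coh2[[1]]$log)
  expect_identical(coh[[5]]$log, coh2[[5]]$log)
  expect_error(generate_cohort(0, 0), "empty cohort")
})

test_that("noise-free acceleration deviates from gravity only during movement", {
  p <- generate_participant(noiseless_profile(seed = 21))
  cls <- sample_labels(p$log, p$labels)
  nrm <- sqrt(p$log$s1_ax^2 + p$log$s1_ay^2 + p$log$s1_az^2)
  static <- cls %in% c("sitting", "standing")
  expect_lt(max(abs(nrm[static] - 9.81)), 1e-9)
  moving <- cls %in% c("sit_to_stand", "walking")
  expect_gt(max(abs(nrm[moving] - 9.81)), 0.1)
})
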