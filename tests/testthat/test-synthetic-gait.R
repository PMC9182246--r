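test_that("generated strides reproduce the configured geometry", {
  cfg <- gait_config(n_strides = 1L, turn_fraction = 0,
                     stride_length_mean = 1.3, jitter_frac = 0, seed = 4)
  p <- generate_foot_pose(cfg)
  expect_equal(p$strides$true_length_m, 1.3, tolerance = 1e-6)
  expect_equal(p$strides$vmin_true_length_m, 1.3, tolerance = 1e-6)
  # same seed twice: bit-identical
  expect_identical(p, generate_foot_pose(cfg))
  # invalid configurations are rejected
  expect_error(gait_config(stride_length_mean = -1), "stride_length_mean")
  expect_error(gait_config(turn_fraction = 1.2), "turn_fraction")
})

test_that("turning strides change the heading by the configured angle", {
  cfg <- gait_config(n_strides = 4L, turn_fraction = 1, turn_angle_deg = 45,
                     jitter_frac = 0, seed = 5)
  p <- generate_foot_pose(cfg)
  for (j in seq_len(nrow(p$strides))) {
    s <- p$strides[j, ]
    dpsi <- quat_yaw(p$quat[s$end, ]) - quat_yaw(p$quat[s$start, ])
    dpsi <- atan2(sin(dpsi), cos(dpsi))
    expect_equal(abs(dpsi), 45 * pi / 180, tolerance = 1e-9)
  }
  expect_true(all(!p$strides$straight))
})

test_that("foot-flat phases have exactly zero velocity and angular velocity", {
  p <- generate_foot_pose(gait_config(n_strides = 3L, seed = 6))
  for (i in seq_len(nrow(p$flat))) {
    k <- p$flat$start[i]:p$flat$end[i]
    expect_identical(max(abs(p$vel[k, ])), 0)
    expect_identical(max(abs(p$omega_world[k, ])), 0)
    expect_identical(max(abs(p$omega_body[k, ])), 0)
  }
})

test_that("mounted-point kinematics follow the rigid-body transport formula", {
  # planar case: constant omega = (0,0,8.5) rad/s, r = (0.1,0,0) m gives a
  # centripetal acceleration of magnitude omega^2 r = 7.225 m/s^2 along -r
  w <- c(0, 0, 8.5)
  r <- c(0.1, 0, 0)
  a_rot <- cross3(w, cross3(w, r))
  expect_equal(a_rot, c(-7.225, 0, 0), tolerance = 1e-12)

  p <- generate_foot_pose(gait_config(n_strides = 2L, turn_fraction = 0.5,
                                      seed = 3))
  # zero lever arm, identity mount: sensor sees the foot-origin kinematics
  kin0 <- ideal_point_kinematics(p, mounting_spec("cavity"))
  f0 <- p$acc
  f0[, 3] <- f0[, 3] + 9.81
  expect_equal(quat_rotate(p$quat, kin0$acc), f0, tolerance = 1e-9)
  expect_equal(kin0$gyr, p$omega_body, tolerance = 1e-12)
  # static: specific-force norm is exactly g, omega zero
  expect_equal(sqrt(sum(kin0$acc[10, ]^2)), 9.81, tolerance = 1e-9)
  expect_equal(unname(kin0$gyr[10, ]), c(0, 0, 0))

  # finite-difference oracle: differentiate the mounted point's world
  # trajectory (4th-order central stencil) and compare with the analytic
  # transport acceleration
  m <- mounting_spec("heel", r = c(-0.06, 0.02, 0.05),
                     rotation = quat_mul(quat_y(0.4), quat_z(0.3)))
  kin <- ideal_point_kinematics(p, m)
  pw <- p$pos + quat_rotate(p$quat, m$r)
  dt <- 1 / p$fs
  n <- nrow(pw)
  i <- 3:(n - 2)
  fd <- (-pw[i - 2, ] + 16 * pw[i - 1, ] - 30 * pw[i, ] + 16 * pw[i + 1, ] -
           pw[i + 2, ]) / (12 * dt^2)
  q_ws <- quat_mul(p$quat, m$rotation)
  a_pt <- quat_rotate(q_ws, kin$acc)
  a_pt[, 3] <- a_pt[, 3] - 9.81
  expect_lt(max(abs(fd - a_pt[i, ])) / max(abs(a_pt)), 1e-4)
})

test_that("attachment dynamics obey the oscillator contracts", {
  p <- generate_foot_pose(gait_config(n_strides = 2L, seed = 8))
  m0 <- mounting_spec("cavity", impact_gain = 0, rollover_coupling = 0)
  kin <- ideal_point_kinematics(p, m0)
  expect_identical(apply_attachment_dynamics(kin, m0, p$impacts)$acc, kin$acc)

  # transient energy decreases monotonically with the damping ratio
  energy_for <- function(zeta) {
    m <- mounting_spec("heel", f_n = 50, zeta = zeta, impact_gain = 1)
    out <- apply_attachment_dynamics(kin, m, p$impacts)
    sum((out$acc - kin$acc)^2)
  }
  expect_gt(energy_for(0.1), energy_for(0.9))

  # the impulse response rings at the damped frequency f_n*sqrt(1-zeta^2)
  kern <- oscillator_kernel(50, 0.2, 2048)
  zc <- which(diff(sign(kern$disp)) != 0)
  period <- 2 * mean(diff(zc)) / 2048
  expect_equal(1 / period, 50 * sqrt(1 - 0.2^2), tolerance = 0.01)
  expect_equal(50 * sqrt(1 - 0.2^2), 48.99, tolerance = 1e-2)

  # closed form: the kernel satisfies the damped-oscillator ODE
  wn <- 2 * pi * 50
  resid <- kern$acc * wn^2 + 2 * 0.2 * wn * kern$vel + wn^2 * kern$disp
  expect_lt(max(abs(resid)) / wn^2, 1e-6)
})

test_that("IMU sampling point-samples, clips and aliases as specified", {
  const <- list(acc = matrix(rep(c(1, 2, 9.81), each = 2048), ncol = 3),
                gyr = matrix(0.1, 2048, 3), fs = 2048)
  s <- sample_imu(const, noise_acc_sd = 0, noise_gyr_sd = 0)
  expect_true(all(s$acc[, 1] == 1 & s$acc[, 3] == 9.81))
  expect_equal(unname(s$gyr[1, 1]), 0.1 * 180 / pi, tolerance = 1e-12)

  # saturation at the gyroscope range
  big <- list(acc = matrix(0, 2048, 3),
              gyr = matrix(c(100, 0, 0), 2048, 3, byrow = TRUE), fs = 2048)
  s_big <- sample_imu(big, noise_acc_sd = 0, noise_gyr_sd = 0)
  expect_true(all(s_big$gyr[, 1] == 2000))

  # 120 Hz component point-sampled at 204.8 Hz aliases to 84.8 Hz
  t_hi <- (0:(2048 * 4 - 1)) / 2048
  tone <- list(acc = cbind(sin(2 * pi * 120 * t_hi), 0, 0),
               gyr = matrix(0, length(t_hi), 3), fs = 2048)
  s_tone <- sample_imu(tone, noise_acc_sd = 0, noise_gyr_sd = 0)
  n <- n_samples(s_tone)
  spec <- Mod(stats::fft(s_tone$acc[, 1]))[1:(n %/% 2)]
  f_peak <- (which.max(spec) - 1) * 204.8 / n
  expect_equal(f_peak, 84.8, tolerance = 0.3)

  # rates that do not divide the internal rate are rejected
  expect_error(sample_imu(const, fs = 150), "integer multiple")
})

test_that("simulated markers move rigidly with the foot", {
  p <- generate_foot_pose(gait_config(n_strides = 2L, turn_fraction = 0,
                                      jitter_frac = 0, seed = 9))
  mk <- simulate_markers(p, gap_rate_per_s = 0)
  # both markers translate by the same planar displacement over a straight
  # stride (rigid translation between identical postures)
  s <- p$strides[1, ]
  for (m in mk) {
    f0 <- round((s$start - 1) / p$fs * m$fs) + 1
    f1 <- round((s$end - 1) / p$fs * m$fs) + 1
    d <- sqrt(sum((m$pos[f1, 1:2] - m$pos[f0, 1:2])^2))
    expect_equal(d, s$true_length_m, tolerance = 1e-3)
  }

  # static pose, zero offset: constant marker position
  p_idx <- 1:50
  expect_equal(max(abs(diff(mk$CAL$pos[p_idx, ]))), 0, tolerance = 1e-12)

  # a 90-degree turn makes heel and toe displacements differ by > 1 cm
  pt <- generate_foot_pose(gait_config(n_strides = 1L, turn_fraction = 1,
                                       turn_angle_deg = 90, jitter_frac = 0,
                                       seed = 10))
  mt <- simulate_markers(pt, gap_rate_per_s = 0)
  st <- pt$strides[1, ]
  d_mk <- vapply(mt, function(m) {
    f0 <- round((st$start - 1) / pt$fs * m$fs) + 1
    f1 <- round((st$end - 1) / pt$fs * m$fs) + 1
    sqrt(sum((m$pos[f1, 1:2] - m$pos[f0, 1:2])^2))
  }, numeric(1))
  expect_gt(abs(d_mk["CAL"] - d_mk["TOE"]), 0.01)
})

test_that("assembled sessions share one rigid motion and are deterministic", {
  proto <- small_protocol(n = 4L, turn_fraction = 0)
  ses <- assemble_session(proto, mounts = rigid_mounting_specs(), seed = 3,
                          feet = "left", attachment = FALSE,
                          noise_acc_sd = 0, noise_gyr_sd = 0,
                          marker_gap_rate_per_s = 0,
                          mocap_offset_jitter_s = 0)
  ref <- ses$sets$left$streams$cavity
  for (s in ses$sets$left$streams) {
    expect_identical(s$acc, ref$acc)
    expect_identical(s$gyr, ref$gyr)
  }
  ses2 <- assemble_session(proto, mounts = rigid_mounting_specs(), seed = 3,
                           feet = "left", attachment = FALSE,
                           noise_acc_sd = 0, noise_gyr_sd = 0,
                           marker_gap_rate_per_s = 0,
                           mocap_offset_jitter_s = 0)
  expect_identical(ses$sets$left$streams$heel$acc,
                   ses2$sets$left$streams$heel$acc)
  expect_true(all(ses$strides$left$speed_category == "normal"))

  dup <- rigid_mounting_specs()
  dup[["medial"]] <- dup[["heel"]]
  expect_error(assemble_session(proto, mounts = dup, seed = 1),
               "distinct positions")
})
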