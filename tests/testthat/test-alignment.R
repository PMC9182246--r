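test_that("the first shared static window is found with first-index semantics", {
  # all-constant signals: the very first window qualifies
  streams <- lapply(SENSOR_POSITIONS, function(p) static_stream(position = p))
  names(streams) <- SENSOR_POSITIONS
  set <- sensor_set(streams)
  expect_equal(unname(find_static_window(set)), c(1, 501))

  # variance above threshold everywhere: structured error
  noisy <- lapply(SENSOR_POSITIONS, function(p) {
    static_stream(position = p, noise = 1, seed = match(p, SENSOR_POSITIONS))
  })
  names(noisy) <- SENSOR_POSITIONS
  expect_error(find_static_window(sensor_set(noisy)), "no static region")
})

test_that("static window matches an exhaustive variance scan", {
  set.seed(20)
  n <- 2000
  make <- function(p) {
    acc <- matrix(rnorm(3 * n, 0, 0.5), ncol = 3)  # motion noise
    acc[1001:n, ] <- matrix(rep(c(0, 0, 9.81), each = n - 1000), ncol = 3) +
      matrix(rnorm(3 * (n - 1000), 0, 0.02), ncol = 3)
    imu_stream(acc, matrix(0, n, 3), fs = 204.8, position = p)
  }
  streams <- lapply(SENSOR_POSITIONS, make)
  names(streams) <- SENSOR_POSITIONS
  set <- sensor_set(streams)
  win <- find_static_window(set, window = 500, var_threshold = 0.01)

  # brute force over every window and sensor
  brute_ok <- rep(TRUE, n - 499)
  for (s in streams) {
    for (j in 1:3) {
      for (i in seq_len(n - 499)) {
        if (stats::var(s$acc[i:(i + 499), j]) * 499 / 500 >= 0.01) {
          brute_ok[i] <- FALSE
        }
      }
    }
  }
  expect_equal(unname(win[1]), which(brute_ok)[1])
})

test_that("gravity alignment maps the median static acceleration onto +z", {
  up <- static_stream(grav = c(0, 0, 9.81))
  ga <- gravity_align(up, c(1, 501))
  expect_equal(ga$rotation, quat_identity(), tolerance = 1e-9)

  side <- static_stream(grav = c(9.81, 0, 0))
  ga2 <- gravity_align(side, c(1, 501))
  med <- apply(ga2$stream$acc[1:500, ], 2, median)
  expect_equal(unname(med), c(0, 0, 9.81), tolerance = 1e-9)

  flipped <- static_stream(grav = c(0, 0, -9.81))
  ga3 <- gravity_align(flipped, c(1, 501))
  med3 <- apply(ga3$stream$acc[1:500, ], 2, median)
  expect_equal(unname(med3), c(0, 0, 9.81), tolerance = 1e-9)

  weightless <- static_stream(grav = c(0, 0, 0.1))
  expect_error(gravity_align(weightless, c(1, 501)), "gravity")
})

test_that("yaw alignment recovers constructed planar rotations", {
  set.seed(21)
  n <- 2000
  gyr_ref <- cbind(rnorm(n, 0, 300), rnorm(n, 0, 300), rnorm(n, 0, 50))
  ref <- imu_stream(matrix(0, n, 3) + 9.81 * rep(c(0, 0, 1), each = n),
                    gyr_ref, fs = 204.8, position = "cavity")
  expect_equal(yaw_align(ref, ref)$delta_phi, 0, tolerance = 1e-12)

  # stream rotated by -30 deg about z needs +30 deg to re-align
  rot <- rotate_stream_z(ref, -30 * pi / 180)
  ya <- yaw_align(rot, ref)
  expect_equal(ya$delta_phi, 30 * pi / 180, tolerance = 1e-6)
  # sign consistency: swapping the arguments flips the angle
  expect_equal(yaw_align(ref, rot)$delta_phi, -30 * pi / 180,
               tolerance = 1e-6)

  quiet <- imu_stream(ref$acc, gyr_ref / 100, fs = 204.8,
                      position = "cavity")
  expect_error(yaw_align(quiet, quiet), "insufficient dynamic content")
})

test_that("yaw median is robust to corrupted samples", {
  set.seed(22)
  n <- 4000
  gyr_ref <- cbind(rnorm(n, 0, 300), rnorm(n, 0, 300), 0)
  acc <- matrix(rep(c(0, 0, 9.81), each = n), ncol = 3)
  ref <- imu_stream(acc, gyr_ref, fs = 204.8, position = "cavity")
  rot <- rotate_stream_z(ref, -25 * pi / 180)
  clean <- yaw_align(rot, ref)$delta_phi

  corrupt <- rot
  bad <- sample(n, n %/% 10)
  corrupt$gyr[bad, ] <- matrix(rnorm(3 * length(bad), 0, 400),
                               ncol = 3)
  dirty <- yaw_align(corrupt, ref)$delta_phi
  expect_lt(abs(dirty - clean) * 180 / pi, 2)
})

test_that("full sensor-set alignment recovers mounting yaws and is idempotent", {
  yaws <- c(insole = 10, cavity = 0, instep = -45, heel = 120,
            lateral = -10, medial = 45)
  mounts <- default_mounting_specs(yaw_deg = yaws)
  ses <- assemble_session(small_protocol(n = 6L, turn_fraction = 0),
                          mounts = mounts, seed = 13, feet = "left",
                          attachment = FALSE, noise_acc_sd = 0,
                          noise_gyr_sd = 0, marker_gap_rate_per_s = 0,
                          mocap_offset_jitter_s = 0)
  al <- align_sensor_set(ses$sets$left)
  # the mounting tilt is removed by the gravity step; the yaw step must
  # recover the z-rotation of the mount relative to the cavity sensor
  for (p in names(yaws)) {
    got <- al$alignment$delta_phi_rad[al$alignment$position == p] * 180 / pi
    expect_lt(abs(got - yaws[[p]]), 1,
              label = sprintf("yaw recovery for %s (got %.2f)", p, got))
  }
  # re-aligning an aligned set yields ~zero yaw corrections
  al2 <- align_sensor_set(al$set)
  expect_lt(max(abs(al2$alignment$delta_phi_rad)) * 180 / pi, 0.5)
})
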