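rand_stream <- function(n = 120, seed = 1, position = "cavity") {
  set.seed(seed)
  imu_stream(matrix(rnorm(3 * n, 0, 5), ncol = 3) +
               rep(c(0, 0, 9.81), each = n),
             matrix(rnorm(3 * n, 0, 100), ncol = 3),
             fs = 204.8, position = position)
}

test_that("pairwise 3D and norm differences follow their definitions", {
  a <- rand_stream(seed = 1)
  b <- rand_stream(seed = 2, position = "heel")
  expect_equal(unname(pairwise_diff_3d(a, a, 1, 121)), c(0, 0))
  expect_equal(unname(pairwise_diff_norm(a, a, 1, 121)), c(0, 0))

  # constant accelerometer offset of (1,0,0): 3D difference exactly 1
  shifted <- a
  shifted$acc[, 1] <- shifted$acc[, 1] + 1
  expect_equal(unname(pairwise_diff_3d(shifted, a, 1, 121)["d3d_acc"]), 1,
               tolerance = 1e-12)

  # doubling the signal: norm difference is minus the mean norm (for the
  # ordering (i, j) = (original, doubled))
  doubled <- a
  doubled$acc <- 2 * a$acc
  doubled$gyr <- 2 * a$gyr
  expect_equal(unname(pairwise_diff_norm(a, doubled, 1, 121)["dnorm_acc"]),
               -mean(sqrt(rowSums(a$acc[1:120, ]^2))), tolerance = 1e-12)

  # symmetry of the 3D difference
  expect_equal(pairwise_diff_3d(a, b, 1, 121), pairwise_diff_3d(b, a, 1, 121))
})

test_that("triangle inequality holds for every random stride pair", {
  for (seed in 1:25) {
    a <- rand_stream(seed = seed)
    b <- rand_stream(seed = seed + 100, position = "heel")
    d3 <- pairwise_diff_3d(a, b, 1, 121)
    dn <- pairwise_diff_norm(a, b, 1, 121)
    expect_gte(d3[["d3d_acc"]], abs(dn[["dnorm_acc"]]))
    expect_gte(d3[["d3d_gyr"]], abs(dn[["dnorm_gyr"]]))
  }
})

test_that("residual energy is the windowed sum of squared gyro norms", {
  n <- 100
  quiet <- imu_stream(matrix(rep(c(0, 0, 9.81), each = n), ncol = 3),
                      matrix(0, n, 3), fs = 204.8, position = "cavity")
  expect_equal(residual_energy(quiet, 50L)$e_vmin, 0)

  # constant gyro norm 1 deg/s over the 8-sample window -> 8 deg^2/s^2
  unit <- quiet
  unit$gyr[, 1] <- 1
  expect_equal(residual_energy(unit, 50L)$e_vmin, 8)

  # homogeneity of degree 2
  doubled <- unit
  doubled$gyr <- 2 * unit$gyr
  expect_equal(residual_energy(doubled, 50L)$e_vmin,
               4 * residual_energy(unit, 50L)$e_vmin)

  # edge truncation is flagged
  expect_true(residual_energy(unit, 2L)$truncated)
})

test_that("peak acceleration picks the maximum norm including spikes", {
  s <- rand_stream(seed = 3)
  k <- 1:120
  expect_equal(peak_acceleration(s, 1, 121),
               max(sqrt(rowSums(s$acc[k, ]^2))))
  still <- static_stream(grav = c(0, 0, 9.81), n = 100)
  expect_equal(peak_acceleration(still, 1, 101), 9.81, tolerance = 1e-12)
  spiked <- still
  spiked$acc[42, ] <- c(0, 0, 50)
  expect_equal(peak_acceleration(spiked, 1, 101), 50)
})

test_that("Welch band powers separate low and high frequency content", {
  fs <- 204.8
  t <- (0:409) / fs  # 2 s
  sine <- cbind(sin(2 * pi * 10 * t), 0, 0)
  bp <- psd_band_power(sine, fs)
  expect_gt(bp[["low"]] / max(bp[["high"]], 1e-300), 100)

  expect_equal(unname(psd_band_power(matrix(0, 410, 3), fs)), c(0, 0))
  expect_true(all(is.na(psd_band_power(matrix(1, 40, 3), fs))))

  # white noise: flat spectrum, band means agree within sampling error
  set.seed(60)
  ratios <- replicate(100, {
    p <- welch_psd(rnorm(410), fs)
    mean(p$psd[p$freq > 0 & p$freq <= 20]) /
      mean(p$psd[p$freq > 80 & p$freq < 102.4])
  })
  expect_lt(abs(mean(ratios) - 1), 0.5)
  expect_true(all(ratios > 1 / 3 & ratios < 3))

  # the norm of a noisy 3D signal has a strong mean: its power concentrates
  # in the excluded DC bin, not in the reported bands
  x3 <- matrix(rnorm(410 * 3), ncol = 3)
  p_norm <- welch_psd(sqrt(rowSums(x3^2)), fs)
  expect_gt(p_norm$psd[1], 10 * mean(p_norm$psd[-(1:3)]))
})

test_that("Welch PSD integrates to the signal power on stationary noise", {
  set.seed(61)
  x <- rnorm(4096, 0, 2)
  p <- welch_psd(x, fs = 204.8)
  df <- p$freq[2] - p$freq[1]
  expect_equal(sum(p$psd) * df, 4, tolerance = 0.15)
})

test_that("cross-sensor STD profile matches closed forms and localizes", {
  ses <- fixture("default8", function() default_session(seed = 8))
  set <- ses$sets$left
  labels <- ses$strides$left

  # identical streams: all-zero profile
  same <- sensor_set(stats::setNames(lapply(SENSOR_POSITIONS, function(p) {
    s <- set$streams$cavity
    s$position <- p
    s
  }), SENSOR_POSITIONS))
  prof0 <- cross_sensor_std_profile(same, labels[1:2, ])
  expect_lt(max(abs(as.matrix(prof0[, -1]))), 1e-12)

  # one sensor offset by +1 m/s^2 on x: constant closed-form profile
  offset <- same
  offset$streams$heel$acc[, 1] <- offset$streams$heel$acc[, 1] + 1
  prof1 <- cross_sensor_std_profile(offset, labels[1:2, ])
  expected_sd <- stats::sd(c(1, 0, 0, 0, 0, 0))
  expect_equal(max(abs(prof1$acc_x - expected_sd)), 0, tolerance = 1e-9)
  expect_lt(max(abs(prof1$acc_y)), 1e-12)

  # real session: disagreement concentrates near the contact events, not in
  # mid-swing (stride phase ~0.3 is mid-swing with the border convention)
  al <- align_sensor_set(set)
  prof <- cross_sensor_std_profile(al$set, labels)
  swing <- prof$acc_z[prof$phase > 0.25 & prof$phase < 0.35]
  contact <- prof$acc_z[prof$phase > 0.45 & prof$phase < 0.60]
  expect_gt(max(contact), max(swing))
})
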