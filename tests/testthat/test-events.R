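test_that("stride borders snap to the window minimum and stay shared", {
  set.seed(30)
  n <- 800
  sig <- sin(2 * pi * (1:n) / 180) * 100
  # true minima of the sine
  mins <- which(diff(sign(diff(sig))) == 2) + 1L
  m1 <- mins[1]; m2 <- mins[2]; m3 <- mins[3]
  labels <- data.frame(stride_id = 1:2,
                       start = c(m1, m2 + 4L),  # one label 4 samples off
                       end = c(m2 + 4L, m3))
  snapped <- snap_stride_borders(sig, labels, fs = 204.8, snap_window_ms = 50)
  # brute-force argmin in the +/- 25 ms window around the offset label
  half <- round(0.025 * 204.8)
  brute <- (m2 + 4L - half:-half)[which.min(sig[(m2 + 4L - half):(m2 + 4L + half)])]
  expect_equal(snapped$start[2], m2)
  expect_equal(snapped$start[2],
               (m2 + 4L - half) + which.min(sig[(m2 + 4L - half):(m2 + 4L + half)]) - 1L)
  # already at a minimum: unchanged; shared border stays shared
  expect_equal(snapped$start[1], m1)
  expect_equal(snapped$end[1], snapped$start[2])
})

test_that("events are detected in order and t_vmin falls in the true foot-flat", {
  ses <- fixture("rigid8", function() rigid_session(seed = 7))
  al <- align_sensor_set(ses$sets$left)
  labels <- snap_stride_borders(ml_gyro(al$set$streams$instep),
                                ses$strides$left, fs = 204.8)
  # reconstruct the true foot-flat intervals (IMU samples) from the
  # generator's phase layout: flat spans [0.64, 1) of each gait cycle, and a
  # labeled stride starts at 0.09 of its cycle
  for (pos in c("cavity", "heel")) {
    ev <- detect_events(al$set$streams[[pos]], labels)
    expect_true(all(ev$valid))
    expect_true(all(labels$start <= ev$tc & ev$tc < ev$ic &
                      ev$ic < ev$tvmin & ev$tvmin < labels$end))
    n_cyc <- labels$end - labels$start
    flat_from <- labels$start + round((0.64 - 0.09) * n_cyc)
    expect_true(all(ev$tvmin >= flat_from - 2))
    # noise-free: gyro energy at t_vmin is ~0
    e <- vapply(ev$tvmin, function(tv) {
      residual_energy(al$set$streams[[pos]], tv)$e_vmin
    }, numeric(1))
    expect_lt(max(e), 1e-12)
  }
})

test_that("t_vmin equals the exhaustive minimal-energy window", {
  ses <- fixture("default8", function() default_session(seed = 8))
  al <- align_sensor_set(ses$sets$left)
  stream <- al$set$streams$heel
  labels <- snap_stride_borders(ml_gyro(al$set$streams$instep),
                                ses$strides$left, fs = 204.8)
  ev <- detect_events(stream, labels)
  i <- which(ev$valid)[1]
  energy <- rowSums(stream$gyr^2)
  cand <- ev$ic[i]:(labels$end[i] - 8L)
  wsum <- vapply(cand, function(s) sum(energy[s:(s + 7L)]), numeric(1))
  expect_equal(ev$tvmin[i], cand[which.min(wsum)] + 4L)
})

test_that("degenerate signals yield invalid events with reasons", {
  n <- 200
  mono <- imu_stream(matrix(rep(c(0, 0, 9.81), each = n), ncol = 3),
                     cbind(0, seq(200, 1, length.out = n), 0),
                     fs = 204.8, position = "cavity")
  labels <- data.frame(stride_id = 1L, start = 1L, end = n + 1L)
  ev <- detect_events(mono, labels)  # ML gyro strictly negative: no crossing
  expect_false(ev$valid)
  expect_equal(ev$reason, "order")
})

test_that("event validation enforces order and the 60% IC rule", {
  labels <- data.frame(stride_id = 1:3, start = c(0L, 100L, 200L),
                       end = c(100L, 200L, 300L))
  ev <- data.frame(stride_id = 1:3,
                   tc = c(10L, 110L, 210L),
                   ic = c(50L, 165L, 250L),   # stride 2: IC at 65%
                   tvmin = c(80L, 180L, 240L),  # stride 3: tvmin < ic
                   valid = TRUE, reason = "none")
  out <- validate_events(ev, labels)
  expect_equal(out$valid, c(TRUE, FALSE, FALSE))
  expect_equal(out$reason, c("none", "no_ic_60", "order"))
})

test_that("v_min strides lose one stride per gait sequence", {
  mk_labels <- function(bounds) {
    data.frame(stride_id = seq_along(bounds[-1]),
               start = bounds[-length(bounds)], end = bounds[-1])
  }
  mk_events <- function(labels, valid = TRUE) {
    data.frame(stride_id = labels$stride_id,
               tc = labels$start + 10L, ic = labels$start + 40L,
               tvmin = labels$start + 70L,
               valid = rep_len(valid, nrow(labels)), reason = "none")
  }
  # 5 adjacent valid strides in one sequence -> 4 v_min strides
  l1 <- mk_labels(seq(1L, by = 100L, length.out = 6))
  expect_equal(nrow(build_vmin_strides(mk_events(l1), l1)), 4)

  # two sequences of 3 and 4 strides -> 2 + 3 = 5
  l2 <- rbind(mk_labels(seq(1L, by = 100L, length.out = 4)),
              mk_labels(seq(1000L, by = 100L, length.out = 5)))
  l2$stride_id <- seq_len(nrow(l2))
  expect_equal(nrow(build_vmin_strides(mk_events(l2), l2)), 5)

  # a single isolated stride -> none
  l3 <- mk_labels(c(1L, 100L))
  expect_equal(nrow(build_vmin_strides(mk_events(l3), l3)), 0)

  # an invalid stride breaks the sequence
  e4 <- mk_events(l1)
  e4$valid[3] <- FALSE
  expect_equal(nrow(build_vmin_strides(e4, l1)), 2)  # pairs (1,2) and (4,5)
})

test_that("v_min borders differ per sensor but stay within the stride pair", {
  ses <- fixture("default8", function() default_session(seed = 8))
  al <- align_sensor_set(ses$sets$left)
  labels <- snap_stride_borders(ml_gyro(al$set$streams$instep),
                                ses$strides$left, fs = 204.8)
  vmins <- lapply(al$set$streams, function(s) {
    build_vmin_strides(detect_events(s, labels), labels)
  })
  ids <- Reduce(intersect, lapply(vmins, function(v) v$stride_id))
  expect_gt(length(ids), 0)
  for (id in ids) {
    k <- match(id, labels$stride_id)
    lo <- labels$start[k]
    hi <- labels$end[min(k + 1L, nrow(labels))]
    for (v in vmins) {
      row <- v[v$stride_id == id, ]
      expect_true(row$start >= lo && row$end <= hi)
    }
  }
})
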