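# Per-stride strapdown double integration: initial orientation from the
# t_vmin window, gyroscope orientation integration, gravity removal,
# forward/backward dedrifted velocity, and the planar stride length.

#' Initial orientation from the t_vmin window
#'
#' Assumes the only acceleration in a short window centred on t_vmin is
#' gravity: the rotation maps the median in-window accelerometer vector onto
#' the world +z axis, and the remaining heading freedom is fixed by rotating
#' the sensor x-axis (projected on the ground plane) onto the forward
#' direction (1, 0, 0).
#'
#' @param stream Aligned [imu_stream()].
#' @param tvmin Centre sample of the window (absolute index).
#' @param window Window width, samples.
#' @return Unit quaternion mapping sensor-frame vectors to the world frame.
#' @export
initial_orientation <- function(stream, tvmin, window = 8L) {
  half <- window %/% 2L
  lo <- max(1L, tvmin - half)
  hi <- min(n_samples(stream), lo + window - 1L)
  med <- apply(stream$acc[lo:hi, , drop = FALSE], 2, stats::median)
  if (sqrt(sum(med^2)) < 1) {
    stop("degenerate t_vmin window (|median acc| < 1 m/s^2)", call. = FALSE)
  }
  q_tilt <- quat_between(med, c(0, 0, 1))
  x_world <- quat_rotate(q_tilt, c(1, 0, 0))
  if (sum(x_world[1:2]^2) < 1e-12) {
    # x-axis vertical after tilt correction: heading is undefined, keep it
    return(q_tilt)
  }
  yaw_corr <- -atan2(x_world[2], x_world[1])
  quat_mul(quat_z(yaw_corr), q_tilt)
}

#' Integrate orientation from the gyroscope
#'
#' Strapdown quaternion integration: one quaternion-exponential step per
#' sample interval using the mean of the two bounding angular-velocity
#' samples, renormalized each step.
#'
#' @param gyr N x 3 angular velocity, deg/s (sensor frame).
#' @param q0 Initial orientation quaternion (sensor to world).
#' @param fs Sampling rate, Hz.
#' @return N x 4 matrix of unit quaternions.
#' @export
integrate_orientation <- function(gyr, q0, fs) {
  n <- nrow(gyr)
  out <- matrix(0, n, 4)
  out[1, ] <- q0 / sqrt(sum(q0^2))
  if (n == 1) return(out)
  rad <- gyr * pi / 180
  rv <- (rad[-n, , drop = FALSE] + rad[-1, , drop = FALSE]) / 2 / fs
  dq <- quat_from_rotvec(rv)
  for (k in seq_len(n - 1L)) {
    q <- quat_mul(out[k, ], dq[k, ])
    out[k + 1L, ] <- q / sqrt(sum(q^2))
  }
  out
}

#' Forward/backward dedrifted velocity
#'
#' Integrates the gravity-free world acceleration forward (v(start) = 0) and
#' backward (v(end) = 0) and blends the two with a logistic weight
#' `w(t) = sigma(c (t - T/2) / T)`, normalized to be exactly 0 at the first
#' and 1 at the last sample so both endpoint velocities are exactly zero.
#'
#' @param acc_world N x 3 world-frame, gravity-removed acceleration, m/s^2.
#' @param fs Sampling rate, Hz.
#' @param steepness Logistic steepness `c`.
#' @return N x 3 velocity, m/s.
#' @export
dedrifted_velocity <- function(acc_world, fs, steepness = 10) {
  n <- nrow(acc_world)
  v_fwd <- cumtrapz_mat(acc_world, 1 / fs)
  v_end <- v_fwd[n, ]
  v_bwd <- sweep(v_fwd, 2, v_end)  # backward integral assuming v(end) = 0
  tt <- (seq_len(n) - 1) / max(n - 1, 1)
  s <- stats::plogis(steepness * (tt - 0.5))
  w <- (s - s[1]) / (s[n] - s[1])
  (1 - w) * v_fwd + w * v_bwd
}

#' IMU stride length of one v_min stride
#'
#' Full double-integration chain over `[start, end)`: initial orientation
#' from the window at the starting t_vmin, gyroscope orientation
#' integration, rotation of the specific force to the world frame and removal
#' of gravity, forward/backward dedrifted velocity, trapezoidal position
#' integration, and finally the planar (x-y) Euclidean distance between the
#' first and last position.
#'
#' @param stream Aligned [imu_stream()].
#' @param start,end v_min stride bounds (absolute samples, half-open).
#' @param config A [pipeline_config()].
#' @return List with `length_m`, and the `trajectory` (list with `quat`,
#'   `acc_world`, `vel`, `pos`) for inspection.
#' @export
stride_trajectory <- function(stream, start, end, config = pipeline_config()) {
  if (start < 1 || end > n_samples(stream) + 1L || start >= end) {
    stop("stride bounds outside the stream", call. = FALSE)
  }
  idx <- start:(end - 1L)
  q0 <- initial_orientation(stream, start, config$init_window_samples)
  quat <- integrate_orientation(stream$gyr[idx, , drop = FALSE], q0, stream$fs)
  acc_world <- quat_rotate(quat, stream$acc[idx, , drop = FALSE])
  acc_world[, 3] <- acc_world[, 3] - config$gravity_mps2
  vel <- dedrifted_velocity(acc_world, stream$fs, config$sigmoid_steepness)
  pos <- cumtrapz_mat(vel, 1 / stream$fs)
  list(
    length_m = sqrt(sum((pos[nrow(pos), 1:2] - pos[1, 1:2])^2)),
    trajectory = list(quat = quat, acc_world = acc_world, vel = vel,
                      pos = pos)
  )
}

#' @rdname stride_trajectory
#' @export
stride_length <- function(stream, start, end, config = pipeline_config()) {
  stride_trajectory(stream, start, end, config)$length_m
}
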