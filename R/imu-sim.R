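# Rigid-body sensor kinematics, attachment dynamics and IMU sampling.

ACC_CLIP_MPS2 <- 157    # +/- 16 g accelerometer range
GYR_CLIP_DPS <- 2000    # gyroscope range

#' Ideal kinematics at a mounted point
#'
#' Computes the exact sensor-frame specific force and angular velocity of a
#' point rigidly mounted on the foot at lever arm `r`. The point acceleration
#' is the rigid-body transport formula
#' `a_p = a_o + alpha x r_w + omega x (omega x r_w)` (centripetal sign; the
#' angular-acceleration Euler term is included because the mounted point's
#' trajectory is only consistent with its acceleration if it is). The
#' accelerometer reads specific force `a_p - g` with `g = (0, 0, -9.81)`, so a
#' resting sensor reports +9.81 m/s^2 on its up axis.
#'
#' @param pose A `pose_series` from [generate_foot_pose()].
#' @param mount A [mounting_spec()].
#' @return List with `acc` (specific force, m/s^2, sensor frame), `gyr`
#'   (rad/s, sensor frame), and `fs`.
#' @export
ideal_point_kinematics <- function(pose, mount) {
  stopifnot(inherits(pose, "pose_series"), inherits(mount, "mounting_spec"))
  r_w <- quat_rotate(pose$quat, mount$r)
  a_point <- pose$acc +
    cross3(pose$alpha_world, r_w) +
    cross3(pose$omega_world, cross3(pose$omega_world, r_w))
  g_vec <- c(0, 0, -GRAVITY_MPS2)
  f_world <- sweep(a_point, 2, g_vec)
  # world -> body -> sensor
  q_ws <- quat_mul(pose$quat, mount$rotation)
  acc_s <- quat_rotate(quat_conj(q_ws), f_world)
  gyr_s <- quat_rotate(quat_conj(mount$rotation), pose$omega_body)
  list(acc = acc_s, gyr = gyr_s, fs = pose$fs)
}

# Damped-oscillator transient kernels. The attachment displacement response
# to an impulse is x(t) = exp(-lambda t) sin(wd t) with lambda = zeta*wn and
# wd = wn*sqrt(1 - zeta^2). The accelerometer sees its second derivative and
# the gyroscope (for the rotational wobble) its first. Built this way the
# transients integrate to exactly zero net displacement and orientation, so
# with ideal sampling the stride length is untouched; errors enter only
# through the finite IMU sampling of the ringing.
oscillator_kernel <- function(f_n, zeta, fs) {
  wn <- 2 * pi * f_n
  lam <- zeta * wn
  wd <- wn * sqrt(max(1 - zeta^2, 1e-12))
  t_max <- -log(1e-4) / lam
  t <- seq(0, t_max, by = 1 / fs)
  env <- exp(-lam * t)
  list(
    t = t,
    disp = env * sin(wd * t),
    vel = env * (wd * cos(wd * t) - lam * sin(wd * t)),
    # normalized so the peak magnitudes are ~1 for small zeta
    acc = env * ((lam^2 - wd^2) * sin(wd * t) - 2 * lam * wd * cos(wd * t)) /
      wn^2,
    gyr = env * (wd * cos(wd * t) - lam * sin(wd * t)) / wd
  )
}

#' Apply attachment dynamics to an ideal sensor series
#'
#' Models the sensor attachment as a damped linear oscillator excited at every
#' initial-contact impact: a decaying sinusoid (natural frequency `f_n`,
#' damping ratio `zeta`) scaled by `impact_gain` and the impact magnitude is
#' added to the acceleration (on the sensor z-axis with a smaller x component)
#' and, scaled by `gyro_coupling`, to the gyroscope. A `rollover_coupling`
#' fraction of the signal is replaced by a copy delayed by `rollover_delay_s`,
#' emulating the delayed movement onset of sensors coupled to the deforming
#' toe box. With `impact_gain = 0` and `rollover_coupling = 0` the series is
#' returned unchanged.
#'
#' @param kin List with `acc`, `gyr` (sensor frame, rad/s), `fs`, as returned
#'   by [ideal_point_kinematics()].
#' @param mount A [mounting_spec()].
#' @param impacts Data frame with columns `sample` (index at `kin$fs`) and
#'   `magnitude` (m/s^2), as produced by [generate_foot_pose()].
#' @param gyro_coupling Gyro transient amplitude per unit acceleration
#'   transient amplitude, (rad/s)/(m/s^2).
#' @param rollover_delay_s Delay of the rollover-coupled component, seconds.
#' @return The modulated `kin` list.
#' @export
apply_attachment_dynamics <- function(kin, mount, impacts,
                                      gyro_coupling = 0.035,
                                      rollover_delay_s = 0.025) {
  stopifnot(inherits(mount, "mounting_spec"))
  acc <- kin$acc
  gyr <- kin$gyr
  n <- nrow(acc)
  if (mount$rollover_coupling > 0) {
    lag <- as.integer(round(rollover_delay_s * kin$fs))
    rc <- mount$rollover_coupling
    delay <- function(x) {
      if (lag == 0) return(x)
      rbind(x[rep(1L, lag), , drop = FALSE], x[seq_len(n - lag), , drop = FALSE])
    }
    acc <- (1 - rc) * acc + rc * delay(acc)
    gyr <- (1 - rc) * gyr + rc * delay(gyr)
  }
  if (mount$impact_gain > 0 && nrow(impacts) > 0) {
    kern <- oscillator_kernel(mount$f_n, mount$zeta, kin$fs)
    nk <- length(kern$t)
    add_acc <- numeric(n)
    add_gyr <- numeric(n)
    for (i in seq_len(nrow(impacts))) {
      s0 <- impacts$sample[i]
      if (s0 < 1 || s0 > n) next
      idx <- s0:min(n, s0 + nk - 1L)
      amp <- impacts$magnitude[i] * mount$impact_gain
      add_acc[idx] <- add_acc[idx] + amp * kern$acc[seq_along(idx)]
      add_gyr[idx] <- add_gyr[idx] + amp * gyro_coupling *
        kern$gyr[seq_along(idx)]
    }
    acc[, 3] <- acc[, 3] + add_acc
    acc[, 1] <- acc[, 1] + 0.3 * add_acc
    gyr[, 2] <- gyr[, 2] + add_gyr
    gyr[, 1] <- gyr[, 1] + 0.3 * add_gyr
  }
  list(acc = acc, gyr = gyr, fs = kin$fs)
}

#' Sample an IMU stream from a high-rate sensor series
#'
#' Point-samples (no anti-alias filter, matching the behaviour of a real IMU
#' front end reading an under-damped mechanical input) the internal-rate
#' series at `fs`, adds white measurement noise, converts the gyroscope to
#' deg/s and clips to the sensor ranges (+/-157 m/s^2, +/-2000 deg/s).
#'
#' @param kin List with `acc` (m/s^2), `gyr` (rad/s) and `fs` at the internal
#'   rate, which must be an integer multiple of `fs`.
#' @param fs Output sampling rate, Hz (default 204.8).
#' @param noise_acc_sd,noise_gyr_sd White noise standard deviations, m/s^2 and
#'   deg/s.
#' @param seed Optional integer seed for the noise.
#' @param position,foot Metadata for the resulting stream.
#' @return An [imu_stream()].
#' @export
sample_imu <- function(kin, fs = 204.8,
                       noise_acc_sd = 0.02, noise_gyr_sd = 0.05,
                       seed = NULL, position = "cavity", foot = "left") {
  ratio <- kin$fs / fs
  if (fs > kin$fs || abs(ratio - round(ratio)) > 1e-9) {
    stop("internal rate must be an integer multiple of fs", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  idx <- seq(1L, nrow(kin$acc), by = ratio)
  acc <- kin$acc[idx, , drop = FALSE]
  gyr_dps <- kin$gyr[idx, , drop = FALSE] * 180 / pi
  with_seed(seed, {
    if (noise_acc_sd > 0) {
      acc <- acc + matrix(stats::rnorm(length(acc), 0, noise_acc_sd),
                          ncol = 3)
    }
    if (noise_gyr_sd > 0) {
      gyr_dps <- gyr_dps + matrix(stats::rnorm(length(gyr_dps), 0,
                                               noise_gyr_sd), ncol = 3)
    }
    acc <- pmin(pmax(acc, -ACC_CLIP_MPS2), ACC_CLIP_MPS2)
    gyr_dps <- pmin(pmax(gyr_dps, -GYR_CLIP_DPS), GYR_CLIP_DPS)
    imu_stream(acc, gyr_dps, fs = fs, position = position, foot = foot)
  })
}
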