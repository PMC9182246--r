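# Two-step sensor-to-sensor orientation alignment: gravity (tilt) from a
# shared static standing window, then yaw from the planar angular-velocity
# phase difference with the cavity reference sensor.

#' Find the first static window shared by all sensors of a foot
#'
#' Slides a window of `window` samples (step 1) over the accelerometer signals
#' of every stream in the set and returns the first window in which the
#' per-axis variance is below `var_threshold` on all three axes of all
#' sensors simultaneously.
#'
#' @param set A [sensor_set()].
#' @param window Window length, samples.
#' @param var_threshold Per-axis variance threshold, (m/s^2)^2.
#' @return Integer vector `c(start, end)`: a half-open interval
#'   `[start, end)` of length `window` (1-based samples).
#' @export
find_static_window <- function(set, window = 500L, var_threshold = 0.01) {
  stopifnot(inherits(set, "sensor_set"))
  window <- as.integer(window)
  if (set$n < window) stop("signal shorter than the static window", call. = FALSE)
  ok <- rep(TRUE, set$n - window + 1L)
  for (s in set$streams) {
    for (j in 1:3) {
      v <- rolling_var(s$acc[, j], window)
      ok <- ok & (v < var_threshold)
    }
  }
  idx <- which(ok)
  if (!length(idx)) stop("no static region", call. = FALSE)
  c(start = idx[1], end = idx[1] + window)
}

# Rolling variance (denominator n) over windows of length w via cumulative
# sums; returns length N - w + 1.
rolling_var <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  n <- length(x)
  i <- seq_len(n - w + 1L)
  s1 <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  pmax(s2 / w - (s1 / w)^2, 0)
}

#' Gravity-align one stream
#'
#' Rotates the stream by the shortest rotation taking the median accelerometer
#' vector of the static window onto the local +z axis, so that the sensor
#' z-axis points up (against gravity) while standing.
#'
#' @param stream An [imu_stream()].
#' @param window `c(start, end)` half-open static window as returned by
#'   [find_static_window()].
#' @return List with the rotated `stream` and the `rotation` quaternion.
#' @export
gravity_align <- function(stream, window) {
  idx <- window[1]:(window[2] - 1L)
  if (window[1] < 1 || window[2] - 1L > n_samples(stream)) {
    stop("static window outside the stream", call. = FALSE)
  }
  med <- apply(stream$acc[idx, , drop = FALSE], 2, stats::median)
  if (sqrt(sum(med^2)) < 1) {
    stop("no usable gravity vector (|median acc| < 1 m/s^2)", call. = FALSE)
  }
  q <- quat_between(med, c(0, 0, 1))
  out <- stream
  out$acc <- quat_rotate(q, stream$acc)
  out$gyr <- quat_rotate(q, stream$gyr)
  list(stream = out, rotation = q)
}

#' Yaw-align a gravity-aligned stream to a reference stream
#'
#' For every sample where the planar angular-velocity magnitude of *both*
#' streams reaches `omega_threshold`, computes the signed angle from the
#' stream's planar angular velocity to the reference's
#' (`atan2(cross, dot)` with the signed 2D cross product) and returns the
#' median. Rotating the stream by the result about z aligns it with the
#' reference.
#'
#' @param stream,ref Gravity-aligned [imu_stream()]s of equal length.
#' @param omega_threshold Minimum planar |omega| (deg/s) for a sample to be
#'   used.
#' @return List with `delta_phi` (rad) and `n_used`.
#' @export
yaw_align <- function(stream, ref, omega_threshold = 150) {
  if (n_samples(stream) != n_samples(ref)) {
    stop("streams must have equal length", call. = FALSE)
  }
  gi <- stream$gyr[, 1:2, drop = FALSE]
  gj <- ref$gyr[, 1:2, drop = FALSE]
  ni <- sqrt(rowSums(gi^2))
  nj <- sqrt(rowSums(gj^2))
  keep <- ni >= omega_threshold & nj >= omega_threshold
  if (!any(keep)) stop("insufficient dynamic content", call. = FALSE)
  cross <- gi[keep, 1] * gj[keep, 2] - gi[keep, 2] * gj[keep, 1]
  dot <- gi[keep, 1] * gj[keep, 1] + gi[keep, 2] * gj[keep, 2]
  ang <- atan2(cross, dot)
  list(delta_phi = stats::median(ang), n_used = sum(keep))
}

rotate_stream_z <- function(stream, angle) {
  q <- quat_z(angle)
  stream$acc <- quat_rotate(q, stream$acc)
  stream$gyr <- quat_rotate(q, stream$gyr)
  stream
}

#' Align all sensors of one foot to the cavity sensor
#'
#' Two-step alignment of every stream in the set: the tilt is removed with
#' [gravity_align()] (shared static window), then every non-cavity stream is
#' rotated about z by the [yaw_align()] angle with the cavity reference. The
#' cavity stream itself is only gravity-aligned. Pass `slice` to restrict the
#' alignment estimation (static search and yaw median) to one gait test while
#' still rotating the full streams.
#'
#' @param set A [sensor_set()].
#' @param config A [pipeline_config()] (window length, thresholds).
#' @param slice Optional `c(start, end)` half-open sample range used for
#'   estimating the alignment.
#' @return List with `set` (aligned [sensor_set()]) and `alignment`, a data
#'   frame per sensor: gravity rotation quaternion columns, `delta_phi_rad`,
#'   static window bounds, `n_samples_used`.
#' @export
align_sensor_set <- function(set, config = pipeline_config(), slice = NULL) {
  stopifnot(inherits(set, "sensor_set"))
  est_set <- set
  offset <- 0L
  if (!is.null(slice)) {
    idx <- slice[1]:(slice[2] - 1L)
    est_set$streams <- lapply(set$streams, function(s) {
      s$acc <- s$acc[idx, , drop = FALSE]
      s$gyr <- s$gyr[idx, , drop = FALSE]
      s
    })
    est_set$n <- length(idx)
    offset <- slice[1] - 1L
  }
  win <- find_static_window(est_set, config$static_window_samples,
                            config$static_var_threshold)

  grav <- lapply(names(set$streams), function(p) {
    ga_est <- gravity_align(est_set$streams[[p]], win)
    full <- set$streams[[p]]
    full$acc <- quat_rotate(ga_est$rotation, full$acc)
    full$gyr <- quat_rotate(ga_est$rotation, full$gyr)
    list(stream = full, est = {
      e <- est_set$streams[[p]]
      e$acc <- quat_rotate(ga_est$rotation, e$acc)
      e$gyr <- quat_rotate(ga_est$rotation, e$gyr)
      e
    }, rotation = ga_est$rotation)
  })
  names(grav) <- names(set$streams)

  cavity_est <- grav[["cavity"]]$est
  aligned <- list()
  rows <- list()
  for (p in names(set$streams)) {
    if (p == "cavity") {
      dphi <- 0
      n_used <- NA_integer_
      aligned[[p]] <- grav[[p]]$stream
    } else {
      ya <- yaw_align(grav[[p]]$est, cavity_est,
                      config$yaw_omega_threshold_dps)
      dphi <- ya$delta_phi
      n_used <- ya$n_used
      aligned[[p]] <- rotate_stream_z(grav[[p]]$stream, dphi)
    }
    q <- grav[[p]]$rotation
    rows[[p]] <- data.frame(
      position = p, foot = set$foot,
      grav_qw = q[1], grav_qx = q[2], grav_qy = q[3], grav_qz = q[4],
      delta_phi_rad = dphi,
      static_start = unname(win[1]) + offset,
      static_end = unname(win[2]) + offset,
      n_samples_used = n_used,
      stringsAsFactors = FALSE
    )
  }
  list(set = sensor_set(aligned, foot = set$foot),
       alignment = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
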