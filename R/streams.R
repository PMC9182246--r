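# In-memory containers shared by the simulator, the I/O layer and the
# analysis modules.

#' IMU stream container
#'
#' One sensor's synchronized accelerometer and gyroscope recording with its
#' mounting metadata. Units are fixed package-wide: acceleration in m/s^2,
#' angular velocity in deg/s.
#'
#' @param acc N x 3 numeric matrix of specific force, m/s^2.
#' @param gyr N x 3 numeric matrix of angular velocity, deg/s.
#' @param fs Sampling rate, Hz.
#' @param position Sensor position label (one of insole, cavity, instep, heel,
#'   lateral, medial).
#' @param foot `"left"` or `"right"`.
#' @return A list of class `imu_stream`.
#' @export
imu_stream <- function(acc, gyr, fs, position, foot = "left") {
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  if (nrow(acc) != nrow(gyr)) {
    stop("acc and gyr must have the same number of samples", call. = FALSE)
  }
  if (ncol(acc) != 3 || ncol(gyr) != 3) {
    stop("acc and gyr must have 3 columns", call. = FALSE)
  }
  if (!all(is.finite(acc)) || !all(is.finite(gyr))) {
    stop("imu_stream values must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  position <- match.arg(position, SENSOR_POSITIONS)
  foot <- match.arg(foot, c("left", "right"))
  dimnames(acc) <- list(NULL, c("x", "y", "z"))
  dimnames(gyr) <- list(NULL, c("x", "y", "z"))
  structure(list(acc = acc, gyr = gyr, fs = fs,
                 position = position, foot = foot),
            class = "imu_stream")
}

n_samples <- function(stream) nrow(stream$acc)

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %s/%s: %d samples @ %g Hz\n",
              x$foot, x$position, n_samples(x), x$fs))
  invisible(x)
}

#' Sensor set: the six synchronized streams of one foot
#'
#' @param streams Named list of [imu_stream()] objects, exactly one per
#'   position, all sharing sampling rate and length.
#' @param foot `"left"` or `"right"`.
#' @return A list of class `sensor_set`.
#' @export
sensor_set <- function(streams, foot = "left") {
  missing <- setdiff(SENSOR_POSITIONS, names(streams))
  if (length(missing)) {
    stop("missing sensor position(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(streams), SENSOR_POSITIONS)
  if (length(extra)) {
    stop("unknown sensor position(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  streams <- streams[SENSOR_POSITIONS]
  ns <- vapply(streams, n_samples, integer(1))
  fss <- vapply(streams, function(s) s$fs, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("all streams of a sensor_set must share the sample count",
         call. = FALSE)
  }
  if (length(unique(fss)) != 1) {
    stop("all streams of a sensor_set must share the sampling rate",
         call. = FALSE)
  }
  structure(list(foot = foot, streams = streams,
                 fs = fss[[1]], n = ns[[1]]),
            class = "sensor_set")
}

#' @export
print.sensor_set <- function(x, ...) {
  cat(sprintf("<sensor_set> %s foot: %d streams, %d samples @ %g Hz\n",
              x$foot, length(x$streams), x$n, x$fs))
  invisible(x)
}

#' Marker stream container
#'
#' Optical marker trajectory at the motion-capture rate with a gap mask.
#'
#' @param pos N x 3 matrix of world positions, metres. Rows flagged as gaps
#'   may be `NA`.
#' @param gap Logical vector marking missing (untracked) frames.
#' @param label Marker label, `"CAL"` (calcaneus/heel) or `"TOE"`.
#' @param fs Sampling rate, Hz (100 for the emulated capture system).
#' @return A list of class `marker_stream`.
#' @export
marker_stream <- function(pos, gap = NULL, label = c("CAL", "TOE"), fs = 100) {
  label <- match.arg(label)
  pos <- as.matrix(pos)
  if (is.null(gap)) gap <- rep(FALSE, nrow(pos))
  if (length(gap) != nrow(pos)) {
    stop("gap mask length must equal the number of frames", call. = FALSE)
  }
  if (!all(is.finite(pos[!gap, ]))) {
    stop("non-gap marker positions must be finite", call. = FALSE)
  }
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(list(label = label, fs = fs, pos = pos, gap = as.logical(gap)),
            class = "marker_stream")
}

#' @export
print.marker_stream <- function(x, ...) {
  cat(sprintf("<marker_stream> %s: %d frames @ %g Hz (%d gap frames)\n",
              x$label, nrow(x$pos), x$fs, sum(x$gap)))
  invisible(x)
}
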