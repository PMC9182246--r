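# Marker-based reference stride lengths, gap handling, and the cross-sensor
# stride selection rules.

#' Interpolate short marker gaps
#'
#' Linearly interpolates tracking gaps up to `max_gap_ms`; longer gaps stay
#' missing (and flagged in the gap mask).
#'
#' @param marker A [marker_stream()].
#' @param max_gap_ms Longest gap to fill, ms.
#' @return The marker stream with filled positions and updated gap mask.
#' @export
fill_marker_gaps <- function(marker, max_gap_ms = 80) {
  stopifnot(inherits(marker, "marker_stream"))
  max_gap <- as.integer(floor(max_gap_ms / 1000 * marker$fs))
  pos <- marker$pos
  pos[marker$gap, ] <- NA_real_
  filled <- apply(pos, 2, function(x) {
    zoo::na.approx(x, maxgap = max_gap, na.rm = FALSE)
  })
  marker$pos <- filled
  marker$gap <- !stats::complete.cases(filled)
  marker
}

# Marker position at arbitrary IMU-clock instants (linear interpolation on
# the capture grid). Returns NA rows where a query falls in / next to an
# unfilled gap.
marker_at_time <- function(marker, t_imu, mocap_offset_s = 0) {
  t_frames <- (seq_len(nrow(marker$pos)) - 1) / marker$fs + mocap_offset_s
  out <- vapply(1:3, function(j) {
    stats::approx(t_frames, marker$pos[, j], xout = t_imu, rule = 1)$y
  }, numeric(length(t_imu)))
  if (!is.matrix(out)) out <- matrix(out, ncol = 3)
  out
}

#' Marker-based reference stride length
#'
#' Planar (ground-plane) Euclidean distance the marker travels between the
#' v_min-stride start and end instants. Bounds are IMU samples; the marker
#' position at each bound is linearly interpolated on the capture grid using
#' the session clock offset. Returns `NA` if either bound falls into an
#' unfilled gap.
#'
#' @param marker A (gap-filled) [marker_stream()].
#' @param start,end v_min stride bounds in IMU samples.
#' @param fs_imu IMU sampling rate, Hz.
#' @param mocap_offset_s Capture-clock offset (marker frame 1 corresponds to
#'   IMU time `mocap_offset_s`).
#' @return Length in metres, or `NA_real_` if marker data is unusable at a
#'   bound.
#' @export
reference_stride_length <- function(marker, start, end, fs_imu = 204.8,
                                    mocap_offset_s = 0) {
  t_bounds <- (c(start, end) - 1) / fs_imu
  p <- marker_at_time(marker, t_bounds, mocap_offset_s)
  if (anyNA(p)) return(NA_real_)
  sqrt(sum((p[2, 1:2] - p[1, 1:2])^2))
}

#' Cross-sensor stride selection
#'
#' A stride id is kept only if, for *every* sensor of the foot: the events
#' are valid, the heel and toe reference lengths agree within
#' `straightness_threshold_m` (straight-stride criterion), and the marker
#' data at the stride bounds is usable. Violation by any one sensor removes
#' the stride for all sensors.
#'
#' @param ref_table Data frame with one row per stride x sensor:
#'   `stride_id`, `position`, `heel_length_m`, `toe_length_m` (either may be
#'   `NA` when markers are unusable). Strides whose events failed for a
#'   sensor have no row for that sensor and are excluded with reason
#'   `"events"`.
#' @param straightness_threshold_m Maximum |heel - toe| difference, metres.
#' @param required_positions Sensor positions every kept stride must cover.
#' @return List with `kept` (integer stride ids) and `exclusions` (data
#'   frame `stride_id`, `position`, `reason`).
#' @export
select_strides <- function(ref_table, straightness_threshold_m = 0.01,
                           required_positions = SENSOR_POSITIONS) {
  bad_marker <- is.na(ref_table$heel_length_m) | is.na(ref_table$toe_length_m)
  not_straight <- !bad_marker &
    abs(ref_table$heel_length_m - ref_table$toe_length_m) >
      straightness_threshold_m
  reason <- ifelse(bad_marker, "marker_gap",
                   ifelse(not_straight, "not_straight", "ok"))
  exclusions <- data.frame(
    stride_id = ref_table$stride_id,
    position = ref_table$position,
    reason = reason,
    stringsAsFactors = FALSE
  )[reason != "ok", ]
  covered <- tapply(ref_table$position, ref_table$stride_id,
                    function(p) all(required_positions %in% p))
  incomplete <- as.integer(names(covered))[!covered]
  if (length(incomplete)) {
    exclusions <- rbind(exclusions, data.frame(
      stride_id = incomplete, position = NA_character_, reason = "events"
    ))
  }
  bad_ids <- unique(exclusions$stride_id)
  all_ids <- unique(ref_table$stride_id)
  list(kept = sort(setdiff(all_ids, bad_ids)),
       exclusions = exclusions)
}
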