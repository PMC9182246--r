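# Optical marker simulation: world trajectories of shoe-fixed points sampled
# at the motion-capture rate, with tracking gaps.

DEFAULT_MARKER_OFFSETS <- list(
  CAL = c(-0.08, 0.00, 0.05),  # calcaneus (heel) marker, foot frame
  TOE = c(0.17, 0.00, 0.03)    # tip of the shoe
)

#' Simulate motion-capture marker streams from a pose series
#'
#' Rigidly attaches each marker at a foot-frame offset, evaluates its world
#' trajectory and samples it at the capture rate (linear interpolation of the
#' high-rate pose). Tracking gaps are inserted as a Poisson process of gap
#' starts with geometrically distributed gap lengths, so runs both below and
#' above the interpolation limit occur.
#'
#' @param pose A `pose_series`.
#' @param offsets Named list of foot-frame marker offsets (metres); defaults
#'   to a heel (`CAL`) and a shoe-tip (`TOE`) marker.
#' @param fs Capture rate, Hz.
#' @param time_offset_s Capture clock offset: marker frame `f` is taken at
#'   IMU-clock time `(f - 1) / fs + time_offset_s`.
#' @param gap_rate_per_s Expected number of gap starts per second (0 disables
#'   gaps).
#' @param gap_mean_ms Mean gap length, ms (geometric in frames).
#' @param seed Optional seed for the gap process.
#' @return Named list of [marker_stream()] objects.
#' @export
simulate_markers <- function(pose, offsets = DEFAULT_MARKER_OFFSETS,
                             fs = 100, time_offset_s = 0,
                             gap_rate_per_s = 0, gap_mean_ms = 50,
                             seed = NULL) {
  stopifnot(inherits(pose, "pose_series"))
  t_end <- (pose$n - 1) / pose$fs
  t_frames <- seq(0, by = 1 / fs, length.out = floor((t_end - max(time_offset_s, 0)) * fs) + 1L)
  t_query <- t_frames + time_offset_s
  t_query <- pmin(pmax(t_query, 0), t_end)
  t_high <- (seq_len(pose$n) - 1) / pose$fs

  with_seed(seed, {
    out <- lapply(names(offsets), function(lab) {
      world <- pose$pos + quat_rotate(pose$quat, offsets[[lab]])
      sampled <- vapply(1:3, function(j) {
        stats::approx(t_high, world[, j], xout = t_query)$y
      }, numeric(length(t_query)))
      gap <- rep(FALSE, length(t_query))
      if (gap_rate_per_s > 0) {
        n_gaps <- stats::rpois(1, gap_rate_per_s * t_end)
        if (n_gaps > 0) {
          starts <- sample.int(length(t_query), n_gaps)
          lens <- 1L + stats::rgeom(n_gaps, prob = 1000 / (gap_mean_ms * fs))
          for (i in seq_len(n_gaps)) {
            gap[starts[i]:min(length(gap), starts[i] + lens[i] - 1L)] <- TRUE
          }
        }
      }
      sampled[gap, ] <- NA_real_
      marker_stream(sampled, gap = gap, label = lab, fs = fs)
    })
    names(out) <- names(offsets)
    out
  })
}
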