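# Gait-event detection inside labeled strides: terminal contact (TC),
# initial contact (IC) and the least-movement point t_vmin that anchors the
# zero-velocity assumption, plus the derived t_vmin-to-t_vmin stride list.

#' Medial-lateral gyroscope signal
#'
#' In the aligned frame (x forward, y left, z up) the clinically conventional
#' medial-lateral angular-velocity signal — large positive swing peak,
#' negative troughs around terminal and initial contact — is the negated
#' y-axis gyroscope.
#'
#' @param stream An aligned [imu_stream()].
#' @return Numeric vector, deg/s.
#' @export
ml_gyro <- function(stream) -stream$gyr[, 2]

#' Snap stride borders to the nearest ML-gyro minimum
#'
#' Moves every labeled stride border to the sample of the signal minimum
#' within a `snap_window_ms` window centred on the label. Borders shared by
#' adjacent strides are snapped once, so they remain shared; windows
#' truncated by the signal edge are clamped and flagged.
#'
#' @param gyr_ml Medial-lateral gyroscope signal (see [ml_gyro()]), deg/s.
#' @param labels Stride label data frame with `start`, `end` (1-based,
#'   half-open) and `stride_id`.
#' @param fs Sampling rate, Hz.
#' @param snap_window_ms Full window width, ms.
#' @return `labels` with snapped borders and a logical `clamped` column.
#' @export
snap_stride_borders <- function(gyr_ml, labels, fs = 204.8,
                                snap_window_ms = 50) {
  if (nrow(labels) == 0) return(cbind(labels, clamped = logical(0)))
  half <- max(1L, as.integer(round(snap_window_ms / 2 / 1000 * fs)))
  n <- length(gyr_ml)
  borders <- sort(unique(c(labels$start, labels$end)))
  snapped <- integer(length(borders))
  clamped <- logical(length(borders))
  for (i in seq_along(borders)) {
    b <- borders[i]
    lo <- b - half
    hi <- b + half
    clamped[i] <- lo < 1 || hi > n
    lo <- max(1L, lo)
    hi <- min(n, hi)
    snapped[i] <- lo + which.min(gyr_ml[lo:hi]) - 1L
  }
  map <- stats::setNames(snapped, borders)
  was_clamped <- stats::setNames(clamped, borders)
  out <- labels
  out$start <- unname(map[as.character(labels$start)])
  out$end <- unname(map[as.character(labels$end)])
  out$clamped <- unname(was_clamped[as.character(labels$start)] |
                          was_clamped[as.character(labels$end)])
  validate_stride_labels(out)
  out
}

# Rolling sum of x over windows of length w (returns length N - w + 1).
rolling_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  i <- seq_len(length(x) - w + 1L)
  cs[i + w] - cs[i]
}

#' Detect TC, IC and t_vmin within labeled strides
#'
#' Per stride: TC is the first negative-to-positive zero crossing of the
#' medial-lateral gyro after the stride start; IC is the most prominent
#' negative ML-gyro peak after the swing maximum (not earlier than
#' `ic_search_fraction` of the stride), refined to the adjacent minimum of
#' the superior-inferior acceleration; t_vmin is the centre of the
#' `tvmin_window_samples`-sample window of minimal gyroscope-norm energy in
#' `[ic, end)`. Events are validated with [validate_events()].
#'
#' @param stream Aligned [imu_stream()].
#' @param labels Snapped stride label data frame (`stride_id`, `start`,
#'   `end`).
#' @param config A [pipeline_config()].
#' @return Data frame per stride: `stride_id`, `tc`, `ic`, `tvmin`
#'   (absolute samples), `valid`, `reason` (`"order"`, `"no_ic_60"` or
#'   `"none"`).
#' @export
detect_events <- function(stream, labels, config = pipeline_config()) {
  ml_full <- ml_gyro(stream)
  acc_z <- stream$acc[, 3]
  gyr_energy <- rowSums(stream$gyr^2)
  w <- as.integer(config$tvmin_window_samples)

  rows <- lapply(seq_len(nrow(labels)), function(i) {
    s0 <- labels$start[i]
    s1 <- labels$end[i]
    out <- data.frame(stride_id = labels$stride_id[i],
                      tc = NA_integer_, ic = NA_integer_,
                      tvmin = NA_integer_, valid = FALSE, reason = "order",
                      stringsAsFactors = FALSE)
    ml <- ml_full[s0:(s1 - 1L)]
    n <- length(ml)
    cross <- which(ml[-n] <= 0 & ml[-1] > 0)
    if (!length(cross)) return(out)
    tc_rel <- cross[1] + 1L
    out$tc <- s0 + tc_rel - 1L

    search_from <- max(which.max(ml),
                       as.integer(ceiling(config$ic_search_fraction * n)))
    if (search_from >= n) return(out)
    ic_rel <- search_from + which.min(ml[search_from:n]) - 1L
    # refine on the superior-inferior acceleration near the gyro trough
    lo <- max(1L, ic_rel - 6L)
    hi <- min(n, ic_rel + 6L)
    ic_rel <- lo + which.min(acc_z[(s0 + lo - 1L):(s0 + hi - 1L)]) - 1L
    out$ic <- s0 + ic_rel - 1L

    if (s1 - out$ic < w) return(out)
    e <- rolling_sum(gyr_energy[out$ic:(s1 - 1L)], w)
    out$tvmin <- out$ic + which.min(e) - 1L + w %/% 2L
    out$reason <- "none"
    out
  })
  events <- do.call(rbind, rows)
  validate_events(events, labels, config)
}

#' Validate detected gait events
#'
#' A stride's events are invalid if they are not in the expected order
#' (`start <= tc < ic < tvmin < end`, reason `"order"`) or if the initial
#' contact falls after the first 60% of the gait cycle (reason
#' `"no_ic_60"`).
#'
#' @param events Data frame from [detect_events()].
#' @param labels Matching stride label data frame.
#' @param config A [pipeline_config()].
#' @param ic_max_fraction Latest admissible IC, as a fraction of the stride.
#' @return `events` with refreshed `valid` and `reason` columns.
#' @export
validate_events <- function(events, labels, config = pipeline_config(),
                            ic_max_fraction = 0.6) {
  stopifnot(nrow(events) == nrow(labels))
  ord_ok <- !is.na(events$tc) & !is.na(events$ic) & !is.na(events$tvmin) &
    labels$start <= events$tc & events$tc < events$ic &
    events$ic < events$tvmin & events$tvmin < labels$end
  ic_ok <- !is.na(events$ic) &
    (events$ic - labels$start) <= ic_max_fraction * (labels$end - labels$start)
  events$valid <- ord_ok & ic_ok
  events$reason <- ifelse(events$valid, "none",
                          ifelse(!ord_ok, "order", "no_ic_60"))
  events
}

#' Build t_vmin-to-t_vmin strides
#'
#' One v_min stride per pair of adjacent valid strides: it starts at the
#' t_vmin of stride `k` and ends at the t_vmin of the adjacent stride
#' `k + 1`, inheriting `stride_id` from the start stride. Each unbroken gait
#' sequence of `m` valid strides therefore yields `m - 1` v_min strides.
#'
#' @param events Data frame from [detect_events()] for one sensor.
#' @param labels Matching stride label data frame (adjacency is
#'   `end[k] == start[k + 1]`).
#' @return Data frame with `stride_id`, `start`, `end` (absolute samples).
#' @export
build_vmin_strides <- function(events, labels) {
  stopifnot(nrow(events) == nrow(labels))
  n <- nrow(labels)
  if (n < 2) {
    return(data.frame(stride_id = integer(0), start = integer(0),
                      end = integer(0)))
  }
  k <- seq_len(n - 1L)
  adjacent <- labels$end[k] == labels$start[k + 1L]
  ok <- adjacent & events$valid[k] & events$valid[k + 1L]
  data.frame(
    stride_id = labels$stride_id[k][ok],
    start = events$tvmin[k][ok],
    end = events$tvmin[k + 1L][ok]
  )
}
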