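# Raw-signal comparison metrics and per-stride features: sample-wise 3D and
# norm differences between sensor pairs, residual mid-stance gyro energy,
# peak acceleration, Welch band powers and the cross-sensor STD profile.

stride_idx <- function(start, end) start:(end - 1L)

#' Sample-wise 3D difference between two sensors over a stride
#'
#' Mean norm of the sample-wise vector difference,
#' `(1/N) * sum_k ||x_i_k - x_j_k||`, for the accelerometer and the
#' gyroscope. Always non-negative; cannot distinguish noisy differences from
#' constant offsets.
#'
#' @param stream_i,stream_j Aligned [imu_stream()]s.
#' @param start,end Labeled stride bounds (identical for both sensors).
#' @return Named numeric: `d3d_acc` (m/s^2), `d3d_gyr` (deg/s).
#' @export
pairwise_diff_3d <- function(stream_i, stream_j, start, end) {
  if (n_samples(stream_i) != n_samples(stream_j)) {
    stop("streams must share bounds and length", call. = FALSE)
  }
  k <- stride_idx(start, end)
  da <- stream_i$acc[k, , drop = FALSE] - stream_j$acc[k, , drop = FALSE]
  dg <- stream_i$gyr[k, , drop = FALSE] - stream_j$gyr[k, , drop = FALSE]
  c(d3d_acc = mean(sqrt(rowSums(da^2))),
    d3d_gyr = mean(sqrt(rowSums(dg^2))))
}

#' Sample-wise norm difference between two sensors over a stride
#'
#' Mean difference of the vector norms,
#' `(1/N) * sum_k (||x_i_k|| - ||x_j_k||)`. May be negative; is expected to
#' vanish when the sensors differ only by a zero-mean oscillation, which
#' makes it a complement to [pairwise_diff_3d()] for separating offsets from
#' vibration.
#'
#' @inheritParams pairwise_diff_3d
#' @return Named numeric: `dnorm_acc` (m/s^2), `dnorm_gyr` (deg/s).
#' @export
pairwise_diff_norm <- function(stream_i, stream_j, start, end) {
  if (n_samples(stream_i) != n_samples(stream_j)) {
    stop("streams must share bounds and length", call. = FALSE)
  }
  k <- stride_idx(start, end)
  na_i <- sqrt(rowSums(stream_i$acc[k, , drop = FALSE]^2))
  na_j <- sqrt(rowSums(stream_j$acc[k, , drop = FALSE]^2))
  ng_i <- sqrt(rowSums(stream_i$gyr[k, , drop = FALSE]^2))
  ng_j <- sqrt(rowSums(stream_j$gyr[k, , drop = FALSE]^2))
  c(dnorm_acc = mean(na_i - na_j), dnorm_gyr = mean(ng_i - ng_j))
}

#' Residual gyroscope energy around t_vmin
#'
#' Sum of squared gyroscope-norm values in a window (default 8 samples =
#' 40 ms at 204.8 Hz) centred on t_vmin. Any value above zero means the
#' sensor still moved during the assumed zero-velocity phase.
#'
#' @param stream Aligned [imu_stream()].
#' @param tvmin Centre sample.
#' @param window Window width, samples.
#' @return List with `e_vmin` (deg^2/s^2) and `truncated` (window clipped by
#'   a signal edge).
#' @export
residual_energy <- function(stream, tvmin, window = 8L) {
  half <- window %/% 2L
  lo <- tvmin - half
  hi <- lo + window - 1L
  truncated <- lo < 1 || hi > n_samples(stream)
  lo <- max(1L, lo)
  hi <- min(n_samples(stream), hi)
  list(e_vmin = sum(stream$gyr[lo:hi, ]^2), truncated = truncated)
}

#' Peak acceleration norm over a stride
#'
#' @param stream Aligned [imu_stream()].
#' @param start,end Stride bounds.
#' @return `a_max` in m/s^2 (in most strides reached right after initial
#'   contact).
#' @export
peak_acceleration <- function(stream, start, end) {
  k <- stride_idx(start, end)
  max(sqrt(rowSums(stream$acc[k, , drop = FALSE]^2)))
}

# Periodic Hann window (the convention of FFT-segment averaging).
hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Welch power spectral density
#'
#' Welch's method with a Hann window of `nperseg` samples, 50% overlap and
#' segments zero-padded to `nfft` points (doubling the spectral resolution).
#' One-sided density scaling: integrating the PSD over frequency recovers the
#' signal power.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param nperseg Segment length, samples.
#' @param noverlap Overlap, samples.
#' @param nfft Zero-padded transform length.
#' @param detrend Remove each segment's mean before transforming.
#' @return List with `freq` (Hz) and `psd` (signal-units^2 / Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 64L, noverlap = 32L, nfft = 128L,
                      detrend = FALSE) {
  n <- length(x)
  if (n < nperseg) stop("signal shorter than one Welch segment", call. = FALSE)
  w <- hann_periodic(nperseg)
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nh <- nfft %/% 2L
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    seg <- c(seg * w, numeric(nfft - nperseg))
    sp <- stats::fft(seg)[1:(nh + 1L)]
    acc <- acc + Mod(sp)^2
  }
  scale <- 1 / (fs * sum(w^2) * length(starts))
  psd <- acc * scale
  psd[2:nh] <- 2 * psd[2:nh]  # one-sided, DC and Nyquist not doubled
  list(freq = (0:nh) * fs / nfft, psd = psd)
}

#' Mean band power of a signal norm
#'
#' Welch PSD of the per-sample vector norm over one stride, averaged over the
#' low band (0, 20] Hz (the human movement range; the DC bin is excluded) and
#' the high band (80, 102.4) Hz next to the Nyquist frequency.
#'
#' @param mat N x 3 signal matrix (stride slice).
#' @param fs Sampling rate, Hz.
#' @param detrend Passed to [welch_psd()].
#' @return Named numeric `c(low, high)`, or `NA`s if the stride is shorter
#'   than one Welch segment.
#' @export
psd_band_power <- function(mat, fs = 204.8, detrend = FALSE) {
  nrm <- sqrt(rowSums(mat^2))
  if (length(nrm) < 64L) return(c(low = NA_real_, high = NA_real_))
  p <- welch_psd(nrm, fs, detrend = detrend)
  low <- p$freq > 0 & p$freq <= 20
  high <- p$freq > 80 & p$freq < 102.4
  c(low = mean(p$psd[low]), high = mean(p$psd[high]))
}

#' Cross-sensor standard-deviation profile
#'
#' For every labeled stride, the per-sample, per-axis standard deviation
#' across the sensors of one foot (sample denominator n - 1), linearly
#' interpolated to 200 samples and averaged over strides. High values mark
#' gait-cycle regions where the sensor positions disagree.
#'
#' @param set Aligned [sensor_set()].
#' @param labels Stride label data frame.
#' @param n_points Profile length.
#' @return Data frame with `phase` (0..1) and one column per axis
#'   (`acc_x..z`, `gyr_x..z`).
#' @export
cross_sensor_std_profile <- function(set, labels, n_points = 200L) {
  streams <- set$streams
  chans <- c(paste0("acc_", c("x", "y", "z")), paste0("gyr_", c("x", "y", "z")))
  profile <- matrix(0, n_points, 6, dimnames = list(NULL, chans))
  used <- 0L
  for (i in seq_len(nrow(labels))) {
    k <- stride_idx(labels$start[i], labels$end[i])
    if (length(k) < 2) next
    per_chan <- vapply(seq_len(6), function(j) {
      vals <- vapply(streams, function(s) {
        m <- if (j <= 3) s$acc else s$gyr
        m[k, ((j - 1L) %% 3L) + 1L]
      }, numeric(length(k)))
      sdv <- apply(vals, 1, stats::sd)
      stats::approx(seq_along(sdv), sdv, n = n_points)$y
    }, numeric(n_points))
    profile <- profile + per_chan
    used <- used + 1L
  }
  if (used > 0) profile <- profile / used
  data.frame(phase = seq(0, 1, length.out = n_points), profile)
}
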