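# Stride-length error statistics, stride-category grouping, feature-error
# correlation, and the end-to-end session pipeline.

EXTREME_OUTLIER_M <- 0.30  # absolute error defining an "extreme outlier"

#' Join IMU and reference stride lengths into an error table
#'
#' Signed error is IMU minus heel reference: positive values are an
#' overestimation by the IMU. Rows missing either length are dropped (their
#' keys are reported in the `dropped` attribute).
#'
#' @param results Data frame with one row per stride x sensor containing
#'   `stride_id`, `position`, `imu_length_m` and `heel_length_m` (plus any
#'   carry-through columns).
#' @return The table with `error_m` and `abs_error_m` columns.
#' @export
compute_stride_errors <- function(results) {
  key <- paste(results$foot %||% "", results$stride_id, results$position)
  if (anyDuplicated(key)) {
    stop("duplicate stride_id x position keys", call. = FALSE)
  }
  ok <- !is.na(results$imu_length_m) & !is.na(results$heel_length_m)
  dropped <- results[!ok, c("stride_id", "position")]
  out <- results[ok, , drop = FALSE]
  out$error_m <- out$imu_length_m - out$heel_length_m
  out$abs_error_m <- abs(out$error_m)
  attr(out, "dropped") <- dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stride-category memberships mirroring the walk-test grouping: the three
# speed groups cover the straight walk tests only, "straight" is their
# union, "5min-walk" the continuous walk, and "all" everything.
stride_categories <- function(test_id, speed_category) {
  straight_test <- grepl("^(4x10|2x20)", test_id)
  cats <- list("all")
  if (straight_test) cats <- c(cats, "straight", speed_category)
  if (grepl("^5min", test_id)) cats <- c(cats, "5min-walk")
  unlist(cats)
}

#' Summarize stride-length errors per sensor and stride category
#'
#' Per sensor position and category: stride count, mean signed error, mean
#' absolute error, interquartile range (linear-interpolation quantiles),
#' Tukey outlier count (outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the signed
#' error) and extreme-outlier count (absolute error above 30 cm).
#'
#' @param errors Error table from [compute_stride_errors()], with `test_id`
#'   and `speed_category` columns.
#' @return Data frame with one row per position x category.
#' @export
summarize_errors <- function(errors) {
  if (nrow(errors) == 0) {
    return(data.frame(position = character(0), category = character(0),
                      n = integer(0)))
  }
  cats <- Map(stride_categories, errors$test_id, errors$speed_category)
  expanded <- errors[rep(seq_len(nrow(errors)), lengths(cats)), ]
  expanded$category <- unlist(cats)
  groups <- split(expanded,
                  list(expanded$position, expanded$category), drop = TRUE)
  rows <- lapply(groups, function(g) {
    q <- stats::quantile(g$error_m, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    data.frame(
      position = g$position[1],
      category = g$category[1],
      n = nrow(g),
      mean_error_m = mean(g$error_m),
      mae_m = mean(g$abs_error_m),
      iqr_m = iqr,
      n_outliers = sum(g$error_m < q[1] - 1.5 * iqr |
                         g$error_m > q[2] + 1.5 * iqr),
      n_extreme = sum(g$abs_error_m > EXTREME_OUTLIER_M),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$category, out$position), ]
}

#' Correlate a raw-data feature with the stride-length error
#'
#' Joins a feature table and an error table on stride x sensor keys and
#' reports the Spearman rank correlation (and, for completeness, Pearson)
#' between the feature and the absolute error at the requested granularity:
#' raw per-stride values, per-gait-test medians, or per-sensor medians.
#'
#' @param features Feature table (e.g. from [analyze_session()]) with
#'   `stride_id`, `position`, `foot`, `test_id` and the feature column.
#' @param errors Error table from [compute_stride_errors()].
#' @param feature Name of the feature column.
#' @param granularity `"stride"`, `"test"` or `"sensor"`.
#' @return List with `rho` (Spearman), `pearson`, `n`, `flagged` (TRUE when
#'   fewer than 3 pairs or a degenerate constant input), and the aggregated
#'   `pairs` data frame.
#' @export
correlate_feature_error <- function(features, errors, feature = "e_vmin",
                                    granularity = c("stride", "test",
                                                    "sensor")) {
  granularity <- match.arg(granularity)
  key_f <- paste(features$foot, features$stride_id, features$position)
  key_e <- paste(errors$foot, errors$stride_id, errors$position)
  m <- match(key_f, key_e)
  ok <- !is.na(m)
  pairs <- data.frame(
    position = features$position[ok],
    test_id = features$test_id[ok],
    feature = features[[feature]][ok],
    abs_error_m = errors$abs_error_m[m[ok]]
  )
  pairs <- pairs[stats::complete.cases(pairs), ]
  if (granularity != "stride") {
    by <- if (granularity == "test") {
      list(position = pairs$position, test_id = pairs$test_id)
    } else {
      list(position = pairs$position)
    }
    pairs <- stats::aggregate(pairs[c("feature", "abs_error_m")], by,
                              stats::median)
  }
  n <- nrow(pairs)
  degenerate <- n < 3 ||
    stats::sd(pairs$feature) == 0 || stats::sd(pairs$abs_error_m) == 0
  list(
    rho = if (degenerate) NA_real_ else
      stats::cor(pairs$feature, pairs$abs_error_m, method = "spearman"),
    pearson = if (degenerate) NA_real_ else
      stats::cor(pairs$feature, pairs$abs_error_m),
    n = n,
    flagged = degenerate,
    pairs = pairs,
    granularity = granularity
  )
}

#' Run the full analysis pipeline on a session
#'
#' Executes, per foot: sensor alignment to the cavity reference, stride
#' border snapping on the instep ML gyro, per-sensor event detection and
#' v_min-stride construction, per-sensor IMU stride lengths, heel/toe marker
#' reference lengths, cross-sensor stride selection, error statistics, and
#' the raw-data features.
#'
#' @param session A `gait_session` (from [simulate_session()] /
#'   [assemble_session()] or [read_session()]).
#' @param config A [pipeline_config()].
#' @param features Compute the per-stride feature table?
#' @param pairwise Compute the pairwise 3D/norm difference table and the STD
#'   profile (the most expensive outputs)?
#' @return List with `alignment`, `labels`, `events`, `vmin_strides`,
#'   `stride_results` (all strides with both lengths), `kept_results`
#'   (selected strides only), `selection`, `summary` (error summary over kept
#'   strides), `features`, `pairwise`, `std_profile`.
#' @export
analyze_session <- function(session, config = pipeline_config(),
                            features = TRUE, pairwise = FALSE) {
  stopifnot(inherits(session, "gait_session"))
  fs <- session$meta$fs_imu
  offset <- session$meta$mocap_offset_s %||% 0

  alignment <- list()
  labels_out <- list()
  events_out <- list()
  vmin_out <- list()
  result_rows <- list()
  feature_rows <- list()
  pairwise_rows <- list()
  std_profiles <- list()
  selections <- list()

  for (foot in names(session$sets)) {
    al <- align_sensor_set(session$sets[[foot]], config)
    alignment[[foot]] <- al$alignment
    set <- al$set

    labels <- session$strides[[foot]]
    labels <- snap_stride_borders(ml_gyro(set$streams[["instep"]]), labels,
                                  fs = fs,
                                  snap_window_ms = config$snap_window_ms)
    labels_out[[foot]] <- labels

    cal <- fill_marker_gaps(session$markers[[foot]]$CAL,
                            config$marker_max_gap_ms)
    toe <- fill_marker_gaps(session$markers[[foot]]$TOE,
                            config$marker_max_gap_ms)

    foot_events <- list()
    foot_rows <- list()
    for (pos in names(set$streams)) {
      stream <- set$streams[[pos]]
      ev <- detect_events(stream, labels, config)
      foot_events[[pos]] <- cbind(position = pos, ev)
      vmin <- build_vmin_strides(ev, labels)
      if (nrow(vmin) == 0) next
      lab_i <- match(vmin$stride_id, labels$stride_id)
      rows <- data.frame(
        foot = foot, position = pos,
        stride_id = vmin$stride_id,
        start = vmin$start, end = vmin$end,
        test_id = labels$test_id[lab_i],
        speed_category = labels$speed_category[lab_i],
        stringsAsFactors = FALSE
      )
      if (!is.null(labels$vmin_true_length_m)) {
        rows$vmin_true_length_m <- labels$vmin_true_length_m[lab_i]
        rows$vmin_straight <- labels$vmin_straight[lab_i]
      }
      rows$imu_length_m <- vapply(seq_len(nrow(vmin)), function(i) {
        stride_length(stream, vmin$start[i], vmin$end[i], config)
      }, numeric(1))
      rows$heel_length_m <- vapply(seq_len(nrow(vmin)), function(i) {
        reference_stride_length(cal, vmin$start[i], vmin$end[i], fs, offset)
      }, numeric(1))
      rows$toe_length_m <- vapply(seq_len(nrow(vmin)), function(i) {
        reference_stride_length(toe, vmin$start[i], vmin$end[i], fs, offset)
      }, numeric(1))
      foot_rows[[pos]] <- rows

      if (features) {
        fr <- rows[c("foot", "position", "stride_id", "test_id",
                     "speed_category")]
        fr$e_vmin <- vapply(seq_len(nrow(vmin)), function(i) {
          residual_energy(stream, vmin$start[i],
                          config$tvmin_window_samples)$e_vmin
        }, numeric(1))
        fr$a_max <- vapply(seq_len(nrow(vmin)), function(i) {
          peak_acceleration(stream, vmin$start[i], vmin$end[i])
        }, numeric(1))
        bands <- t(vapply(seq_len(nrow(vmin)), function(i) {
          k <- vmin$start[i]:(vmin$end[i] - 1L)
          c(psd_band_power(stream$acc[k, , drop = FALSE], fs,
                           config$psd_detrend),
            psd_band_power(stream$gyr[k, , drop = FALSE], fs,
                           config$psd_detrend))
        }, numeric(4)))
        colnames(bands) <- c("psd_low_acc", "psd_high_acc",
                             "psd_low_gyr", "psd_high_gyr")
        feature_rows[[paste(foot, pos)]] <- cbind(fr, bands)
      }
    }
    events_out[[foot]] <- do.call(rbind, c(foot_events,
                                           list(make.row.names = FALSE)))
    vmin_out[[foot]] <- foot_rows
    foot_table <- do.call(rbind, c(foot_rows, list(make.row.names = FALSE)))
    result_rows[[foot]] <- foot_table

    sel <- select_strides(foot_table, config$straightness_threshold_m)
    selections[[foot]] <- sel

    if (pairwise) {
      pos_pairs <- utils::combn(names(set$streams), 2)
      pw <- list()
      for (j in seq_len(ncol(pos_pairs))) {
        pi <- pos_pairs[1, j]
        pj <- pos_pairs[2, j]
        vals <- t(vapply(seq_len(nrow(labels)), function(i) {
          c(pairwise_diff_3d(set$streams[[pi]], set$streams[[pj]],
                             labels$start[i], labels$end[i]),
            pairwise_diff_norm(set$streams[[pi]], set$streams[[pj]],
                               labels$start[i], labels$end[i]))
        }, numeric(4)))
        pw[[j]] <- data.frame(foot = foot, pos_i = pi, pos_j = pj,
                              stride_id = labels$stride_id, vals,
                              stringsAsFactors = FALSE)
      }
      pairwise_rows[[foot]] <- do.call(rbind, c(pw,
                                                list(make.row.names = FALSE)))
      std_profiles[[foot]] <- cross_sensor_std_profile(set, labels)
    }
  }

  stride_results <- do.call(rbind, c(result_rows, list(make.row.names = FALSE)))
  errors <- compute_stride_errors(stride_results)
  kept <- do.call(rbind, lapply(names(selections), function(foot) {
    data.frame(foot = foot, stride_id = selections[[foot]]$kept)
  }))
  kept_key <- paste(kept$foot, kept$stride_id)
  kept_results <- errors[paste(errors$foot, errors$stride_id) %in% kept_key, ]

  list(
    alignment = alignment,
    labels = labels_out,
    events = events_out,
    stride_results = errors,
    kept_results = kept_results,
    selection = selections,
    summary = summarize_errors(kept_results),
    features = if (features) {
      do.call(rbind, c(feature_rows, list(make.row.names = FALSE)))
    },
    pairwise = if (pairwise) {
      do.call(rbind, c(pairwise_rows, list(make.row.names = FALSE)))
    },
    std_profile = if (pairwise) std_profiles
  )
}
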