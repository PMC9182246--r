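# On-disk session layout (text only):
#   meta.json                   rates, feet, positions, seed, clock offset
#   imu_<foot>_<position>.csv   sample, acc_x..z [m/s^2], gyr_x..z [deg/s]
#   marker_<foot>_<label>.csv   frame, x, y, z [m], gap (0/1)
#   strides_<foot>.csv          labeled stride table (ground truth for
#                               synthetic sessions)
# CSV dialect: comma-separated, '.' decimal, header row, UTF-8.

#' Write a session directory
#'
#' Serializes a `gait_session` to the documented CSV + JSON layout. Numeric
#' values round-trip through the text representation to within 1e-9 relative
#' error.
#'
#' @param session A `gait_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "gait_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (foot in names(session$sets)) {
    set <- session$sets[[foot]]
    for (pos in names(set$streams)) {
      s <- set$streams[[pos]]
      df <- data.frame(sample = seq_len(n_samples(s)),
                       acc_x = s$acc[, 1], acc_y = s$acc[, 2],
                       acc_z = s$acc[, 3],
                       gyr_x = s$gyr[, 1], gyr_y = s$gyr[, 2],
                       gyr_z = s$gyr[, 3])
      utils::write.csv(df, file.path(path, sprintf("imu_%s_%s.csv", foot, pos)),
                       row.names = FALSE)
    }
    for (lab in names(session$markers[[foot]])) {
      m <- session$markers[[foot]][[lab]]
      df <- data.frame(frame = seq_len(nrow(m$pos)),
                       x = m$pos[, 1], y = m$pos[, 2], z = m$pos[, 3],
                       gap = as.integer(m$gap))
      utils::write.csv(df, file.path(path, sprintf("marker_%s_%s.csv", foot, lab)),
                       row.names = FALSE)
    }
    utils::write.csv(session$strides[[foot]],
                     file.path(path, sprintf("strides_%s.csv", foot)),
                     row.names = FALSE)
  }
  meta <- session$meta
  meta$protocol <- NULL
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session directory
#'
#' Reads the layout written by [write_session()] back into a validated
#' in-memory `gait_session`. Units are the package-wide ones (m/s^2, deg/s,
#' metres).
#'
#' @param path Session directory.
#' @return A `gait_session`.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("not a session directory (missing meta.json): ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  feet <- meta$feet
  sets <- list()
  markers <- list()
  strides <- list()
  for (foot in feet) {
    streams <- list()
    for (pos in SENSOR_POSITIONS) {
      f <- file.path(path, sprintf("imu_%s_%s.csv", foot, pos))
      if (!file.exists(f)) {
        stop(sprintf("missing sensor position '%s' for %s foot (%s)",
                     pos, foot, basename(f)), call. = FALSE)
      }
      df <- utils::read.csv(f)
      streams[[pos]] <- imu_stream(
        acc = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
        gyr = as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]),
        fs = meta$fs_imu, position = pos, foot = foot
      )
    }
    sets[[foot]] <- sensor_set(streams, foot = foot)

    markers[[foot]] <- list()
    for (lab in c("CAL", "TOE")) {
      f <- file.path(path, sprintf("marker_%s_%s.csv", foot, lab))
      if (!file.exists(f)) {
        stop(sprintf("missing marker '%s' for %s foot", lab, foot),
             call. = FALSE)
      }
      df <- utils::read.csv(f)
      markers[[foot]][[lab]] <- marker_stream(
        pos = as.matrix(df[, c("x", "y", "z")]),
        gap = df$gap != 0, label = lab, fs = meta$fs_mocap
      )
    }

    f <- file.path(path, sprintf("strides_%s.csv", foot))
    if (!file.exists(f)) {
      stop(sprintf("missing stride table for %s foot", foot), call. = FALSE)
    }
    st <- utils::read.csv(f)
    validate_stride_labels(st)
    strides[[foot]] <- st
  }
  structure(list(sets = sets, markers = markers, strides = strides,
                 meta = meta),
            class = "gait_session")
}

# Stride label invariants: start < end, sorted, non-overlapping; adjacent
# strides share end == start.
validate_stride_labels <- function(st) {
  if (nrow(st) == 0) return(invisible(st))
  if (any(st$start >= st$end)) {
    stop("stride labels must satisfy start < end", call. = FALSE)
  }
  if (is.unsorted(st$start)) {
    stop("stride labels must be sorted by start sample", call. = FALSE)
  }
  if (nrow(st) > 1 && any(st$start[-1] < st$end[-nrow(st)])) {
    stop("stride labels must not overlap", call. = FALSE)
  }
  invisible(st)
}
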