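# Assembly of complete synthetic recording sessions: several walking bouts
# per foot, six mounted IMUs sharing one rigid foot motion, and heel/toe
# marker references.

#' Desk-scale walk-test protocol
#'
#' The emulated protocol: 4x10 m and 2x20 m walk tests at self-selected slow,
#' normal and fast speeds plus a continuous figure-eight walk, scaled down to
#' a size suitable for simulation. Turning strides are interspersed with the
#' per-test frequency a shuttle/figure-eight path implies.
#'
#' @param scale Multiplier on the per-test stride counts.
#' @return Data frame with one row per bout: `test_id`, `speed_category`,
#'   `n_strides`, `turn_fraction`, `turn_angle_deg`, `stride_length_m`,
#'   `stride_time_s`.
#' @export
session_protocol <- function(scale = 1) {
  speeds <- data.frame(
    speed_category = SPEED_CATEGORIES,
    stride_length_m = c(1.05, 1.30, 1.55),
    stride_time_s = c(1.25, 1.10, 0.95)
  )
  rows <- rbind(
    data.frame(test_id = paste0("4x10_", speeds$speed_category),
               speeds, n_strides = 20L, turn_fraction = 0.15,
               turn_angle_deg = 60),
    data.frame(test_id = paste0("2x20_", speeds$speed_category),
               speeds, n_strides = 24L, turn_fraction = 0.08,
               turn_angle_deg = 60),
    data.frame(test_id = "5min", speed_category = "normal",
               stride_length_m = 1.30, stride_time_s = 1.10,
               n_strides = 40L, turn_fraction = 0.25, turn_angle_deg = 35)
  )
  rows$n_strides <- pmax(4L, as.integer(round(rows$n_strides * scale)))
  rownames(rows) <- NULL
  rows[, c("test_id", "speed_category", "n_strides", "turn_fraction",
           "turn_angle_deg", "stride_length_m", "stride_time_s")]
}

# Concatenate the per-bout pose segments of one foot into a single
# pose_series, shifting sample indices and renumbering stride ids.
chain_poses <- function(poses, protocol) {
  mats <- c("pos", "quat", "vel", "acc", "omega_world", "omega_body",
            "alpha_world")
  offsets <- c(0L, cumsum(vapply(poses, function(p) p$n, integer(1))))
  full <- poses[[1]]
  for (m in mats) {
    full[[m]] <- do.call(rbind, lapply(poses, function(p) p[[m]]))
  }
  full$n <- offsets[length(offsets)]
  shift_df <- function(get, cols) {
    parts <- lapply(seq_along(poses), function(b) {
      df <- get(poses[[b]])
      df[cols] <- lapply(df[cols], function(x) as.integer(x + offsets[b]))
      df$test_id <- protocol$test_id[b]
      df
    })
    do.call(rbind, parts)
  }
  full$strides <- shift_df(function(p) p$strides, c("start", "end"))
  full$strides$stride_id <- seq_len(nrow(full$strides))
  full$flat <- shift_df(function(p) p$flat, c("start", "end"))
  full$impacts <- shift_df(function(p) p$impacts, "sample")
  full$origin_end <- poses[[length(poses)]]$origin_end
  full$psi_end <- poses[[length(poses)]]$psi_end
  full
}

internal_to_imu_sample <- function(s, ratio) as.integer(round((s - 1) / ratio) + 1L)

mirror_mount <- function(mount) {
  mount$r[2] <- -mount$r[2]
  mount
}

#' Assemble a complete synthetic session
#'
#' Generates one rigid foot motion per foot following `protocol`, derives the
#' six mounted sensor signals from that common motion (lever arm + mounting
#' rotation + attachment dynamics), samples them at the IMU rate, simulates
#' heel/toe markers at the capture rate with an optional capture-clock offset,
#' and emits ground-truth stride labels in IMU samples. Deterministic given
#' `seed`.
#'
#' @param protocol Bout table from [session_protocol()] (or a compatible data
#'   frame).
#' @param mounts Named list of exactly six [mounting_spec()]s with distinct
#'   positions (default [default_mounting_specs()]).
#' @param seed Integer session seed.
#' @param feet Which feet to simulate.
#' @param fs IMU sampling rate, Hz.
#' @param fs_internal Internal simulation rate, Hz (integer multiple of `fs`).
#' @param attachment Apply attachment dynamics (impact transients, rollover
#'   coupling)?
#' @param noise_acc_sd,noise_gyr_sd IMU noise levels (m/s^2, deg/s); set to 0
#'   for noise-free sessions.
#' @param marker_gap_rate_per_s Marker gap process intensity.
#' @param mocap_offset_jitter_s Half-width of the uniform capture-clock offset
#'   (the emulated hardware synchronization is accurate to 10 ms); the drawn
#'   offset is recorded in the session metadata.
#' @return A list of class `gait_session` with `$sets` (per-foot
#'   [sensor_set()]), `$markers` (per-foot list of CAL/TOE
#'   [marker_stream()]s), `$strides` (per-foot ground-truth stride tables in
#'   IMU samples) and `$meta`.
#' @export
assemble_session <- function(protocol = session_protocol(),
                             mounts = default_mounting_specs(),
                             seed = 1L,
                             feet = c("left", "right"),
                             fs = 204.8,
                             fs_internal = 2048,
                             attachment = TRUE,
                             noise_acc_sd = 0.02,
                             noise_gyr_sd = 0.05,
                             marker_gap_rate_per_s = 0.05,
                             mocap_offset_jitter_s = 0.01) {
  feet <- match.arg(feet, c("left", "right"), several.ok = TRUE)
  if (length(mounts) != 6 ||
      anyDuplicated(vapply(mounts, function(m) m$position, character(1)))) {
    stop("mounts must contain six specs with distinct positions",
         call. = FALSE)
  }
  names(mounts) <- vapply(mounts, function(m) m$position, character(1))
  ratio <- as.integer(round(fs_internal / fs))
  if (abs(fs_internal / fs - ratio) > 1e-9) {
    stop("fs_internal must be an integer multiple of fs", call. = FALSE)
  }

  mocap_offset_s <- with_seed(derive_seed(seed, 1L), {
    if (mocap_offset_jitter_s > 0) {
      stats::runif(1, -mocap_offset_jitter_s, mocap_offset_jitter_s)
    } else 0
  })

  sets <- list()
  markers <- list()
  stride_tabs <- list()
  for (fi in seq_along(feet)) {
    foot <- feet[fi]
    poses <- vector("list", nrow(protocol))
    psi0 <- 0
    origin <- c(0, if (foot == "left") 0.10 else -0.10, 0)
    for (b in seq_len(nrow(protocol))) {
      cfg <- gait_config(
        stride_length_mean = protocol$stride_length_m[b],
        stride_time_mean = protocol$stride_time_s[b],
        speed_category = protocol$speed_category[b],
        n_strides = protocol$n_strides[b],
        turn_fraction = protocol$turn_fraction[b],
        turn_angle_deg = protocol$turn_angle_deg[b],
        seed = derive_seed(seed, 100L * fi + b)
      )
      lead_in <- if (b == 1) 3 else 1.5
      # phase-shift the right foot by half a stride
      if (b == 1 && foot == "right") lead_in <- lead_in + protocol$stride_time_s[1] / 2
      poses[[b]] <- generate_foot_pose(cfg, fs_internal = fs_internal,
                                       lead_in_s = lead_in, lead_out_s = 0.75,
                                       psi0 = psi0, origin = origin)
      psi0 <- poses[[b]]$psi_end
      origin <- poses[[b]]$origin_end
    }
    pose <- chain_poses(poses, protocol)

    foot_mounts <- if (foot == "right") lapply(mounts, mirror_mount) else mounts
    streams <- lapply(names(foot_mounts), function(p) {
      kin <- ideal_point_kinematics(pose, foot_mounts[[p]])
      if (attachment) {
        kin <- apply_attachment_dynamics(kin, foot_mounts[[p]], pose$impacts)
      }
      sample_imu(kin, fs = fs,
                 noise_acc_sd = noise_acc_sd, noise_gyr_sd = noise_gyr_sd,
                 seed = derive_seed(seed, 1000L * fi + match(p, SENSOR_POSITIONS)),
                 position = p, foot = foot)
    })
    names(streams) <- names(foot_mounts)
    sets[[foot]] <- sensor_set(streams, foot = foot)

    markers[[foot]] <- simulate_markers(
      pose, fs = 100, time_offset_s = mocap_offset_s,
      gap_rate_per_s = marker_gap_rate_per_s,
      seed = derive_seed(seed, 5000L + fi)
    )

    st <- pose$strides
    st$start <- internal_to_imu_sample(st$start, ratio)
    st$end <- internal_to_imu_sample(st$end, ratio)
    st$foot <- foot
    st$turn_angle_deg <- st$turn_angle_rad * 180 / pi
    st$turn_angle_rad <- NULL
    stride_tabs[[foot]] <- st
  }

  structure(list(
    sets = sets,
    markers = markers,
    strides = stride_tabs,
    meta = list(
      fs_imu = fs, fs_mocap = 100, fs_internal = fs_internal,
      seed = as.integer(seed), feet = feet,
      positions = SENSOR_POSITIONS,
      mocap_offset_s = mocap_offset_s,
      attachment = attachment,
      noise_acc_sd = noise_acc_sd, noise_gyr_sd = noise_gyr_sd,
      protocol = protocol
    )
  ), class = "gait_session")
}

#' Simulate a default study-protocol session
#'
#' Convenience wrapper around [assemble_session()] with the default protocol
#' and mounting table.
#'
#' @param seed Integer session seed.
#' @param ... Passed to [assemble_session()].
#' @return A `gait_session`.
#' @export
simulate_session <- function(seed = 1L, ...) {
  assemble_session(seed = seed, ...)
}

#' @export
print.gait_session <- function(x, ...) {
  n_str <- sum(vapply(x$strides, nrow, integer(1)))
  cat(sprintf(
    "<gait_session> feet: %s | %d labeled strides | IMU %g Hz, mocap %g Hz\n",
    paste(x$meta$feet, collapse = "+"), n_str, x$meta$fs_imu, x$meta$fs_mocap
  ))
  invisible(x)
}
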