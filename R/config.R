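# Configuration objects for the synthetic gait generator and the analysis
# pipeline.

SENSOR_POSITIONS <- c("insole", "cavity", "instep", "heel", "lateral", "medial")
SPEED_CATEGORIES <- c("slow", "normal", "fast")
GRAVITY_MPS2 <- 9.81

#' Gait bout configuration
#'
#' Describes one continuous bout of walking for the synthetic generator:
#' mean stride geometry and timing, speed category tag, number of strides and
#' the fraction of turning strides.
#'
#' @param stride_length_mean Mean stride length in metres (> 0).
#' @param stride_time_mean Mean stride duration in seconds (> 0).
#' @param speed_category One of `"slow"`, `"normal"`, `"fast"`; a grouping tag
#'   carried through to the error analysis.
#' @param n_strides Number of labeled strides the bout should yield.
#' @param turn_fraction Fraction of strides that change heading, in `[0, 1]`.
#' @param turn_angle_deg Heading change of a turning stride, degrees.
#' @param step_height Peak foot lift during swing, metres.
#' @param jitter_frac Relative (Gaussian) stride-to-stride variation of length
#'   and duration; 0 gives perfectly periodic gait.
#' @param seed Integer seed making the bout reproducible.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(stride_length_mean = 1.3,
                        stride_time_mean = 1.1,
                        speed_category = "normal",
                        n_strides = 10L,
                        turn_fraction = 0,
                        turn_angle_deg = 45,
                        step_height = 0.05,
                        jitter_frac = 0.03,
                        seed = 1L) {
  if (!is.numeric(stride_length_mean) || stride_length_mean <= 0) {
    stop("stride_length_mean must be > 0", call. = FALSE)
  }
  if (!is.numeric(stride_time_mean) || stride_time_mean <= 0) {
    stop("stride_time_mean must be > 0", call. = FALSE)
  }
  if (turn_fraction < 0 || turn_fraction > 1) {
    stop("turn_fraction must be in [0, 1]", call. = FALSE)
  }
  speed_category <- match.arg(speed_category, SPEED_CATEGORIES)
  structure(list(
    stride_length_mean = stride_length_mean,
    stride_time_mean = stride_time_mean,
    speed_category = speed_category,
    n_strides = as.integer(n_strides),
    turn_fraction = turn_fraction,
    turn_angle_deg = turn_angle_deg,
    step_height = step_height,
    jitter_frac = jitter_frac,
    seed = as.integer(seed)
  ), class = "gait_config")
}

#' Sensor mounting specification
#'
#' Where and how one IMU is mounted on the shoe: lever arm from the foot
#' origin, mounting rotation, and the parameters of the damped-oscillator
#' attachment response that modulates impact transients.
#'
#' @param position One of insole, cavity, instep, heel, lateral, medial.
#' @param r Lever arm (3-vector, metres, foot frame) from the foot-segment
#'   origin to the sensor; `|r|` must be at most 0.2 m.
#' @param rotation Unit quaternion `c(w, x, y, z)` mapping sensor-frame vectors
#'   into the foot frame.
#' @param f_n Attachment natural frequency, Hz (> 0).
#' @param zeta Attachment damping ratio (> 0); stiff integrated mounts are
#'   near-critically damped, loose collar clips are underdamped.
#' @param impact_gain Dimensionless gain of the impact-excited oscillator; 0
#'   disables impact transients.
#' @param rollover_coupling Fraction in `[0, 1]` of the delayed rollover
#'   deformation transmitted to the sensor.
#' @return A list of class `mounting_spec`.
#' @export
mounting_spec <- function(position,
                          r = c(0, 0, 0),
                          rotation = quat_identity(),
                          f_n = 80,
                          zeta = 0.5,
                          impact_gain = 0,
                          rollover_coupling = 0) {
  position <- match.arg(position, SENSOR_POSITIONS)
  if (sqrt(sum(r^2)) > 0.2) stop("|r| must be <= 0.2 m", call. = FALSE)
  if (f_n <= 0) stop("f_n must be > 0", call. = FALSE)
  if (zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  if (rollover_coupling < 0 || rollover_coupling > 1) {
    stop("rollover_coupling must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(rotation^2) - 1) > 1e-6) {
    stop("mounting rotation must be a unit quaternion", call. = FALSE)
  }
  structure(list(
    position = position,
    r = as.numeric(r),
    rotation = as.numeric(rotation),
    f_n = f_n,
    zeta = zeta,
    impact_gain = impact_gain,
    rollover_coupling = rollover_coupling
  ), class = "mounting_spec")
}

#' Default mounting table for the six shoe positions
#'
#' Embedded positions (cavity, insole) are stiff and well damped; the instep
#' clip is damped but strongly coupled to the rollover deformation of the toe
#' box; the collar clips (heel, lateral, medial) are underdamped with large
#' impact gains. Lever arms and mounting rotations approximate the physical
#' placement on a left shoe (x forward, y left, z up); for the right foot the
#' lateral/medial lever arms are mirrored by the session assembler.
#'
#' @param yaw_deg Optional named numeric vector of extra mounting yaw angles
#'   (degrees, about the sensor z-axis) per position, e.g.
#'   `c(instep = -10)`. Unnamed positions default to the table below.
#' @return Named list of [mounting_spec()] objects, one per position.
#' @export
default_mounting_specs <- function(yaw_deg = NULL) {
  base <- list(
    insole  = list(r = c(0.06, 0.00, 0.010), tilt = quat_identity(),
                   yaw = 3, f_n = 120, zeta = 0.70, gain = 0.80, rc = 0.10),
    cavity  = list(r = c(0.05, 0.01, 0.005), tilt = quat_identity(),
                   yaw = 0, f_n = 120, zeta = 0.70, gain = 0.90, rc = 0.00),
    instep  = list(r = c(0.09, 0.00, 0.070), tilt = quat_y(-20 * pi / 180),
                   yaw = -8, f_n = 70, zeta = 0.45, gain = 0.30, rc = 0.80),
    heel    = list(r = c(-0.06, 0.00, 0.060), tilt = quat_y(75 * pi / 180),
                   yaw = 12, f_n = 45, zeta = 0.12, gain = 1.3, rc = 0.00),
    lateral = list(r = c(0.00, -0.045, 0.050), tilt = quat_x(70 * pi / 180),
                   yaw = -30, f_n = 55, zeta = 0.15, gain = 1.5, rc = 0.00),
    medial  = list(r = c(0.00, 0.045, 0.050), tilt = quat_x(-70 * pi / 180),
                   yaw = 25, f_n = 50, zeta = 0.18, gain = 1.2, rc = 0.05)
  )
  out <- lapply(names(base), function(p) {
    b <- base[[p]]
    yaw <- b$yaw
    if (!is.null(yaw_deg) && p %in% names(yaw_deg)) yaw <- yaw_deg[[p]]
    mounting_spec(
      position = p,
      r = b$r,
      rotation = quat_mul(b$tilt, quat_z(yaw * pi / 180)),
      f_n = b$f_n, zeta = b$zeta,
      impact_gain = b$gain, rollover_coupling = b$rc
    )
  })
  names(out) <- names(base)
  out
}

#' Degenerate mounting table (rigid ideal sensors)
#'
#' All six positions with zero lever arm, identity rotation and no attachment
#' dynamics. Used to check rigid-motion conservation: all sensors then record
#' identical signals.
#'
#' @return Named list of [mounting_spec()] objects.
#' @export
rigid_mounting_specs <- function() {
  out <- lapply(SENSOR_POSITIONS, function(p) {
    mounting_spec(p, r = c(0, 0, 0), rotation = quat_identity(),
                  f_n = 120, zeta = 0.7, impact_gain = 0,
                  rollover_coupling = 0)
  })
  names(out) <- SENSOR_POSITIONS
  out
}

#' Analysis pipeline configuration
#'
#' All tunable parameters of the analysis modules with their defaults. Values
#' are documented with units; see the methods vignette for rationale.
#'
#' @param static_window_samples Length of the static window used for gravity
#'   alignment, samples (paper value 500 at 204.8 Hz).
#' @param static_var_threshold Per-axis accelerometer variance threshold
#'   declaring a window static, (m/s^2)^2.
#' @param yaw_omega_threshold_dps Minimum planar angular-velocity magnitude for
#'   a sample to enter the yaw-alignment median, deg/s.
#' @param snap_window_ms Full width of the window used to snap labeled stride
#'   borders to the nearest ML-gyro minimum, ms.
#' @param ic_search_fraction Fraction of the stride after which the initial
#'   contact search begins if no swing maximum is found, dimensionless.
#' @param tvmin_window_samples Width of the least-movement energy window,
#'   samples (8 samples = 40 ms at 204.8 Hz).
#' @param sigmoid_steepness Steepness `c` of the logistic forward/backward
#'   dedrifting weight.
#' @param gravity_mps2 Gravity magnitude removed before integration, m/s^2.
#' @param init_window_samples Width of the initial-orientation window centred
#'   on t_vmin, samples.
#' @param straightness_threshold_m Maximum allowed |heel - toe| reference
#'   length difference for a straight stride, metres.
#' @param marker_max_gap_ms Longest marker gap that is linearly interpolated,
#'   ms.
#' @param psd_detrend Detrend Welch segments before transforming.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(static_window_samples = 500L,
                            static_var_threshold = 0.01,
                            yaw_omega_threshold_dps = 150,
                            snap_window_ms = 50,
                            ic_search_fraction = 0.35,
                            tvmin_window_samples = 8L,
                            sigmoid_steepness = 10,
                            gravity_mps2 = GRAVITY_MPS2,
                            init_window_samples = 8L,
                            straightness_threshold_m = 0.01,
                            marker_max_gap_ms = 80,
                            psd_detrend = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}
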