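# Ground-truth foot kinematics generator.
#
# A gait cycle is built from C^3-smooth polynomial segments so that linear
# acceleration, angular velocity and angular acceleration all have exact
# closed forms (required by the lever-arm kinematics oracle) and so that
# velocity and angular velocity are *exactly* zero during every foot-flat
# phase (the zero-velocity assumption the downstream integrator relies on).
#
# Cycle phase layout (fractions of one cycle, labeled borders at 0.09):
#   [0.00, 0.18)  rollover: pitch ramps toe-down (heel rise / push-off)
#   [0.10, 0.62)  translation + step-height bump (+ heading change if turning)
#   [0.18, 0.55)  swing: pitch sweeps to the heel-strike attitude
#   [0.55, 0.64)  landing: foot flattens after initial contact
#   [0.64, 1.00)  foot flat: all rates exactly zero
#
# Foot frame: x forward, y left, z up (right-handed). Toe-down pitch is a
# positive rotation about +y, so the clinically conventional medial-lateral
# gyro signal (swing-positive, troughs at TC/IC) is the *negated* y gyro; see
# ml_gyro().

# Septic smoothstep: s(0)=0, s(1)=1, first three derivatives vanish at both
# ends, keeping acceleration C^1 across segment joins.
s7 <- function(u) 35 * u^4 - 84 * u^5 + 70 * u^6 - 20 * u^7
s7_d <- function(u) 140 * u^3 * (1 - u)^3
s7_dd <- function(u) 420 * u^2 * (1 - u)^2 * (1 - 2 * u)

# Smooth ramp y0 -> y0+dy over cycle fraction [u0, u1]; returns value and the
# first two derivatives with respect to u.
ramp_profile <- function(u, u0, u1, dy) {
  v <- (u - u0) / (u1 - u0)
  inside <- v > 0 & v < 1
  val <- ifelse(v <= 0, 0, ifelse(v >= 1, dy, dy * s7(pmin(pmax(v, 0), 1))))
  d <- ifelse(inside, dy * s7_d(v) / (u1 - u0), 0)
  dd <- ifelse(inside, dy * s7_dd(v) / (u1 - u0)^2, 0)
  list(val = val, d = d, dd = dd)
}

# Smooth bump 0 -> h -> 0 over [u0, u1].
bump_profile <- function(u, u0, u1, h) {
  up <- ramp_profile(u, u0, (u0 + u1) / 2, h)
  down <- ramp_profile(u, (u0 + u1) / 2, u1, -h)
  list(val = up$val + down$val, d = up$d + down$d, dd = up$dd + down$dd)
}

CYCLE_PHASES <- list(
  border = 0.09,       # labeled stride border: ML-gyro trough of the rollover
  rollover = c(0.00, 0.18),
  translate = c(0.10, 0.62),
  swing = c(0.18, 0.55),
  landing = c(0.55, 0.64),
  flat = c(0.64, 1.00),
  ic = 0.595,          # landing mid-point: initial-contact impact instant
  flat_anchor = 0.82   # reference anchor inside the foot-flat phase
)

PITCH_PUSHOFF_DEG <- 28  # toe-down pitch at terminal contact
PITCH_LANDING_DEG <- 18  # toe-up pitch at heel strike
# Heel-strike impact magnitude scales with the kinetic energy of the landing
# foot, i.e. with the square of the average stride speed.
IMPACT_SCALE <- 34       # (m/s^2) per (m/s)^2
# weight-transfer micro-excitations during stance: cycle fractions and their
# magnitude relative to the initial-contact impact
STANCE_MICRO_U <- c(0.70, 0.78, 0.86, 0.94)
STANCE_MICRO_REL <- 0.04

cumtrapz_mat <- function(y, dt) {
  n <- nrow(y)
  if (n < 2) return(y * 0)
  inc <- (y[-1, , drop = FALSE] + y[-n, , drop = FALSE]) / 2 * dt
  rbind(0, apply(inc, 2, cumsum))
}

#' Generate ground-truth foot kinematics for one walking bout
#'
#' Builds a smooth rigid-body pose series (position, orientation, and their
#' exact analytic rates) for `n_strides` labeled strides plus one extra gait
#' cycle, preceded by a standing lead-in. During every foot-flat phase the
#' linear and angular velocity are exactly zero. Turning strides change the
#' heading by `turn_angle_deg` (alternating direction).
#'
#' @param config A [gait_config()].
#' @param fs_internal Internal simulation rate, Hz; must be an integer
#'   multiple of any IMU rate sampled from it later.
#' @param lead_in_s,lead_out_s Standing time before/after the bout, seconds.
#' @param psi0 Initial heading, rad.
#' @param origin Initial foot-origin position, metres.
#' @return A list of class `pose_series` with per-sample matrices `pos`,
#'   `quat`, `vel`, `acc` (world linear acceleration), `omega_world`,
#'   `omega_body` (rad/s), `alpha_world` (rad/s^2); per-stride ground truth in
#'   `$strides` (`true_length_m` between labeled borders, `vmin_true_length_m`
#'   between consecutive foot-flat anchors, straightness flags); foot-flat
#'   intervals in `$flat`; impact events in `$impacts`.
#' @export
generate_foot_pose <- function(config,
                               fs_internal = 2048,
                               lead_in_s = 3,
                               lead_out_s = 1.5,
                               psi0 = 0,
                               origin = c(0, 0, 0)) {
  stopifnot(inherits(config, "gait_config"))
  with_seed(config$seed, {
    n_cycles <- config$n_strides + 1L
    jit <- config$jitter_frac
    len_k <- config$stride_length_mean *
      pmax(0.5, 1 + stats::rnorm(n_cycles, 0, jit))
    dur_k <- config$stride_time_mean *
      pmax(0.5, 1 + stats::rnorm(n_cycles, 0, jit))
    n_turn <- round(config$turn_fraction * n_cycles)
    turn_idx <- if (n_turn >= n_cycles) {
      seq_len(n_cycles)
    } else if (n_turn > 0) {
      sort(sample(n_cycles, n_turn))
    } else integer(0)
    turn_angle <- numeric(n_cycles)
    if (length(turn_idx)) {
      signs <- rep_len(c(1, -1), length(turn_idx))
      turn_angle[turn_idx] <- signs * config$turn_angle_deg * pi / 180
    }

    dt <- 1 / fs_internal
    n_k <- pmax(64L, as.integer(round(dur_k * fs_internal)))
    n_lead <- as.integer(round(lead_in_s * fs_internal))
    n_out <- as.integer(round(lead_out_s * fs_internal))
    n_total <- n_lead + sum(n_k) + n_out

    theta <- theta_t <- theta_tt <- numeric(n_total)
    psi <- psi_t <- psi_tt <- numeric(n_total)
    dsp <- dsp_t <- dsp_tt <- numeric(n_total)
    zb <- zb_t <- zb_tt <- numeric(n_total)

    psi[seq_len(n_lead)] <- psi0
    ph <- CYCLE_PHASES
    th1 <- PITCH_PUSHOFF_DEG * pi / 180
    th2 <- PITCH_LANDING_DEG * pi / 180

    cyc_start <- n_lead + c(0L, cumsum(n_k))[seq_len(n_cycles)] + 1L
    psi_start <- psi0
    d_prev <- 0
    for (k in seq_len(n_cycles)) {
      idx <- cyc_start[k]:(cyc_start[k] + n_k[k] - 1L)
      u <- (seq_along(idx) - 1) / n_k[k]
      Tk <- n_k[k] * dt
      p1 <- ramp_profile(u, ph$rollover[1], ph$rollover[2], th1)
      p2 <- ramp_profile(u, ph$swing[1], ph$swing[2], -(th1 + th2))
      p3 <- ramp_profile(u, ph$landing[1], ph$landing[2], th2)
      theta[idx] <- p1$val + p2$val + p3$val
      theta_t[idx] <- (p1$d + p2$d + p3$d) / Tk
      theta_tt[idx] <- (p1$dd + p2$dd + p3$dd) / Tk^2

      tr <- ramp_profile(u, ph$translate[1], ph$translate[2], len_k[k])
      dsp[idx] <- d_prev + tr$val
      dsp_t[idx] <- tr$d / Tk
      dsp_tt[idx] <- tr$dd / Tk^2
      d_prev <- d_prev + len_k[k]

      bz <- bump_profile(u, ph$translate[1], ph$translate[2], config$step_height)
      zb[idx] <- bz$val
      zb_t[idx] <- bz$d / Tk
      zb_tt[idx] <- bz$dd / Tk^2

      yw <- ramp_profile(u, ph$translate[1], ph$translate[2], turn_angle[k])
      psi[idx] <- psi_start + yw$val
      psi_t[idx] <- yw$d / Tk
      psi_tt[idx] <- yw$dd / Tk^2
      psi_start <- psi_start + turn_angle[k]
    }
    if (n_out > 0) {
      tail_idx <- (n_total - n_out + 1L):n_total
      psi[tail_idx] <- psi_start
      dsp[tail_idx] <- d_prev
    }

    cp <- cos(psi); sp <- sin(psi)

    vel <- cbind(dsp_t * cp, dsp_t * sp, zb_t)
    acc <- cbind(dsp_tt * cp - dsp_t * psi_t * sp,
                 dsp_tt * sp + dsp_t * psi_t * cp,
                 zb_tt)
    # pitch axis is the body y-axis Rz(psi) (0,1,0) = (-sin psi, cos psi, 0)
    omega_world <- cbind(-theta_t * sp, theta_t * cp, psi_t)
    # d/dt [Rz(psi) y_hat] = psi_t * (z x Rz(psi) y_hat) = psi_t*(-cos,-sin,0)
    alpha_world <- cbind(-theta_tt * sp - theta_t * psi_t * cp,
                         theta_tt * cp - theta_t * psi_t * sp,
                         psi_tt)

    dimnames(vel) <- dimnames(acc) <- NULL
    dimnames(omega_world) <- dimnames(alpha_world) <- NULL

    qz <- cbind(cos(psi / 2), 0, 0, sin(psi / 2))
    qy <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)
    quat <- quat_mul(qz, qy)
    omega_body <- quat_rotate(quat_conj(quat), omega_world)

    pos <- cumtrapz_mat(vel, dt)
    pos <- sweep(pos, 2, -as.numeric(origin))

    # ground-truth tables -------------------------------------------------
    border <- as.integer(cyc_start + round(ph$border * n_k))
    flat_anchor <- as.integer(cyc_start + round(ph$flat_anchor * n_k))
    flat_start <- as.integer(cyc_start + ceiling(ph$flat[1] * n_k))
    flat_end <- as.integer(cyc_start + n_k - 1L)

    ns <- config$n_strides
    planar <- function(i, j) {
      sqrt(sum((pos[j, 1:2] - pos[i, 1:2])^2))
    }
    strides <- data.frame(
      stride_id = seq_len(ns),
      start = border[seq_len(ns)],
      end = border[seq_len(ns) + 1L],
      turn_angle_rad = turn_angle[seq_len(ns)],
      straight = abs(turn_angle[seq_len(ns)]) < 1e-12,
      true_length_m = vapply(seq_len(ns), function(j) {
        planar(border[j], border[j + 1L])
      }, numeric(1)),
      vmin_true_length_m = vapply(seq_len(ns), function(j) {
        planar(flat_anchor[j], flat_anchor[j + 1L])
      }, numeric(1)),
      vmin_straight = abs(turn_angle[pmin(seq_len(ns) + 1L, n_cycles)]) < 1e-12,
      speed_category = config$speed_category,
      stringsAsFactors = FALSE
    )
    flat <- data.frame(cycle = seq_len(n_cycles),
                       start = flat_start, end = flat_end)
    ic_mag <- IMPACT_SCALE * (len_k / dur_k)^2
    impacts <- data.frame(
      cycle = seq_len(n_cycles),
      sample = as.integer(cyc_start + round(ph$ic * n_k)),
      magnitude = ic_mag,
      type = "ic",
      stringsAsFactors = FALSE
    )
    for (uu in STANCE_MICRO_U) {
      impacts <- rbind(impacts, data.frame(
        cycle = seq_len(n_cycles),
        sample = as.integer(cyc_start + round(uu * n_k)),
        magnitude = STANCE_MICRO_REL * ic_mag,
        type = "stance",
        stringsAsFactors = FALSE
      ))
    }
    impacts <- impacts[order(impacts$sample), ]
    row.names(impacts) <- NULL

    structure(list(
      fs = fs_internal,
      n = n_total,
      pos = pos, quat = quat, vel = vel, acc = acc,
      omega_world = omega_world, omega_body = omega_body,
      alpha_world = alpha_world,
      strides = strides, flat = flat, impacts = impacts,
      lead_in_n = n_lead,
      psi_end = psi_start,
      origin_end = pos[n_total, ],
      config = config
    ), class = "pose_series")
  })
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf(
    "<pose_series> %d samples @ %g Hz, %d strides (%d turning), %.2f s\n",
    x$n, x$fs, nrow(x$strides), sum(!x$strides$straight), x$n / x$fs
  ))
  invisible(x)
}
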