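# Shared fixtures: small synthetic sessions built once per test run.

small_protocol <- function(n = 8L, speed = "normal", turn_fraction = 0.1,
                           turn_angle = 60, test_id = NULL) {
  speeds <- list(slow = c(1.05, 1.25), normal = c(1.30, 1.10),
                 fast = c(1.55, 0.95))
  data.frame(
    test_id = test_id %||% paste0("2x20_", speed),
    speed_category = speed,
    n_strides = as.integer(n),
    turn_fraction = turn_fraction,
    turn_angle_deg = turn_angle,
    stride_length_m = speeds[[speed]][1],
    stride_time_s = speeds[[speed]][2],
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_tempdir <- function() {
  d <- tempfile("session-")
  dir.create(d)
  d
}

# Memoized fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Noise-free session with default (non-trivial) mounts and no attachment
# dynamics: the rigid-motion reference condition.
rigid_session <- function(seed = 7, n = 8L, turn_fraction = 0.1,
                          turn_angle = 60) {
  assemble_session(small_protocol(n = n, turn_fraction = turn_fraction,
                                  turn_angle = turn_angle),
                   mounts = default_mounting_specs(), seed = seed,
                   feet = "left", attachment = FALSE,
                   noise_acc_sd = 0, noise_gyr_sd = 0,
                   marker_gap_rate_per_s = 0, mocap_offset_jitter_s = 0)
}

# Default-condition session (attachment dynamics + noise + marker gaps).
default_session <- function(seed = 7, n = 8L) {
  assemble_session(small_protocol(n = n), seed = seed, feet = "left")
}

# A bare static stream: gravity along an arbitrary sensor axis plus noise.
static_stream <- function(n = 1200, grav = c(0, 0, 9.81), noise = 0,
                          position = "cavity", seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    acc <- matrix(rep(grav, each = n), ncol = 3) +
      matrix(rnorm(3 * n, 0, noise), ncol = 3)
    gyr <- matrix(rnorm(3 * n, 0, noise), ncol = 3)
    imu_stream(acc, gyr, fs = 204.8, position = position)
  })
}
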