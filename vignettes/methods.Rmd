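---
title: "Stride length from foot-mounted IMUs: models, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride length from foot-mounted IMUs: models, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footimu)
```

## The problem

Spatial gait parameters — above all stride length — are routinely estimated
by double-integrating the signal of a single foot-mounted inertial
measurement unit (IMU). Where exactly the sensor sits on the shoe, and how
firmly it is attached, is far from standardized: commercial and research
systems embed sensors in the midsole or an instrumented insole, clip them to
the instep, or strap them to the heel, lateral or medial collar. All of
these points travel the same ground-plane distance over one straight stride,
so in an ideal rigid world the estimated stride length would be identical.
In practice the *frequency response of the attachment* modulates the impact
transients of each heel strike differently at each position, and those
modulations interact with zero-velocity assumptions and with the finite
sampling rate of the sensor to produce position-dependent integration
errors.

`footimu` implements the complete analysis pipeline for such multi-position
comparisons, together with a physics-based synthetic data generator that
stands in for a motion-capture-referenced multi-sensor recording session.
Everything is deterministic given a seed, so every figure of merit the
package reports can be recomputed from scratch.

## The synthetic session

### Rigid foot motion

`generate_foot_pose()` builds one continuous bout of walking as a rigid-body
pose series at an internal rate of 2048 Hz (10x the IMU rate). A gait cycle
is composed of septic (C^3) smoothstep segments: rollover (toe-down pitch
ramp while the heel lifts), swing (translation by the stride length, a
step-height bump, and the pitch sweep to the heel-strike attitude), landing
(foot flattening after initial contact), and a foot-flat phase in which
linear and angular velocity are *exactly* zero — the zero-velocity
assumption downstream is therefore exactly true of the simulated world,
which makes deviations attributable to the measurement chain rather than to
the kinematics. Closed-form first and second derivatives of every profile
give exact linear acceleration, angular velocity and angular acceleration,
which the lever-arm model below requires.

Stride-to-stride variability is Gaussian on length and duration (3%
relative by default — about what healthy steady-state walking shows).
Turning strides rotate the heading by a configurable angle via the same
smooth profile; directions alternate so a bout has balanced left and right
turns, as a shuttle-walk or figure-eight protocol produces. The default
`session_protocol()` emulates scaled-down 4x10 m and 2x20 m walk tests at
slow/normal/fast self-selected speeds (stride length 1.05/1.30/1.55 m,
stride time 1.25/1.10/0.95 s) plus a longer figure-eight-style walk —
about 170 labeled strides per foot, chosen so a both-feet session yields
well over 300 analysable strides while a full simulation + analysis run
stays around two minutes on one core.

### Sensor signals

`ideal_point_kinematics()` evaluates the exact specific force and angular
velocity at a mounted point with lever arm r:

    a_p = a_o + alpha x r + omega x (omega x r)

in world coordinates, with gravity g = (0, 0, -9.81) m/s^2 subtracted and
the result rotated into the sensor frame. Two remarks on conventions. First,
the centripetal term is written here as `omega x (omega x r)`, which points
*towards* the rotation axis; the equivalent form `omega x (r x omega)` that
sometimes appears in the literature has the opposite (centrifugal) sign —
the package follows the physically consistent centripetal convention, which
is also what a finite-difference differentiation of the mounted point's
trajectory reproduces. For a planar rotation at 8.5 rad/s (about 500 deg/s,
a typical peak foot angular velocity) and a 0.1 m lever arm this term has
magnitude 8.5^2 * 0.1 = 7.225 m/s^2 — a substantial, position-dependent
signal component. Second, the angular-acceleration (Euler) term
`alpha x r` is included: without it the simulated accelerometer would be
inconsistent with the simulated trajectory, and the package's oracle test
(4th-order finite differences of the mounted point's world path against the
analytic formula) would fail.

### Attachment dynamics

Each mounting is modelled as a damped linear oscillator (natural frequency
`f_n`, damping ratio `zeta`) excited by the heel-strike impact and by small
weight-transfer micro-excitations during stance (4% of the impact
magnitude). The impact magnitude scales with the kinetic energy of the
landing foot, i.e. with the square of the average stride speed. Crucially,
the transient added to the accelerometer is the *second derivative of a
decaying displacement* `x(t) = exp(-zeta w_n t) sin(w_d t)` (and the
gyroscope sees the first derivative of the analogous angular wobble): the
sensor physically returns to rest, so the transient integrates to exactly
zero net displacement and orientation. With infinitely fine sampling the
stride length would be untouched; the integration errors that the pipeline
then measures arise solely from sampling a 40-120 Hz ringing at 204.8 Hz —
point-sampled without an anti-alias filter, exactly as a mechanical input
beyond the sensor bandwidth reaches a real IMU front end. This reproduces,
by construction, the hypothesized error pathway of high-frequency signal
content near and beyond the Nyquist frequency.

The default mounting table encodes the qualitative attachment physics:
embedded positions (cavity, insole) are stiff and nearly critically damped
(`f_n` = 120 Hz, `zeta` = 0.7), the instep clip is intermediate but coupled
at 0.8 to the delayed rollover deformation of the toe box (modelled as
blending with a 25 ms delayed copy of the signal), and the collar clips
(heel, lateral, medial) are underdamped (`f_n` = 45-55 Hz, `zeta` =
0.12-0.18) with several-fold larger impact gains. The numerical gains were
fixed once so that the simulated sessions reproduce the qualitative
orderings the method is meant to expose — embedded positions beat collar
positions on mid-stance residual energy and stride-length error, and errors
grow with gait speed — and the package's tests assert *only those
orderings*, never absolute error magnitudes, which in this simulator are
design choices rather than measurements.

### Markers and clocks

Heel (CAL) and shoe-tip (TOE) markers are rigidly attached points sampled at
100 Hz, with tracking gaps generated as a Poisson process of gap starts and
geometric gap lengths, so runs both below and above the 80 ms interpolation
limit occur. The capture clock is offset from the IMU clock by a uniform
draw within +/-10 ms (the synchronization accuracy of a hardware-coupled
system); the offset is recorded in the session metadata and honoured by the
reference module, mirroring a synchronized two-system setup.

What the generator deliberately does *not* model: musculoskeletal detail
(joint kinematics, ground-reaction forces), soft-tissue artefacts, sensor
calibration errors (scale/bias/axis misalignment), nonlinear attachment
response, or ground-contact constraints for the marker points. Passing tests
on this generator therefore demonstrates the *pipeline's* correctness and
its sensitivity to attachment dynamics — not that real shoes have the
specific frequency responses of the default table.

## The analysis pipeline

### Alignment

Sensors are aligned per foot in two steps. A sliding search
(`find_static_window()`) finds the first 500-sample window (about 2.4 s) in
which every accelerometer axis of every sensor has variance below 0.01; the
threshold is interpreted as a variance in (m/s^2)^2, matching the printed
numeral, and is configurable. `gravity_align()` rotates each sensor by the
shortest rotation taking its median static acceleration onto +z. The
remaining degree of freedom — rotation about z — is fixed against the
cavity sensor (whose orientation is mechanically defined by its cavity):
for every sample where both sensors' planar angular-velocity magnitude
reaches 150 deg/s, the *signed* angle `atan2(cross_z, dot)` between the two
planar vectors is computed, and the median over retained samples is the yaw
correction. The signed form is a deliberate choice: the unsigned
`atan2(|cross|, dot)` describes the same geometry but cannot decide the
direction of the correcting rotation. The median is taken over signed
angles for the same reason. On rigid noise-free data this recovers mounting
yaws exactly; with default noise, to well under a degree.

### Events and stride conventions

Labeled strides run from one pre-terminal-contact minimum of the
medial-lateral gyro to the next; in the aligned x-forward/y-left/z-up frame
the clinically conventional ML signal (swing-positive) is the negated
y-gyro, exposed as `ml_gyro()`. Ground-truth borders (standing in for a
human labeller) are snapped to the exact sample of the signal minimum in a
50 ms window, which keeps shared borders shared. Within each labeled stride,
`detect_events()` finds: TC as the first negative-to-positive ML zero
crossing; IC as the most prominent negative ML peak after the swing
maximum, refined to the adjacent minimum of the superior-inferior
acceleration; and t_vmin as the centre of the 8-sample (40 ms) window of
minimal gyroscope-norm energy between IC and the stride end. These concrete
operators are a faithful simplification of the classical gyro-based event
family (heel strike / toe off / mid stance); all search fractions are
config keys. Events are rejected when out of order or when IC falls after
60% of the cycle, and v_min strides (t_vmin to t_vmin of the adjacent
stride) exist only across adjacent valid pairs — each unbroken gait
sequence loses exactly one stride.

A subtlety worth stating: the v_min stride inheriting `stride_id` j spans
the *following* cycle's swing, so the generator records both the
labeled-border truth (`true_length_m`) and the anchor-to-anchor truth for
the v_min stride (`vmin_true_length_m`, with `vmin_straight`); comparisons
of integrated lengths use the latter.

### Double integration

`stride_trajectory()` integrates one v_min stride: initial tilt from the
median acceleration in an 8-sample window at t_vmin (assumed pure gravity),
heading chosen so the sensor x-axis faces forward; strapdown quaternion
integration of the gyro (one exponential step per sample, using the mean of
the bounding samples — second-order accurate and exact for constant rates);
rotation of the specific force to the world frame and subtraction of
9.81 m/s^2; forward and backward cumulative trapezoid velocity integrals
blended with a logistic weight `sigma(c (t - T/2)/T)`, `c = 10`; and
trapezoidal position integration. The logistic weight is normalized to hit
exactly 0 and 1 at the stride ends so both endpoint velocities are exactly
zero (the raw logistic leaves ~0.7% leakage at `c = 10`). Stride length is
the planar Euclidean distance between the first and last position — which
makes it invariant under any world z-rotation, so the arbitrary heading
convention cannot affect it.

### Reference, selection, statistics

Marker gaps up to 80 ms are filled linearly (`zoo::na.approx`); longer gaps
stay missing. The reference length is the planar displacement of the heel
marker between the v_min bounds, linearly interpolated on the 100 Hz grid
through the recorded clock offset — each sensor gets its own reference at
its own bounds, so event-timing differences between sensors do not bias the
comparison. The toe marker provides the straightness check only: if heel
and toe lengths differ by more than 1 cm for *any* sensor of a foot, or any
sensor's events failed, or markers are unusable at a bound, the stride id
is removed for all sensors. Error statistics (per position and category:
slow/normal/fast over the straight tests, their union, the continuous walk,
and all strides) are the signed error (IMU minus heel reference; positive =
overestimation), MAE, type-7 interquartile range, Tukey outliers, and
extreme outliers beyond 30 cm. Quantiles are type 7 (R's default linear
interpolation) — a documented convention, as different quantile rules move
IQR-based counts slightly.

### Raw-data features

Per labeled stride and sensor pair, the mean 3D difference
`(1/N) sum ||x_i - x_j||` and the mean norm difference
`(1/N) sum (||x_i|| - ||x_j||)` separate constant offsets from zero-mean
oscillation (the former bounds the absolute value of the latter — asserted
exactly in the tests). Per v_min stride: residual energy E_vmin (sum of
squared gyro norms in the 40 ms t_vmin window, deg^2/s^2), peak
acceleration norm, and Welch band powers of the accelerometer and gyro
norms — Hann window of 64 samples, 50% overlap, segments zero-padded to
128 points, detrending off by default; band means over (0, 20] Hz
(excluding DC) and (80, 102.4) Hz. Frequency-bin membership uses half-open
intervals so the 80 Hz and Nyquist bins fall outside the high band. The
cross-sensor standard-deviation profile (n-1 denominator) is interpolated
to 200 samples per stride and averaged. Feature-error association uses
Spearman rank correlation (the claims it supports are rank-order claims;
Pearson is reported alongside) at stride, per-test-median and
per-sensor-median granularity.

## Numerical and design choices

- Internal rate 2048 Hz with point-sampling (no anti-alias filter) —
  deliberately preserving under-sampling as an error pathway.
- World frame z-up, x = initial walking direction; gravity 9.81 m/s^2.
- Stride intervals are stored 1-based half-open `[start, end)`; adjacent
  strides share `end == start`.
- The damped-oscillator transient uses the displacement-consistent kernel
  (see above); its closed form is verified against the oscillator ODE to
  machine precision in the tests.
- Sigmoid steepness, window lengths, thresholds and band edges are all
  `pipeline_config()` keys with the defaults given above.
- Degenerate inputs fail loudly with structured messages: no static region,
  insufficient dynamic content for yaw, gravity vectors below 1 m/s^2,
  strides shorter than one Welch segment, marker bounds in unfilled gaps.

## Worked example

```{r example, eval = FALSE}
session <- simulate_session(seed = 1)
result <- analyze_session(session)
subset(result$summary, category == "all",
       c(position, n, mean_error_m, mae_m, iqr_m))
```

On the default protocol this reports mean errors within a few millimetres
for every position, while the MAE separates the embedded sensors (a few
millimetres) from the collar-mounted ones (centimetres) — the package's
central qualitative result, recomputed end to end by
`scripts/acceptance.R` and asserted (as orderings) by the test suite.

## Known limitations

- The simulator's attachment model is linear; real attachments are
  amplitude-dependent and the reported magnitudes therefore transfer only
  as orderings.
- Event detection is tuned to the synthetic signal morphology; real
  pathological gait would need the search fractions revisited.
- The alignment assumes a rigid foot during high-angular-velocity phases;
  strong shoe deformation violates it (as it does for any
  angular-velocity-based alignment).
- Only CSV/JSON session I/O is provided; binary capture formats must be
  converted upstream.
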