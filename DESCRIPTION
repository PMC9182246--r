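Package: footimu
Title: Stride-Length Estimation and Sensor-Position Analysis for Foot-Mounted IMUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-position foot-mounted inertial
    measurement unit (IMU) recordings of regular walking. Implements the full
    stride-length pipeline: gravity and yaw sensor-to-sensor alignment from
    angular velocity, gait-event detection (terminal contact, initial contact,
    mid-stance least-movement point), zero-velocity-anchored strapdown double
    integration with sigmoidal forward-backward dedrifting, marker-based
    reference stride lengths with straightness filtering, raw-signal comparison
    features (3D and norm differences, residual mid-stance energy, peak
    acceleration, Welch band powers), and descriptive error statistics. A
    rigid-body gait simulator with per-position mounting lever arms and
    damped-oscillator attachment dynamics generates synthetic six-sensor
    sessions with motion-capture-style marker references for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
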