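Package: vorx
Title: Objective Compliance Scoring for Gaze-Stabilization (VORx1) Exercises
Version: 0.1.0
Authors@R:
    person("vorx", "developers", email = "vorx@example.org", role = c("aut", "cre"))
Description: Tools for objective monitoring of metronome-paced
    vestibulo-ocular reflex (VORx1) gaze-stabilization exercises from
    head-angle time series. Provides time-aware smoothing, prominence- and
    threshold-filtered peak/valley detection, interval-to-bpm conversion
    and speed-compliance classification, gaze-compliance scoring, reward
    computation, head-pose estimation from 2D facial landmarks with
    rotation-error metrics (per-axis Euler error, pooled MSE, quaternion
    geodesic), a camera-versus-IMU validation harness (cross-correlation
    alignment, DC compensation, peak matching, interpeak and frequency
    error metrics, confusion-matrix classification metrics), and a
    synthetic-signal generator emulating metronome-paced head motion with
    tempo drift, frame-time jitter and sensor noise. Includes a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
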