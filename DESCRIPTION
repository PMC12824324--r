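Package: chronobeh
Title: Timing and Kinematic Analysis of Operant and Locomotor Interval Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing interval-timing behaviour in rodents from raw
    effector traces. Converts continuous bilateral lever-position recordings
    into press events, coordinated bilateral attempts and reward-resolved
    trials for fixed-interval (peak-interval) and two-interval hold-production
    schedules; computes the standard timing and kinematic metrics (overshoot
    and overshoot fraction, interlimb correlation, bilateral movement onset
    variability, movement speed, trajectory variability, efficiency, peri-reward
    histograms with area-under-curve and peak-interval estimates, and robustness
    splits); segments and scores a 7 s front-back-front treadmill sequence
    (phase durations, peak acceleration speed, stereotypy, compensatory
    strategy classification); and provides a rank-based statistical stack
    implemented from first principles (Kruskal-Wallis, Scheirer-Ray-Hare
    two-way rank test, rank-based LSD post hoc comparisons, Mann-Whitney,
    Kolmogorov-Smirnov normality) with mid-rank tie handling. A seeded
    synthetic-session generator with separately controllable clock-distortion
    and motor-slowing parameters lets the perception/production dissociation
    logic be exercised and calibrated without access to animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
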