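Package: chemogas
Title: Simulation and Signal Processing for Pressure-Based Biogas
    Monitoring in Multiplexed Anaerobic Chemostats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for laboratory-scale anaerobic chemostats that measure
    biogas production as headspace pressure with hysteresis degassing
    (pump-out triggered at an upper pressure threshold, stopped at a lower
    one). Provides a reactor digital twin - ideal-gas headspace physics, a
    hysteresis degassing controller, pulse feed/waste schedulers, a
    quantizing noisy sensor model, dissolved-gas re-equilibration, and
    injectable sampling/leak artifacts - together with the processing
    pipeline that turns raw sawtooth pressure logs into cumulative biogas
    volume at standard conditions (293.15 K, 1.013 bar): degassing-event
    detection and stitching, rate-of-change spike rejection, ideal-gas
    normalization, and least-squares production-rate estimation. Also
    includes linear pump/sensor calibration, weekly COD-normalized
    performance aggregation, and nonparametric group comparison
    (tie-corrected Kruskal-Wallis with Dunn post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
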