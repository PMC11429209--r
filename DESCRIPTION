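Package: monofil
Title: Mechanics and Metrological Verification of Semmes-Weinstein
    Monofilaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analytical mechanics of the 10 gf Semmes-Weinstein
    monofilament used in diabetic-foot screening: Euler critical buckling
    force with clamped-pinned and clamped-sliding end conditions,
    self-weight tip deflection of the horizontal filament, linear
    temperature and humidity corrections to the Young's modulus, and
    inverse estimation of the modulus from a measured buckling force.
    Includes parameter sweeps (critical-force grids over length and
    diameter, manufacturing-tolerance deflection tables), feature
    extraction from force-displacement compression curves, fatigue-cycle
    decay analysis, verification verdicts against the nominal 10 gf
    rating, Bland-Altman instrument-agreement statistics, synthetic
    generators emulating a motorised calibration bench, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
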