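Package: reachkin
Title: Minimum-Jerk Kinematic Analysis of Point-to-Point Cursor Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing movement quality in human-machine-interface
    target-acquisition tasks. Implements the closed-form minimum-jerk
    trajectory model for point-to-point movements, trial segmentation and the
    standard cursor kinematic metrics (time to target, peak velocity, path
    efficiency, position error against the minimum-jerk reference), the
    variance-comparison statistical battery used to contrast control
    modalities (two-way ANOVA, variance F-tests, Brown-Forsythe tests,
    distance regressions), and a calibrated synthetic trajectory generator
    that emulates manipulandum-driven and muscle-signal-driven (sonomyography)
    cursor control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), car, optparse
Config/testthat/edition: 3
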