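Package: zebtrack
Title: Behavioral Tracking and Visual Feedback Computation for Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline re-implementation of a high-resolution larval zebrafish
    behavioral tracking and behavior-driven stimulus feedback pipeline.
    Provides running-extremum background estimation, centroid and eye-region
    extraction, iterative contrast-based tail-point fitting, tail curvature
    and online bout / tail-beat-frequency detection, multi-animal identity
    assignment with contact handling, one- and two-dimensional closed-loop
    optomotor feedback equations, virtual open-loop stimulus geometry
    (looming, optomotor gratings, prey arcs), and hierarchical clustering of
    swim-bout kinematics. A synthetic-fixture module renders ground-truthed
    fish images, swim traces, and prey trajectories so the whole stack is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
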