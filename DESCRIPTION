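Package: cmjkit
Title: Automated Temporal Analysis of Countermovement Jumps from Planar
    Landmark Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automated temporal analysis of countermovement
    vertical jumps (CMJ) from planar (sagittal X-Z) trajectories of 14
    body landmarks, as produced by marker-based motion capture or
    markerless pose estimation. Computes whole-body centre of mass with a
    four-segment Dempster model, detects the nine canonical jump events
    on the CoM and toe traces by rule-based thresholding and extrema,
    extracts 21 kinematic variables per trial (phase durations, depths,
    velocities, joint angles, three jump-height estimators), and provides
    the method-agreement statistics battery used to validate such systems
    (Bland-Altman bias and limits of agreement with confidence intervals,
    RMSE, Pearson r, ICC(3,1), two-way repeated-measures ANOVA, Cohen's d
    standardised by the harmonic mean of the group SDs). A synthetic CMJ
    trajectory generator with analytically known event times and a
    two-method measurement-error model makes every stage testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
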