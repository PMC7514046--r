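Package: miniscrewsim
Title: Simulated Interradicular Miniscrew Placement and Miniscrew-Root
    Distance Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Virtual placement of a tapered orthodontic miniscrew (1.5 mm x
    6 mm) at posterior interradicular sites of parametric three-dimensional
    dental segments, with measurement of the miniscrew-root distance
    available for molar distalization by 0.1-mm axial slicing under a
    direction-constrained shortest-distance rule. Includes a seeded
    generator of synthetic segment anatomy and whole cohorts stratified by
    vertical facial type, an occlusal coordinate frame built from cusp
    landmarks, contact/noncontact outcome classification, ordinal (0-6)
    categorization of distances, cohort summary tables, and a cumulative
    logit model with cluster-robust (generalized estimating equation style)
    inference, plus voxel-domain counterparts of the analytic measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
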