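Package: sinusect
Title: 3D Morphometry of Ethmoid Sinus Cavities from CT-Derived Masks
Version: 0.1.0
Authors@R: person("sinusect", "developers", role = c("aut", "cre"),
    email = "sinusect@example.org")
Description: Landmark-based reorientation of head-CT cavity masks to the
    Frankfurt-plane convention, surface reconstruction with anatomical
    boundary clipping, proportional cross-sectioning with closed periodic
    spline contour fitting, per-section width/height/aspect-ratio
    profiling, and the cohort statistics used to compare sexes. Includes a
    synthetic cavity-cohort generator with analytic ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
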