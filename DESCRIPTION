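Package: sweetdot
Title: Inkjet Dot-Pattern Surface Structuring and Sweetness-Perception Analysis
Version: 0.1.0
Authors@R:
    person("sweetdot", "maintainers", email = "sweetdot@example.org",
           role = c("aut", "cre"))
Description: Tools for designing constant-tastant-load inkjet dot patterns on
    chocolate plates, rasterizing pattern bitmaps into valve-event print
    schedules, reconstructing printed-dot geometry from top- and side-view
    images (paraboloid surface area), synthesizing biomimetic tongue surfaces
    with placed papillae and an oscillatory-shear tastant smear model, and the
    accompanying sensory statistics (mixed two-way ANOVA with Tukey post-hoc,
    amplification ratios, stimulus-size linear response). Includes seeded
    synthetic-data generators (panel ratings, rendered dot images,
    stained-tongue images) so the full pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
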