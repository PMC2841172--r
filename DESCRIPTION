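Package: morphodisp
Title: Geometric Morphometrics of Parallel Character Displacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and testing parallel character
    displacement from two-dimensional landmark data: generalized
    Procrustes superimposition, thin-plate-spline partial warp and
    uniform-component shape variables (including separate-subset
    superimposition of articulated structures), factorial multivariate
    analysis of variance with Pillai's trace, allopatry-to-sympatry
    phenotypic change vectors, and residual-randomization permutation
    (RRPP) tests of vector magnitudes and orientations, together with a
    synthetic landmark-data generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
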