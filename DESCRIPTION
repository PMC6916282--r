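Package: dynarc
Title: Inverse Planning and Motion Modeling for Dynamic-Arc Radiotherapy
    with a Multileaf Collimator
Version: 0.1.0
Authors@R: person("dynarc", "developers", role = c("aut", "cre"),
    email = "dynarc@example.org")
Description: Treatment-plan optimization for dynamic-arc delivery of
    stereotactic body radiotherapy with a robot-mounted linac and multileaf
    collimator (MLC). Implements the three-stage inverse-planning pipeline
    (projected L-BFGS fluence optimization, reducing-level Xia-Verhey leaf
    sequencing with arc redistribution, and direct aperture optimization
    under machine delivery constraints), an effective-fluence model of MLC
    leaf motion between arc control points, post-optimization recalculation
    with interpolated nodes and apertures, and evaluation via dose-volume
    histograms, a conformity index, and delivery-time estimates. All
    components run on synthetic water phantoms generated by the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
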