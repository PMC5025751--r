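Package: actinstep
Title: Target-Zone Geometry and Stepping Statistics for Myosin X on Actin Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the helical lattice of F-actin and of fascin-crosslinked
    actin bundles to compute the binding "target zones" accessible to the
    lead head of a two-headed myosin X motor, together with the dimer's
    reach envelope, lever-arm stroke geometry and bending-penalty step
    preferences. Provides a synthetic single-molecule data generator
    (piecewise-constant stepping traces with exponential or Erlang dwells,
    signed Gaussian-mixture step sizes, localization noise, truncated-
    exponential run lengths, stopped-flow-like kinetic transients) and the
    matching analysis pipeline: chi-square step finding with counter-fit
    model selection, Gaussian-mixture fitting by expectation-maximization
    with cross-validated component selection, truncated-exponential
    run-length fitting, pooled velocity statistics, transient and
    actin-dependence kinetic fits, and a gated two-head ATPase cycle model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
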