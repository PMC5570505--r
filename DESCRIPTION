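Package: replifork
Title: Single-Molecule DNA Combing Analysis of Replication Fork Stalling
    and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-pulse (CldU/IdU) labeled DNA combing fibers
    from replicating cells. Classifies labeled-track patterns on single
    fibers, rigorously identifies replication fork stalls from
    neighboring-fork context, resolves ambiguous patterns by probabilistic
    enumeration weighted by the dataset's apparent stall rate, and computes
    stall-corrected replication kinetics: origin firing rate, per-pulse
    fork density, and Gaussian-fit fork rate. Includes Poisson inference of
    DNA lesion density from intact-fragment fractions and a stochastic
    fiber simulator with full ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
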