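Package: ofcattn
Title: Winner-Take-All Attentional Modulation of Value Coding in
    Orbitofrontal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a primate passive-viewing
    cue-reward task in which covert shifts of attention modulate the
    value signal carried by orbitofrontal cortex (OFC) neurons.  The
    package generates complete synthetic sessions (trial schedules,
    inhomogeneous-Poisson spike trains driven by a winner-take-all
    attention process, and pupil traces), screens neurons for visual
    responsiveness and value selectivity, quantifies perturbation-driven
    attentional modulation with sliding-window statistics and
    Benjamini-Hochberg false-discovery control, and fits a normalization
    model in which the attentional weight on the lower-value cue is a
    sigmoid function of the value difference, compared against reduced
    constant-weight models by split-half cross-validated R-squared and
    AICc.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
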