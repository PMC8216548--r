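Package: pippet
Title: Continuous-Time Bayesian Phase and Tempo Inference from Event Timing
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Point-process filters for rhythmic entrainment. Implements a
    family of variational Bayesian filters that continuously estimate the
    phase (and optionally tempo) of a hidden temporal process from the
    precise timing of discrete events, given an expectation template
    describing when events are likely: a background rate plus Gaussian
    peaks over phase. Includes the one-dimensional phase filter, its
    multi-stream generalization, the joint phase-and-tempo filter, the
    matching generative simulators (drift-diffusion phase plus
    inhomogeneous point-process events), deterministic stimulus builders
    (metronomes, swung rhythms, timing perturbations), and scripted
    simulation experiments covering event-response characterization,
    swing tracking, syncopation failure, tempo inference, period-dependent
    phase correction, and the filled-duration illusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
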