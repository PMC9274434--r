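Package: dotlattice
Title: Hysteresis, Adaptation and Orientation Bias in Multistable
    Dot-Lattice Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the individual-differences analysis of serial
    dependence in multistable dot-lattice perception. Provides a
    synthetic-observer simulator for the two-session dot-lattice
    paradigm (main, control and absolute-orientation-bias tasks),
    hierarchical Bayesian logistic models of the second-lattice percept
    with random intercepts and random hysteresis/adaptation slopes
    (fitted with JAGS via 'rjags'), Bayes-factor model comparison by
    bridge sampling, encompassing-prior order-constraint tests and
    one-sided Savage-Dickey density ratios, cross-session
    correlation-model families, axial circular statistics for
    orientation-bias data, a sequential Bayes-factor stopping rule, and
    an end-to-end replica pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
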