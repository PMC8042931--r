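Package: teworld
Title: Forward-Time Simulation of Transposable Element Proliferation in
    Asexual Host Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based, forward-time simulator of transposable element
    (TE) dynamics in an asexual host population. Hosts carry spatially
    explicit chromosomes in which TE copies replicate, excise and die;
    insertions landing inside genes draw a categorical fitness effect
    (lethal, deleterious, neutral or beneficial) that modifies an inherited
    survival likelihood exactly once. Populations double each generation and
    are thinned by carrying-capacity selection. The package also provides
    closed-form and cascaded-binomial (Galton-Watson) machinery for the
    survival of a beneficial lineage, and an experiment harness that sweeps
    the beneficial-insertion probability across named high/low parameter
    conditions, classifying each run as TE extinction, host extinction or
    long-term persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    parallel,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
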