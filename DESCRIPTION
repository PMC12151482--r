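Package: burstdilution
Title: Stochastic Gene Expression in Proliferating Cells: Lineage and
    Population Perspectives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and analytics toolkit for bursty gene expression in
    growing and dividing cells. Protein concentration follows a
    piecewise-deterministic Markov process with exponentially distributed
    synthesis bursts, growth-mediated dilution with positive feedback
    (high concentration slows growth, hence slows dilution), and optional
    random partitioning of molecules between daughters at division.
    Provides exact stationary concentration distributions and moments in
    both the single-cell (lineage) and population perspectives, existence
    regions for the two stationary laws, event-driven lineage simulators,
    an agent-based colony simulator with timer, adder, or state-dependent
    division control, partitioning-noise predictions, ensemble estimators
    with bootstrap standard errors, and config-driven experiments that
    compare the two perspectives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
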