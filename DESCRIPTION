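Package: boolpop
Title: Exact Population-Level Simulation of Heterogeneous Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates heterogeneous populations of non-interacting Boolean
    network individuals exactly, with no sampling error, by changing linear
    basis from per-state indicators to product (moment) variables indexed by
    subsets of model variables. Update rules are converted to linear form by
    Moebius inversion on the subset lattice, products are reduced by Boolean
    idempotence, and a worklist closure yields a finite sparse operator that
    evolves any mixed population, however heterogeneous. Supports
    deterministic, probabilistic (large-population limit) and continuous-time
    Boolean dynamics, loss-of-function screening through wild-type
    augmentation, a BoolNet-style rules dialect, and Monte Carlo plus
    exhaustive state-space reference simulators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
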