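Package: pbesim
Title: Sectional Finite-Volume Schemes for Tracer-Mass Aggregation Population Balances
Version: 1.0.0
Authors@R:
    person("Pbesim", "Maintainers", email = "maintainer@pbesim.org", role = c("aut", "cre"))
Description: Tools for simulating aggregation (Smoluchowski coagulation) population
    balance equations on sectional volume grids, tracking both the granule number
    density and the tracer mass distribution of the reduced two-property model.
    Implements a conservative finite-volume discretization on geometric grids, the
    cell average technique as a reference comparator, batch and MSMPR (mixed-suspension
    mixed-product removal) crystallizer drivers with nucleation and washout, adaptive
    stiff time integration, and the closed-form solutions and error statistics used
    to benchmark sectional schemes for gelling and non-gelling kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
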