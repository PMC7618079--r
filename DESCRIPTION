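Package: deathclock
Title: Death-Clock Cell-Based Models of Emergent Cell Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-based simulation and closed-form theory for the emergence of
    winners and losers in cell competition. Cells accumulate extracellular death
    signals into a "death clock" and initiate apoptosis when the clock reaches a
    threshold during G1 phase. The package provides an exact event-driven
    well-mixed simulator and a 2D vertex-based epithelium simulator (with T1/T2
    rearrangements, cell division and target-area-shrinkage apoptosis), the
    survival-probability theory of the G2 death-signal model, viability and
    competition-regime classifiers including the tolerance-emission
    parameterisation, and orthogonal-array Latin hypercube sweep machinery for
    the mechanical model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
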