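Package: gemqc
Title: Validation, Simulation and Version Comparison of Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("gemqc", "maintainers", email = "gemqc@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing constraint-based metabolic network
    reconstructions. Reads and writes the two SBML dialects used by the
    consensus yeast network distributions (Level 3 with the Flux Balance
    Constraints package, and the older Level 2 COBRA-compatible encoding),
    preserving MIRIAM-style annotations. Provides flux balance analysis on
    defined media, single-gene-deletion essentiality and auxotrophy
    benchmarking with full contingency statistics (including the Matthews
    correlation coefficient and geometric-mean accuracy), flux variability
    analysis and blocked-reaction detection, annotation-coverage auditing,
    and structured diffing of model versions that share stable identifiers.
    Includes a deterministic synthetic-fixture generator with brute-force
    oracles so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
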