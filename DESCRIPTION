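Package: emuflux
Title: Elementary Metabolite Unit Based 13C Metabolic Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Steady-state 13C metabolic flux analysis for a compact
    atom-mapped network spanning the serine synthesis pathway, the pentose
    phosphate pathway, the TCA cycle and de novo/salvage nucleotide
    synthesis. Provides a plain-text carbon-transition network format with
    a branch-reporter registry, elementary metabolite unit (EMU)
    decomposition with cascaded linear solves for simulated mass-isotopomer
    distributions (MIDs), a brute-force positional-isotopomer oracle,
    ingestion and natural-abundance correction of measured isotopologue
    tables, analytical growth-rate-relative flux solving from branch-point
    flux ratios, a least-squares refit cross-check, kinetic flux profiling
    of labeling time courses, and a synthetic-data generator for
    control/inhibited scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
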