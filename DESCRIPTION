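Package: deuteRate
Title: Protein Turnover Rates from Deuterated-Water Labeling Time Courses
Version: 0.1.0
Authors@R:
    person("deuteRate", "Developers", email = "deuterate@example.org",
           role = c("aut", "cre"))
Description: Estimates protein turnover rates from heavy-water (2H2O)
    metabolic labeling time courses of peptide monoisotopic relative
    abundance. Implements the classical exponential-decay kinetic model,
    the excess-deuterium-enrichment growth model, and a reformulated
    kinetic model in which the enrichment is scaled by the peptide's
    number of exchangeable hydrogens (N_EH), making the fitted rate
    practically independent of N_EH. Includes the per-timepoint linear
    de-biasing of enrichment against N_EH, protein-level aggregation and
    comparison statistics, a synthetic time-course simulator for
    benchmarking, tabular readers/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
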