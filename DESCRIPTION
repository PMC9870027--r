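Package: gidee
Title: Genome-Wide Imputed Differential Expression Enrichment for Tissue Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks tissues by enrichment of trait-associated imputed differential
    expression from transcriptome-wide association study (TWAS) results. Given
    per-tissue MetaXcan-style gene-trait association tables, GTEx-style normalised
    expression matrices and tissue sample sizes, the package restricts each tissue to
    robustly imputed genes (prediction R-squared above the per-tissue median), computes
    four enrichment tests (mean squared z-score, empirical Brown's combined p-value,
    and one-sided binomial tests on matrix-spectral-decomposition effective gene counts
    under Bonferroni and FDR significance thresholds), removes the expression-panel
    sample-size effect by linear-regression residualisation, and aggregates per-test
    tissue ranks over all combinations of tests, with the combined mean-squared-z plus
    Brown ranking (SZBP) as the headline prioritisation. Includes a synthetic
    multi-tissue data generator with planted enrichment for end-to-end validation, a
    trait-clustering utility, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
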