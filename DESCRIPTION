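Package: mwasenrich
Title: Methylome-Wide Association of Count Traits and mQTL-GWAS Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for methylome-wide association studies (MWAS) of
    bounded, right-skewed count phenotypes measured on Illumina 450k-style
    methylation arrays. Implements probe blacklist filtering, beta/M-value
    handling, a two-step residualized negative-binomial association model,
    genomic-inflation diagnostics, cross-dataset sign-concordance and p-value
    shift statistics, gene-set shift enrichment for CpGs mapped to gene sets,
    and a clumped, deduplicated, bin-matched permutation test for enrichment of
    CpG-associated mQTLs in GWAS summary statistics. A synthetic-data module
    generates every input with known ground truth so the full pipeline can be
    validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
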