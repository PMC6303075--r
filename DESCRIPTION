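Package: sexdiallel
Title: Sex-Specific Diallel Variance Partitioning and Dominance Reversal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic analysis of full diallel crosses with
    sex-specific fitness data. Partitions phenotypic variance into the
    Hayman inheritance classes (additive, parental, dominance, symmetric
    and asymmetric epistasis) and their sex interactions by unconstrained
    restricted maximum likelihood (negative variance components permitted),
    extracts best linear unbiased predictions per strain or cross, rotates
    sex-specific prediction axes into sexually concordant and sexually
    antagonistic dimensions, and tests for sex-specific dominance reversal
    via per-strain array covariances between outcross family means and
    parental-self means correlated across the sexes. Includes a synthetic
    diallel generator with an explicit biallelic-locus architecture so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    readxl,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
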