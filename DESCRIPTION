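Package: usherpanel
Title: Diagnostic Variant Filtering and Genotype Classification for
    Usher Syndrome Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for molecular diagnosis of Usher syndrome type 1 from
    targeted multi-gene amplicon panels: quality-control filtering of
    variant calls with allele-fraction zygosity bands, HGVS-based
    consequence classification, three-source population-frequency rarity
    filtering, pathogenicity tiering, per-patient genotype diagnosis
    (biallelic, digenic, monoallelic, unsolved, with disease-modifier
    candidates) including pedigree-based segregation and phase, and
    cohort-level diagnostic-yield reporting with a modifier-versus-onset
    comparison.  A synthetic amplicon-cohort simulator with known planted
    diagnoses provides ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
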