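Package: pavprot
Title: Variant Peptide Libraries and Genotype-Aware Association Analysis for
    Bottom-Up Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds variant-aware tryptic peptide libraries (reference,
    PAV-inclusive, PAV-exclusive) from a protein gene model and population
    genotypes, detects MS-PAVs (variant peptides whose detection tracks donor
    genotype) with Fisher's exact tests under Bonferroni control, maps
    MS-pQTLs with covariate-adjusted linear models on inverse-normalized
    protein intensities quantified from the PAV-exclusive library, and
    classifies variants into robust-pQTL / epitope-effect / underpowered
    regimens. Includes a synthetic-data generator emulating DIA-style
    quantification reports over nanoparticle fractions, so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
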