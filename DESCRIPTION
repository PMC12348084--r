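Package: arrayqc
Title: Quality Control for Genotyping-Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample- and variant-level quality control for genotyping-array
    cohorts: genetic sex inference from X-chromosome homozygosity, GRM- and
    IBD-based relatedness with relationship classification, principal-component
    ancestry inference with a six-standard-deviation outlier rule, exact
    Hardy-Weinberg testing, duplicate-pair genotype concordance, runs-of-
    homozygosity detection with LOESS-residual outlier flagging, post-imputation
    quality stratification, APOE epsilon-diplotype calling from imputed dosages,
    and candidate-SNP replication. Includes a synthetic-cohort generator with
    ground-truth sidecars (population structure, planted relatives, specimen and
    batch missingness, autozygosity tracts) so every stage is testable without
    access-controlled data, bit-exact PLINK 1 BED/BIM/FAM input/output, and an
    end-to-end pipeline runner with a telescoping run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
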