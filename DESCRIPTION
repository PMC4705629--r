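Package: copdexome
Title: Extreme-Phenotype Exome Burden Scoring and siRNA Screen Statistics
        for COPD Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Reusable computational core for an extreme-phenotype exome
        case-control design in chronic obstructive pulmonary disease:
        site- and genotype-level variant filtering (VQSLOD, DP, GQ), a
        per-gene functional deficit score summing class-weighted variant
        effects, cohort t-test contrasts, fast correlation-based filter
        (FCBF) feature selection with leave-one-out merit aggregation,
        expression-abundance candidate filtering on FPKM matrices,
        rank-list intersection of external prioritizer output, and the
        siRNA viability-screen gene-environment interaction statistic
        (robust Z with IQR/1.35 pseudo-SD, two-tailed Benjamini-Hochberg
        calls). Includes synthetic-data generators that emulate the full
        study design so every stage is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, vcfR
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
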