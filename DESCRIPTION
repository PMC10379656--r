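Package: epiqt
Title: Genome-Wide Two-Locus Epistasis Scans for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive covariate-adjusted SNP-SNP interaction analysis for
    quantitative traits such as cerebrospinal-fluid biomarkers. Provides
    PLINK binary genotype input/output, variant and subject quality control
    (call rate, minor allele frequency, Hardy-Weinberg exact test), a blocked
    all-pairs interaction scan with a nested-model F test on the interaction
    term, hierarchical R-squared variance partitioning for top pairs,
    SNP-to-gene mapping with gene-pair categorisation and protein-protein
    interaction overlap, and a seeded synthetic-cohort generator with planted
    main and epistatic effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
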