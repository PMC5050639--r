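Package: imputebench
Title: Ascertainment Bias of Missing-Genotype Imputation in GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for quantifying how reference-panel-free
    imputation of missing genotypes (per-marker mean, multivariate-normal EM
    on the realized relationship matrix, and iterative random forest) affects
    the power and false-positive rate of single-marker mixed-model GWAS in
    inbred crop panels.  Provides seeded generators for biallelic marker
    panels with map-based linkage-disequilibrium structure, GBS-like
    missingness, and alpha-lattice field trials; LD-block partitions by
    single-linkage clustering of map positions or recombination bins; QTL and
    phenotype simulation with Beta-distributed effects at controlled
    heritability; kinship-aware association tests with Bonferroni, Li-Ji
    effective-marker, and liberal significance thresholds; and bin-level
    confusion scoring of power and false-positive rate across golden-standard,
    ascertainment-bias, and GBS-style experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    ranger,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
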