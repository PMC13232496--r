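Package: spitres
Title: Image-Based Phenotyping and Genetic Mapping of Spittlebug
    Resistance in Forage Grasses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies insect-induced plant damage from lightbox
    photographs by two routes: supervised RGB threshold classification of
    green, chlorotic and necrotic tissue (DTR) and unsupervised median-cut
    color quantization into three color subgroups (DQU). Downstream tools
    fit multi-trial linear mixed models with a pedigree numerator
    relationship matrix by REML, extract BLUEs and BLUPs, estimate Cullis
    broad-sense heritability from pairwise prediction-error variances, and
    apply per-trial heritability quality control. Genotype utilities cover
    VCF import/export, minor-allele-frequency and call-rate filtering,
    VanRaden kinship, principal-component covariates, dosage-based linkage
    disequilibrium and binned LD decay with the r2 = 0.2 crossing distance.
    A single-marker association scan, Benjamini-Hochberg validation and
    LD-informed QTL window construction convert marker-trait associations
    into genomic intervals. A synthetic-data module generates images,
    F1 family genotypes, pedigrees, phenotypes and insect counts with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    vcfR,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    EBImage,
    knitr,
    rmarkdown
Config/testthat/edition: 3
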