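Package: methlink
Title: Differential CpG Methylation, Expression and Phenotype Analysis for
    Two-Group Cardiac Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking promoter CpG methylation to gene
    expression in two-group (wild-type versus knockout) designs. Implements
    per-CpG differential methylation calling with a beta-binomial model,
    arcsine link, generalized-least-squares fit and Wald test; negative
    binomial differential expression with TMM normalization and a
    likelihood-ratio test; TSS-window linkage of differentially methylated
    CpGs to genes with a 25 percent methylation-expression anticorrelation
    filter and directional classification; an infarct-boundary roughness
    index from equal-area best-fit ellipses; metabolite methylation-potential
    ratios, adenylate energy charge and cardiomyocyte census statistics; and
    a synthetic-data generator with ground-truth tables so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
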