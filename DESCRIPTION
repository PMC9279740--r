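Package: synergyseq
Title: Factorial Cytokine-Stimulation RNA-Seq Synergy Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-factor cytokine stimulation experiments from bulk
    RNA-seq count matrices. Given a four-condition design (control, each single
    cytokine, and the combination), the package normalizes counts, estimates
    per-gene log2 fold changes with delta-method standard errors, calls
    differential expression with an exact conditional Poisson test and
    Benjamini-Hochberg adjustment, and classifies regulated genes as
    synergistic (positive or negative), additive, or antagonistic using Wald
    tests of the combined effect against the sum of and against each single
    effect. Includes a factorial count simulator with known per-gene
    interaction structure, hypergeometric gene-set over-representation,
    ligand-receptor co-regulation reporting, and the small closed-form assay
    statistics used for validation (2^-ddCt relative quantification,
    complement-dependent cytotoxicity percentage, geometric mean fluorescence
    intensity, Student's t summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
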