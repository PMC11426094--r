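Package: aglscan
Title: Approximate Generalized Least Squares GWAS for Additive and Dominance Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-SNP genome-wide association testing for quantitative traits
    in pedigreed populations using the approximate generalized least squares
    (AGLS) method: phenotypes are pre-adjusted by twice the predicted
    transmitting ability (the pedigree-based polygenic BLUP), genotype-class
    means are fitted per SNP, and additive and dominance effects are tested
    with contrast t-statistics whose additive coefficients remain valid under
    Hardy-Weinberg disequilibrium. Includes quantitative-genetics effect
    decomposition (allelic means and effects, average effect of gene
    substitution, dominance deviations and their classification), screening of
    rare homozygous-recessive genotypes by their negative phenotypic impact,
    heifer-culling and SNP-guided mating rules, exact mixed-model (GLS and
    Henderson's MME) reference solvers for validation, and a pedigree-based
    quantitative-trait simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    MASS,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
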