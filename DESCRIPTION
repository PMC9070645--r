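Package: diallelGP
Title: Across-Population Genomic Prediction in Half-Diallel Mating Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic prediction of cross means and within-cross
    (Mendelian-sampling) genetic values in bi-parental families connected
    within a half-diallel mating design, trained either within the design or
    across populations from a diversity panel. Provides a synthetic-data
    generator for structured panels and half-diallel progenies, genotype
    matrix algebra (filters, parental-average genotypes, VanRaden genomic
    relationships, PCA projection), EM-REML variance-component estimation
    with broad-sense heritability on an entry-mean basis, penalized
    marker-effect models (ridge and LASSO by cyclic coordinate descent with
    inner cross-validated shrinkage), three training scenarios with
    predictive-ability assessment, training-set optimization (PEVmean,
    CDmean, MeanRel), and a relative-importance analysis of the factors
    driving predictive ability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    lme4,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
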