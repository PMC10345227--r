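Package: hmotriad
Title: Hierarchical Interaction Selection for Human Milk
    Oligosaccharide, Infant Gut Microbiome and Cognition Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-step association analysis linking human milk
    oligosaccharide (HMO) concentrations, infant gut Bifidobacterium and
    Bacteroides relative abundances, and Mullen Scales of Early Learning
    (MSEL) cognition scores in a longitudinal mother-infant cohort.
    Variable selection uses a hierarchy-preserving latent overlapping
    group LASSO (an interaction can only enter together with both of its
    main effects) with subject-level 10-fold cross-validation repeated
    for stability; effect sizes come from a random-intercept linear mixed
    model fitted by restricted maximum likelihood. Includes double-MAD
    outlier flagging, species prevalence filtering, standardization and
    age residualization of predictors, A-tetrasaccharide and secretor
    stratification rules, cohort summary tables with Welch and chi-square
    comparisons, and a synthetic longitudinal cohort generator with a
    saved truth file for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
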