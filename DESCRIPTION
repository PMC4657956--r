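Package: bsbmm
Title: Binomial Mixed Models for Differential Methylation in Bisulfite
    Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Site-by-site association testing for bisulfite sequencing
    count data (WGBS/RRBS) using a binomial mixed model with a
    kinship-structured genetic random effect and an independent
    over-dispersion effect, fitted by auxiliary-variable MCMC with
    approximate Wald inference.  Includes a Polya-Gamma sampling backend,
    beta-binomial, binomial GLM, linear and linear mixed model baselines,
    proportion transformations and site filters, a generative simulator
    with realistic kinship and read-depth structure, and evaluation
    utilities (permutation-based empirical FDR, Storey q-values, genomic
    control, AUC, differentially methylated region calling).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
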