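Package: swinePOP
Title: Genetic Analysis of Pelvic Organ Prolapse in Sows
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical-genetics pipeline for culling due to pelvic organ
    prolapse (POP) in commercial sow herds. Provides quality control and
    binary-trait coding of multi-parity sow life-history records, pedigree
    and genomic (VanRaden) relationship matrices, Gibbs samplers for
    threshold (probit) marker-effects models with Bayes-B, Bayes-C and
    Bayes-Cpi priors, bivariate linear Bayes-C0 models for between-parity
    genetic correlations, threshold animal models for liability-scale
    heritability, Dempster-Lerner conversion to the observed scale,
    1 Mb window variance decomposition with window posterior probabilities
    of association (WPPA), and a synthetic-data generator that emulates
    multi-parity sow cohorts with a sparse QTL architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
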