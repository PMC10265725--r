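Package: pedconnectome
Title: Longitudinal Weighted Structural Connectome Analysis for Paediatric Mild TBI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for longitudinal analysis of FA-weighted
    structural brain networks in paediatric mild traumatic brain injury versus
    orthopaedic injury cohorts. Builds 90-node AAL connectomes from fibre
    assignment tables, applies the fully-connected exclusion filter, computes
    weighted global and nodal graph-theory metrics with degree-preserving
    random-network standardization (small-worldness), removes scanner/site
    effects with covariate-preserving empirical-Bayes harmonization, classifies
    persistent post-concussive symptoms with a regression-based reliable change
    index, and fits longitudinal linear mixed-effects models with
    Benjamini-Hochberg correction, confidence-interval-gated Cohen's d effect
    sizes, and interaction probing. Includes a fully synthetic cohort generator
    with known ground-truth effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    sva,
    optparse
Config/testthat/edition: 3
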