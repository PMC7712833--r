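Package: mbnDiallel
Title: Multiplicative-Binomial Recursive Models for Perinatal Mortality
    in Diallel Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian analysis of perinatal mortality in multi-variety
    diallel crosses using the multiplicative binomial (MBN) distribution,
    which extends the binomial with a dispersion parameter so that
    stillbirth counts within a litter may be over- or under-dispersed.
    Litter size and the logit of the MBN location parameter are modelled
    jointly in a recursive hierarchical animal model with pedigree-based
    additive genetic and sow permanent environmental effects; five
    predictors for the logit (no recursion, shared linear, shared
    quadratic, cross-specific linear, cross-specific quadratic in the
    litter-size deviation) are fitted by a Gibbs sampler with adaptive
    Metropolis-Hastings steps. Cross effects are reparameterised into
    Dickerson direct, maternal and heterosis components, and models are
    ranked by the conditional predictive ordinate (CPO). A synthetic-data
    generator reproduces the diallel structure (pedigree, crosses,
    parities, year-seasons) for simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'mbnDiallel-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'cpo.R'
    'design.R'
    'dickerson.R'
    'mbn.R'
    'mcmc.R'
    'pedigree.R'
    'phenotypes.R'
    'simulate.R'
    'summarize.R'
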