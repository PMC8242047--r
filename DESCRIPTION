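Package: fossilbd
Title: Bayesian Birth-Death Inference from Fossil Occurrence Data
Version: 0.1.0
Authors@R:
    person("fossilbd", "developers", email = "fossilbd@example.org",
           role = c("aut", "cre"))
Description: Estimates speciation and extinction dynamics from taxon-labelled
    fossil occurrence tables with age-range uncertainty.  Models the fossil
    sampling (preservation) process as a Poisson process (homogeneous,
    lifespan-hump, or stage-wise time-variable, with optional gamma rate
    heterogeneity across taxa) and jointly infers per-species times of
    speciation and extinction together with piecewise-constant birth-death
    rates whose number of shifts is unknown (reversible-jump and
    birth-death-process MCMC samplers).  Further models link diversification
    rates to time-continuous environmental covariates under a horseshoe
    shrinkage prior, to the standing diversity of interacting clades, and to
    taxon age via a Weibull age-dependent extinction hazard.  Includes a
    forward simulator of clade histories and fossil records with known
    ground truth, and a pipeline/CLI orchestrating age-randomized replicate
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
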