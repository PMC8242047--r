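---
title: "Models and methods in fossilbd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fossilbd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fossilbd` estimates speciation and extinction dynamics from fossil
occurrence tables.  This vignette explains the models, the priors and
numerical conventions, what the synthetic-data generator does and does not
emulate, and the design choices made where more than one reasonable option
existed.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data and the augmented likelihood

The data are occurrences: `(taxon, min_age, max_age)` rows, ages in Ma
before present, increasing into the past.  Age intervals come from the
geological stage (or finer bin) an occurrence is assigned to; the package
propagates that uncertainty by drawing, per replicate, one fixed age
uniformly within each interval (`resample_ages()`, ten replicates by
default) and repeating every analysis per replicate.

All time intervals are half-open `[older, younger)`: an age exactly on a
stage boundary belongs to the younger stage, an event exactly on a rate
shift belongs to the younger interval.  The default stage grid is the ICS
2020 Cretaceous plus the Danian.

Each species `i` has latent times of speciation and extinction
`Ts_i > Te_i`.  Given piecewise-constant speciation and extinction rates
`lambda(t), mu(t)`, the augmented-data birth--death log-likelihood is

```
sum_j [ B_j log lambda_j + D_j log mu_j - (lambda_j + mu_j) S_j ]
```

with `B_j`/`D_j` the speciation/extinction events in interval `j` and
`S_j` the summed lineage duration.  Every `Ts` — including the clade
origin — is counted as a speciation event; this makes the likelihood a
product over species, which the vectorized Metropolis sweeps over
`(Ts, Te)` exploit.  Extant (or simulation-censored) species contribute
exposure but no extinction event.

## Preservation models

Occurrences of a species are a Poisson process on `[Te, Ts]`, conditioned
on at least one occurrence (an unobserved species yields no row).  Three
rate shapes are available:

* **HPP** — constant rate `q` (occurrences/species/Myr):
  `k log q - q d - log(1 - exp(-q d))`, `d = Ts - Te`.
* **NHPP** — the lifespan hump `q * 6u(1-u)` with `u = (Ts-t)/d`.  The
  quadratic is the simplest mean-preserving hump that vanishes at both
  range ends; its integral over the lifespan is exactly `q d`.
* **TPP** — one rate per geological stage; the expected count is the sum
  of stage rates times lineage overlap.

The gamma model multiplies each taxon's rate by a mean-one
`Gamma(alpha, alpha)` factor, discretized into four equal-weight
categories (category medians renormalized to mean one — the
deterministic, cheap convention used for rate heterogeneity elsewhere in
phylogenetics).  `pp_model_test()` ranks all variants by AICc with the
occurrence count as sample size; AICc (not AIC) because per-dataset
occurrence counts are modest, and the parameter counts are printed so the
difference is visible.

## Episodic rates: RJMCMC and BDMCMC

`rjmcmc_sample()`/`bdmcmc_sample()` jointly sample preservation
parameters, all `(Ts, Te)` under the hard bracket (oldest/youngest
occurrence), and independent shift-point processes for speciation and
extinction.  Priors: rates `Gamma(1.1, 1)`; shift counts `Poisson(1)`
each; shift times uniform over the observed occurrence span; `q`
`Gamma(1.1, 0.1)`; gamma shape `Gamma(1, 0.5)`.  These are declared, weakly informative defaults and are all
arguments.

Within a configuration, rates are exact Gibbs draws from Gamma full
conditionals.  Reversible-jump moves add (new rate drawn from the prior,
attached to the younger half), remove (younger side's rate discarded) or
move a shift; with the ordered-uniform time prior and prior-draw
proposals everything cancels to `L'/L * eps/(k+1)` for an add.  The
BDMCMC variant runs one unit of virtual time of a continuous-time
birth--death process over shift points per iteration; with birth
intensity `eps` and births from the prior, detailed balance makes each
shift's death rate the likelihood ratio without/with it.  The two
samplers are cross-checked on shared data in the test suite.

Proposal windows adapt to 20–40% acceptance during the burn-in (first
10% of iterations, also the discarded fraction in all summaries) and are
frozen afterwards.  Rates through time are step functions evaluated on a
0.1-Myr grid; net diversification is computed per posterior sample, so
`r(t) = lambda(t) - mu(t)` holds exactly in every summary.  Replicate
pooling concatenates post-burn-in samples; this requires a common grid,
so the pipeline fixes one span (the occurrence-table span) for all
age-randomized replicates.

## Covariate-dependent rates (MBD) and the shrinkage weight

`mbd_sample()` ties rates to standardized time-continuous covariates:
linear `baseline * max(0, 1 + sum G_j v_j)` or exponential
`baseline * exp(sum G_j v_j)` links, evaluated stepwise on a 0.1-Myr
grid.  The integral term uses the exact per-cell lineage exposure, so
with all `G = 0` the likelihood reduces to the constant-rate form to
machine precision (a test asserts 1e-8).  Covariates are z-scored over
the analysis window; the correlation parameters are therefore per
standard deviation of the covariate.

The horseshoe prior is `G_j ~ N(0, tau^2 psi_j^2)`,
`psi_j ~ HalfCauchy(1)`, `tau ~ HalfCauchy(0.1)` shared across the
speciation and extinction coefficient vectors, with the inverse-gamma
augmentation giving exact Gibbs updates of all scales; `G_j` moves by a
mixture of random-walk and draw-from-the-prior proposals (the latter
keeps mixing exact when a covariate carries no information).

The per-covariate **shrinkage weight** is reported as the posterior mean
of

```
omega_j = 1 - 1 / (1 + tau^2 psi_j^2 I_j)
```

where `I_j` is the observed information the data carry about `G_j` (the
relevant event count weighted by the squared standardized covariate at
the event times).  This is the standard horseshoe shrinkage coefficient
for the Gaussian approximation of the likelihood: it is the factor by
which the conditional posterior mean of `G_j` is *not* shrunk toward
zero, so `omega_j > 0.5` reads as "signal dominates shrinkage".  The
information factor matters: without it (i.e. `1 - 1/(1 + (tau psi)^2)`),
`omega > 0.5` would require coefficients of order one, and effects of the
size actually reported for fossil data (|G| ~ 0.1 per standard deviation)
could never be called significant.  `omega` is invariant to covariate
sign flips, and the 95% CI of `G_j` excluding zero agrees with
`omega_j > 0.5` on the recovery simulations (tested).

## Clade interactions (MCDD)

Rates respond linearly to standing diversities:
`lambda_i(t) = lambda0_i * max(0, 1 - sum_j g_lambda[i,j] D_j(t))` and
symmetrically (`+`) for extinction; coefficients are per-species
fractions of the baseline (truncated at zero), diversities are
recomputed from the input lineage times and include all living species.
Baselines are Gibbs-sampled; each coefficient has a **spike-and-slab**
prior: point mass 1/2 at exactly zero and a `Normal(0, 0.25)` slab.  The
point mass is a deliberate choice: the reported "probability of
competition" is the posterior sampling frequency of positive values, and
that frequency is only a calibrated significance measure if "no
interaction" has positive prior mass — with a purely continuous prior
the sign frequency of a null coefficient regularly exceeds 0.9 (two
independent clades both drift in time, a spurious-regression artefact),
and simulations with no planted interaction produced spurious calls in
nearly every replicate.  With the spike, non-interacting clades yield no
off-diagonal probability above 0.9 while a planted +15%/species effect
is recovered with probability > 0.9 (both tested).

## Age-dependent extinction (ADE)

Species longevities are `Weibull(shape, scale)`; the hazard at taxon age
`t` is `(shape/scale) (t/scale)^(shape-1)`, so `shape = 1` is Van
Valen's age-independent case and the hazard ratio between two ages is
`(t2/t1)^(shape-1)` independent of the scale.  `ade_sample()` samples
`(shape, scale, q)` jointly with all `(Ts, Te)`.

Two likelihood details matter for calibration.  First, only species with
at least one fossil are observed, and short-lived species are the ones
lost — exactly the region that identifies the shape.  The likelihood
therefore uses the *unconditioned* preservation density together with
the exact normalization `P(observed) = 1 - E[exp(-q d)]` over the
Weibull longevity law (per extinct species).  Combining the
per-species conditioned preservation term with the Weibull density
instead double-counts the conditioning and visibly biases the shape
downward.  Second, `E[exp(-q d)]` is computed by a trapezoid rule after
the substitution `d = scale * e^t`, under which the integrand is smooth
with double-exponential decay; a 32-point Gauss--Laguerre rule is *not*
accurate enough here (its error at shape 2 is ~4e-3, large enough to
shift the shape posterior).  Species censored at the dataset's younger
edge contribute log-survival terms; window-split analyses assign species
by extinction time and left-truncate lineages that enter the window
already alive.  Priors: `shape ~ LogNormal(0, 1)` (centred on
age-independence, symmetric on the log scale), `scale ~ Gamma(1.1, 0.1)`,
`q ~ Gamma(1.1, 0.1)`.

## The synthetic-data generator

`simulate_history()` is an event-driven (Gillespie) simulator with four
regimes: piecewise-constant rates; covariate-linked rates updated on a
0.1-Myr grid (mirroring the inference discretization); diversity
dependence with rates recomputed after every event; and age-dependent
extinction with each species' longevity drawn at birth from the Weibull
(exact for the non-Markovian process).  `simulate_clades()` couples
several clades through the interaction matrices.  Conditioning is by
rejection on a species-count range; clades are not conditioned on
survival (the empirical clades are extinct).  `sample_fossils()` draws
occurrence times from the preservation model (gamma heterogeneity uses
continuous mean-one multipliers), drops unobserved species, and
`impose_age_uncertainty()` coarsens exact ages to stage intervals.

Defaults in the recovery worlds are chosen once for realism, not tuned:

* Turnover: baselines giving mean species longevities of ~2.5–5 Myr and
  clade sizes of ~150–450 species, the scale of the empirical family
  datasets (~100–350 occurrences, tens of species, at preservation
  q ≈ 3 occ/species/Myr; the empirical stage-level rates reach ~4–7).
* The temperature covariate is a degrees-Celsius curve with ~8.5 °C of
  secular cooling across 100–66 Ma plus Myr-scale oscillations,
  matching the ~7–10 °C proxy-inferred Late Cretaceous cooling; its
  standard deviation over the window is ~3 °C.  The planted extinction
  correlation is −0.08 *per degree* (the scale on which such
  coefficients are reported for real data), i.e. ≈ −0.24 per standard
  deviation after standardization.  A per-standard-deviation −0.08
  effect is ≈1 standard error at these sample sizes and is not
  recoverable by any estimator — an identifiability fact worth stating
  explicitly.
* The cross-clade interaction world plants +15% of baseline extinction
  per species of the competitor clade.

What a green recovery test establishes: that the samplers identify
effects of the stated sizes from fossil records of the stated richness
under the model's own assumptions.  What it does not establish: robustness
to taxonomic error, spatially biased sampling, correlated age errors
across occurrences (ages are resampled independently per occurrence — the
per-formation block alternative is an explicit open switch), or
preservation misspecification beyond the shapes modelled.

## Numerical conventions and degenerate inputs

* `log(1 - e^{-x})` via `log1p`/`expm1` branches; likelihoods return
  `-Inf` (never `NaN`) for invalid states, which Metropolis rejects.
* Zero-variance covariates standardize to zeros with a warning; the
  posterior of their coefficients is then exactly the prior (tested by
  Kolmogorov–Smirnov).
* Zero-duration rate intervals contribute nothing; empty stages are
  dropped from TPP parameter counts.
* Chains are reproducible bit-for-bit given a seed; replicate seeds are
  derived from one master seed (`child_seeds()`), all below 2^31.
* Test and acceptance chains are scaled down (10^3–10^4 iterations
  versus the production-scale 5–20 million) and recovery loops use 20 (or
  fewer, for module tests) replicates; thresholds follow the stated
  proportions.

## Known limitations

* The trans-dimensional samplers are plain R; study-scale chains (10^7
  iterations on thousands of occurrences) would want a compiled kernel.
* The MBD fit conditions on point estimates of `(Ts, Te)` (as in the
  study design) rather than propagating their posterior.
* No spatially explicit preservation, no formation-count covariate, no
  mass-extinction-specific sampler variant, no joint ADE + shift model.
* `omega` depends on an observed-information plug-in; with strongly
  truncated linear-link rates it is approximate.
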