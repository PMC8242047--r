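# fossilbd

Bayesian birth–death inference from fossil occurrence data, in R.

`fossilbd` is for palaeobiologists who have a table of taxon-labelled
fossil occurrences with stratigraphic age ranges and want
preservation-aware estimates of speciation and extinction dynamics:
when rates shifted, whether a clade was in decline, which environmental
variables and clade interactions the rates track, and whether extinction
risk depends on species age.

## The models

Each species *i* has latent times of speciation and extinction
(*Ts_i*, *Te_i*, in Ma).  Fossils are a Poisson sampling (preservation)
process on [*Te*, *Ts*] with rate *q* occurrences/species/Myr —
homogeneous (HPP), hump-shaped over the lifespan (NHPP), or stage-wise
(TPP), with optional gamma rate heterogeneity across taxa.  Conditional
on all (*Ts*, *Te*), piecewise-constant birth–death rates have the
augmented-data log-likelihood

    sum_j [ B_j log λ_j + D_j log μ_j − (λ_j + μ_j) S_j ]

(*B_j*, *D_j* events and *S_j* lineage-Myr in interval *j*).  Everything
is sampled jointly by reversible-jump MCMC or a birth–death process over
shift points (two cross-validating trans-dimensional samplers).  On the
estimated (*Ts*, *Te*), three further models run:

* **MBD** — λ(t), μ(t) tied to standardized covariate curves by linear
  or exponential links, coefficients *Gλ_j*, *Gμ_j* under a horseshoe
  prior with per-covariate shrinkage weights ω (ω > 0.5 ⇒ significant).
* **MCDD** — multi-clade diversity dependence:
  μ_i(t) = μ0_i·max(0, 1 + Σ_j gμ_ij·D_j(t)) (and mirrored for λ);
  g's have spike-and-slab priors and interactions are reported as
  posterior sign frequencies.
* **ADE** — Weibull age-dependent extinction: hazard
  h(t) = (ɸ/s)(t/s)^(ɸ−1); ɸ = 1 is Van Valen's age-independent case.

A forward simulator (`simulate_history`, `simulate_clades`,
`sample_fossils`, `impose_age_uncertainty`) generates fossil records with
known ground truth under every regime, and `run_pipeline()` /the
`fossilbd` CLI orchestrate the full replicated analysis.

## Worked example

Simulate a clade whose extinction rate quadruples at 76 Ma, sample
fossils at q = 3, and ask the reversible-jump sampler to find the shift:

```r
library(fossilbd)

reg <- regime_piecewise(lambda = c(0.25, 0.25), mu = c(0.1, 0.4),
                        shift_times = 76, origin_age = 100, end_age = 66)
h   <- simulate_history(reg, seed = 11, min_species = 150, max_species = 350)
occ <- sample_fossils(h, preservation_model("HPP", q = 3), seed = 2)
occ_summary(occ)

tr  <- rjmcmc_sample(occ, model = "HPP", iterations = 20000,
                     sampling_freq = 20, seed = 5, extant_age = 66)
keep   <- seq(51, 1000)                       # 10% burn-in
shifts <- unlist(lapply(tr$mu[keep], `[[`, "s"))
mean(shifts >= 74 & shifts <= 78)             # mu-shift mass near 76 Ma
rtt <- rate_through_time(tr)
mean(rtt$mu_mean[rtt$age > 80])               # extinction before the shift
mean(rtt$mu_mean[rtt$age < 74])               # ... and after
mean(rtt$net_mean[rtt$age < 74])              # net diversification after
mean(tr$stats$q_mean[keep])                   # preservation rate
```

Output from this exact run:

```
Occurrence data set: clade
  1633 occurrences, 301 taxa (1 singletons), 5.43 occ/taxon
[1] 0.890595     # 89% of mu-shift posterior mass within 76 +/- 2 Myr
[1] 0.11434      # posterior mean extinction rate before the shift (true 0.1)
[1] 0.3669567    # after the shift (true 0.4)
[1] -0.1202788   # net diversification is negative after the shift
[1] 2.985229     # preservation rate (true 3)
```

The sampler places the extinction upshift at the planted 76 Ma, infers
negative net diversification after it (the decline signature), and
recovers the preservation rate.

## Layout

* `R/` — data handling (`read_occurrences`, `resample_ages`,
  `rescale_covariate`, stage grids), simulator, preservation models
  (`preservation_loglik`, `pp_model_test`), episodic samplers
  (`rjmcmc_sample`, `bdmcmc_sample`, `rate_through_time`,
  `diversity_trajectory`, `combine_replicates`), `mbd_sample`,
  `mcdd_sample`, `ade_sample`, `run_pipeline`, `fossilbd_cli`.
* `vignettes/fossilbd-methods.Rmd` — models, priors, numerical
  conventions and design rationale.
* `tests/testthat/` — unit, property and acceptance suites.
* `inst/exec/fossilbd` — command-line entry point.
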