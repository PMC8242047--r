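# Shared synthetic worlds used across tests.  Scenario parameters are fixed
# design choices (documented in the methods vignette); seeds are derived
# deterministically per replicate from fixed bases via child_seeds().

# Late Cretaceous-like global temperature proxy in degrees C: secular
# cooling (~8.5 C over 100-66 Ma, cf. the 7-10 C proxy-inferred cooling)
# plus Myr-scale oscillations.
fbd_temp_curve <- function() {
  ages <- seq(105, 60, by = -0.25)
  covariate_curve(ages,
                  15 + 0.25 * (ages - 66) + 1.8 * sin((ages - 66) / 3.5) +
                    2.5 * sin((ages - 66) / 1.1),
                  name = "temperature")
}

# one MBD recovery replicate: high-turnover clade (mean longevity ~2.6 Myr)
# whose extinction rate tracks temperature with a coefficient of -0.08 per
# degree C, the scale on which such effects are reported for real data
# (expressed per standard deviation internally); plus a white-noise
# covariate.  Returns the fitted per-covariate summary.
fbd_mbd_replicate <- function(r, iterations = 6000) {
  tc <- fbd_temp_curve()
  sdC <- stats::sd(covariate_at(tc, seq(100, 66, -0.1)))
  sds <- child_seeds(1000 + r, 4)
  set.seed(sds[1])
  noise <- covariate_curve(tc$age, stats::rnorm(nrow(tc)), name = "noise")
  reg <- regime_covariate(0.45, 0.38, c(0, 0), c(-0.08 * sdC, 0),
                          list(tc, noise), "exponential", 100, 66)
  h <- simulate_history(reg, seed = sds[2], min_species = 150,
                        max_species = 450)
  occ <- sample_fossils(h, preservation_model("HPP", 3), seed = sds[3])
  tt <- true_times(h, taxa = sort(unique(occ$taxon)))
  tr <- mbd_sample(tt, list(tc, noise), iterations = iterations,
                   sampling_freq = 10, seed = sds[4], link = "exponential",
                   window = c(100, 66))
  mbd_summary(tr)
}

# one MCDD replicate: clade B's standing diversity adds +15% of baseline
# per species to clade A's extinction rate (g_mu[A,B] = 0.15); fossil
# sampling at q = 3 then inference from the sampled species' true times.
fbd_mcdd_replicate <- function(r, g_ab = 0.15, iterations = 5000,
                               seed_base = 2000) {
  sds <- child_seeds(seed_base + r, 3)
  gl <- matrix(0, 2, 2)
  gm <- matrix(0, 2, 2)
  gm[1, 2] <- g_ab
  hs <- simulate_clades(c(0.2, 0.2), c(if (g_ab > 0) 0.05 else 0.08, 0.1),
                        gl, gm, 100, 66, seed = sds[1],
                        min_species = 80, max_species = 400,
                        clade_ids = c("A", "B"))
  tl <- lapply(hs, function(h) {
    occ <- sample_fossils(h, preservation_model("HPP", 3), seed = sds[2])
    true_times(h, taxa = sort(unique(occ$taxon)))
  })
  names(tl) <- c("A", "B")
  tr <- mcdd_sample(tl, iterations = iterations, sampling_freq = 10,
                    seed = sds[3])
  mcdd_summary(tr)
}

# one ADE replicate: Weibull longevities (scale 5 Myr), speciation 0.25,
# 110-60 Ma, HPP q = 3; returns the posterior summary of the shape.
fbd_ade_replicate <- function(r, shape, iterations = 5000,
                              seed_base = 4000) {
  sds <- child_seeds(seed_base + r, 3)
  reg <- regime_age_dependent(0.25, shape, 5, 110, 60)
  h <- simulate_history(reg, seed = sds[1], min_species = 150,
                        max_species = 400)
  occ <- sample_fossils(h, preservation_model("HPP", 3), seed = sds[2])
  tr <- ade_sample(occ, iterations = iterations, sampling_freq = 10,
                   seed = sds[3], extant_age = 60)
  ade_summary(tr)
}

# cached standard datasets reused across test files (built once per run)
fbd_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, build) {
    if (!exists(key, envir = env)) assign(key, build(), envir = env)
    get(key, envir = env)
  }
})

# constant-rate clade (lambda 0.2, mu 0.1, 100-66 Ma) with q = 3 fossils
fbd_const_clade <- function() {
  fbd_cache("const_clade", function() {
    reg <- regime_piecewise(0.2, 0.1, numeric(), 100, 66)
    h <- simulate_history(reg, seed = 21, min_species = 100,
                          max_species = 300)
    occ <- sample_fossils(h, preservation_model("HPP", 3), seed = 3)
    list(history = h, occ = occ)
  })
}

# extinction-upshift clade: mu 0.1 -> 0.4 at 76 Ma
fbd_shift_clade <- function() {
  fbd_cache("shift_clade", function() {
    reg <- regime_piecewise(c(0.25, 0.25), c(0.1, 0.4), 76, 100, 66)
    h <- simulate_history(reg, seed = 11, min_species = 150,
                          max_species = 350)
    occ <- sample_fossils(h, preservation_model("HPP", 3), seed = 2)
    list(history = h, occ = occ)
  })
}

fbd_tiny_table <- function() {
  occurrence_table(taxon = c("Trex", "Trex", "Trex", "Edmonto", "Anky"),
                   min_age = c(66.0, 66.8, 67.5, 70.0, 72.1),
                   max_age = c(67.2, 68.0, 69.0, 72.1, 76.0),
                   region = c("new_world", "new_world", "new_world",
                              "old_world", "other"),
                   clade = c("Tyrannosauridae", "Tyrannosauridae",
                             "Tyrannosauridae", "Hadrosauridae",
                             "Ankylosauridae"),
                   name = "tiny")
}
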