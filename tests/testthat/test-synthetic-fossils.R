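test_that("history simulation: determinism, conservation, degenerate regimes", {
  reg <- regime_piecewise(0.3, 0.1, numeric(), 90, 66)
  h1 <- simulate_history(reg, seed = 5, min_species = 10)
  h2 <- simulate_history(reg, seed = 5, min_species = 10)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_false(nrow(simulate_history(reg, seed = 6, min_species = 10)) ==
                 nrow(h1) &&
                 all(simulate_history(reg, seed = 6, min_species = 10)$ts ==
                       h1$ts))
  # single origin: every species but the first has a parent
  expect_equal(sum(h1$parent > 0), nrow(h1) - 1L)
  expect_true(all(h1$ts > h1$te))
  # diversity >= 1 throughout the clade's span
  ages <- seq(max(h1$ts) - 1e-6, min(h1$te) + 1e-6, length.out = 64)
  D <- fossilbd:::count_diversity(h1$ts, h1$te, ages)
  expect_true(all(D >= 1))

  # mu = 0: everyone survives to end_age
  h0 <- simulate_history(regime_piecewise(0.3, 0, numeric(), 90, 66),
                         seed = 2, min_species = 5)
  expect_true(all(h0$extant))
  expect_true(all(h0$te == 66))

  # runaway rates abort with a clear message
  expect_error(simulate_history(regime_piecewise(2, 0, numeric(), 200, 0),
                                seed = 1, cap = 200, max_attempts = 1),
               "cap")
})

test_that("Weibull shape 1 gives exponential longevities (pooled mean)", {
  d <- c(); ext <- c(); early <- c()
  for (s in 1:12) {
    h <- simulate_history(regime_age_dependent(0.25, 1, 5, 110, 60),
                          seed = 400 + s, min_species = 100,
                          max_species = 500)
    d <- c(d, h$ts - h$te)
    ext <- c(ext, h$extant)
    early <- c(early, h$ts >= 85)
  }
  d_unc <- d[!ext & early]
  expect_gt(length(d_unc), 500)
  se <- stats::sd(d_unc) / sqrt(length(d_unc))
  # species born >= 25 Myr before the simulation end: the chance of
  # right-censoring is e^-5, so these longevities are effectively an
  # unbiased exponential sample of mean = scale
  expect_lt(abs(mean(d_unc) - 5), 3 * se + 0.05)
})

test_that("piecewise regime produces rise-then-decline mean trajectories", {
  up <- 0; down <- 0; n <- 60
  reg <- regime_piecewise(c(0.2, 0.1), c(0.05, 0.3), 76, 100, 66)
  for (s in seq_len(n)) {
    h <- tryCatch(simulate_history(reg, seed = 6000 + s, min_species = 2,
                                   max_attempts = 20),
                  fossilbd_error = function(e) NULL)
    if (is.null(h)) next
    D <- fossilbd:::count_diversity(h$ts, h$te, c(96, 76.5, 66.5))
    up <- up + (D[2] > D[1])
    down <- down + (D[3] < D[2])
  }
  # sign test: growth before 76 Ma and decline after, p < 0.01
  expect_lt(stats::binom.test(up, n, 0.5, "greater")$p.value, 0.01)
  expect_lt(stats::binom.test(down, n, 0.5, "greater")$p.value, 0.01)
})

test_that("fossil sampling matches the preservation model's Poisson counts", {
  # 4000 species of lifespan 10 Myr at q = 0.5: mean count ~ Poisson(5)
  n <- 4000
  h <- fossilbd:::new_history(ts = rep(76, n), te = rep(66, n),
                              parent = c(0L, rep(1L, n - 1L)),
                              extant = rep(FALSE, n), "flat", 1, NULL)
  occ <- sample_fossils(h, preservation_model("HPP", 0.5), seed = 9)
  expect_lt(abs(nrow(occ) / n - 5), 3 * sqrt(5 / n))
  expect_true(all(occ$min_age >= 66 & occ$min_age <= 76))

  # q -> 0: empty table
  occ0 <- sample_fossils(h[1:50, ], preservation_model("HPP", 1e-8),
                         seed = 1)
  expect_equal(nrow(occ0), 0L)

  # TPP with rate ~0 in the Maastrichtian: no occurrences dated there
  g <- default_stage_grid()
  q <- rep(2, nrow(g)); q[g$stage == "Maastrichtian"] <- 1e-12
  occ_t <- sample_fossils(h[1:500, ], preservation_model("TPP", q, grid = g),
                          seed = 4)
  st <- stage_of(g, occ_t$min_age)
  expect_false(any(g$stage[st] == "Maastrichtian"))

  # NHPP concentrates occurrences mid-lifespan (hump)
  occ_n <- sample_fossils(h, preservation_model("NHPP", 0.5), seed = 5)
  u <- (76 - occ_n$min_age) / 10
  expect_gt(mean(u > 0.25 & u < 0.75), 0.55)   # Beta(2,2): 68.75% expected
})

test_that("stage-level age uncertainty brackets the true age", {
  g <- default_stage_grid()
  sh <- fbd_shift_clade()
  occ <- sh$occ
  unc <- impose_age_uncertainty(occ, g)
  expect_true(all(unc$min_age <= occ$min_age & occ$min_age <= unc$max_age))
  # boundary age goes to the younger stage
  b <- occurrence_table("X", 72.1, 72.1)
  ub <- impose_age_uncertainty(b, g)
  expect_equal(c(ub$max_age, ub$min_age), c(72.1, 66.0))
  # resampling the uncertain ages always brackets the truth
  rs <- resample_ages(unc, 3, seed = 2)
  for (r in rs) expect_true(all(r$age >= unc$min_age & r$age <= unc$max_age))
  # an age outside the grid errors
  expect_error(impose_age_uncertainty(occurrence_table("Y", 30, 30), g),
               "outside")
})

test_that("covariate regime with G = 0 is indistinguishable from piecewise", {
  tc <- fbd_temp_curve()
  reg_cov <- regime_covariate(0.25, 0.2, c(0), c(0), list(tc),
                              "exponential", 100, 66)
  reg_pw <- regime_piecewise(0.25, 0.2, numeric(), 100, 66)
  d1 <- c(); d2 <- c()
  for (s in 1:8) {
    h1 <- simulate_history(reg_cov, seed = 7000 + s, min_species = 50,
                           max_species = 600)
    h2 <- simulate_history(reg_pw, seed = 7500 + s, min_species = 50,
                           max_species = 600)
    d1 <- c(d1, (h1$ts - h1$te)[!h1$extant])
    d2 <- c(d2, (h2$ts - h2$te)[!h2$extant])
  }
  expect_gt(length(d1), 500)
  expect_gt(stats::ks.test(d1, d2)$p.value, 0.01)
})

test_that("ground-truth export round-trips", {
  h <- fbd_const_clade()$history
  f <- withr::local_tempfile(fileext = ".tsv")
  write_history(h, f)
  tt <- read_lineage_times(f)
  expect_equal(tt$ts, h$ts)
  expect_equal(tt$te, h$te)
  expect_equal(tt$extant, h$extant)
})
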