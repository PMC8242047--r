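test_that("preservation likelihood closed forms and model nesting", {
  # HPP, q = 1, Ts = 10, Te = 5, k = 3: -5 - log(1 - exp(-5))
  expect_equal(preservation_loglik(c(6, 7, 9), 10, 5,
                                   preservation_model("HPP", 1)),
               -5 - log(1 - exp(-5)), tolerance = 1e-10)
  expect_equal(round(preservation_loglik(c(6, 7, 9), 10, 5,
                                         preservation_model("HPP", 1)), 5),
               -4.99324)

  # TPP with all stage rates equal == HPP
  g <- default_stage_grid()
  m_t <- preservation_model("TPP", rep(1.7, nrow(g)), grid = g)
  m_h <- preservation_model("HPP", 1.7)
  ages <- c(67.3, 70.0, 74.2, 80.1)
  expect_equal(preservation_loglik(ages, 85, 66.5, m_t),
               preservation_loglik(ages, 85, 66.5, m_h), tolerance = 1e-10)

  # NHPP: hump rate integrates to q * lifespan
  q <- 1.5; ts <- 10; te <- 5
  rho <- function(t) q * 6 * ((ts - t) / (ts - te)) * (1 - (ts - t) / (ts - te))
  expect_equal(stats::integrate(rho, te, ts, rel.tol = 1e-10)$value,
               q * (ts - te), tolerance = 1e-8)

  # occurrences outside [te, ts] are rejected
  expect_error(preservation_loglik(c(4), 10, 5, m_h), "outside")
})

test_that("conditioned HPP likelihood is a proper distribution over counts", {
  q <- 0.8; ts <- 9; te <- 3; d <- ts - te
  m <- preservation_model("HPP", q)
  p_k <- vapply(1:80, function(k) {
    ll <- preservation_loglik(stats::runif(k, te, ts), ts, te, m)
    exp(ll + k * log(d) - lgamma(k + 1))
  }, 0.0)
  expect_equal(sum(p_k), 1, tolerance = 1e-6)
})

test_that("gamma heterogeneity: mean-one categories, homogeneous limit", {
  mcat <- fossilbd:::gamma_categories(0.7, 4)
  expect_equal(mean(mcat), 1)
  expect_true(all(diff(mcat) > 0))
  m_inf <- preservation_model("HPP", 2, gamma_alpha = 1e6)
  m_h <- preservation_model("HPP", 2)
  expect_equal(preservation_loglik(c(67, 70), 75, 66, m_inf),
               preservation_loglik(c(67, 70), 75, 66, m_h),
               tolerance = 1e-4)
  # permutation invariance of occurrence ages
  m_g <- preservation_model("NHPP", 2, gamma_alpha = 0.9)
  a <- c(67.5, 69.1, 72.4)
  expect_identical(preservation_loglik(a, 75, 66, m_g),
                   preservation_loglik(rev(a), 75, 66, m_g))
})

test_that("pp_model_test recovers the generating model", {
  g <- default_stage_grid()
  reg <- regime_piecewise(0.2, 0.1, numeric(), 100, 66)
  hit_h <- 0; hit_t <- 0; n_rep <- 12
  for (r in seq_len(n_rep)) {
    h <- simulate_history(reg, seed = 1800 + r, min_species = 150,
                          max_species = 350)
    # HPP-generated data: HPP within 2 AICc of the best model
    occ <- sample_fossils(h, preservation_model("HPP", 1), seed = 1900 + r)
    tt <- true_times(h, taxa = sort(unique(occ$taxon)))
    pt <- pp_model_test(occ, tt, g, gamma = FALSE)
    hit_h <- hit_h + (pt$AICc[pt$model == "HPP"] - min(pt$AICc) <= 2)
    # TPP-generated data with a 5-fold Maastrichtian jump: TPP best
    q <- rep(1, nrow(g)); q[g$stage == "Maastrichtian"] <- 5
    occ2 <- sample_fossils(h, preservation_model("TPP", q, grid = g),
                           seed = 1950 + r)
    tt2 <- true_times(h, taxa = sort(unique(occ2$taxon)))
    hit_t <- hit_t + (attr(pp_model_test(occ2, tt2, g, gamma = FALSE),
                           "best") == "TPP")
  }
  expect_gte(hit_h, ceiling(0.9 * n_rep))   # scaled down from 50 replicates
  expect_gte(hit_t, ceiling(0.9 * n_rep))
})

test_that("single taxon in a single stage: TPP and HPP agree up to penalty", {
  g <- default_stage_grid()
  occ <- occurrence_table(rep("X", 4), c(67, 68, 69, 70), c(67, 68, 69, 70))
  tt <- lineage_times("X", 71.5, 66.5)
  pt <- pp_model_test(occ, tt, g, gamma = FALSE)
  expect_equal(pt$logL[pt$model == "TPP"], pt$logL[pt$model == "HPP"],
               tolerance = 1e-4)
})

test_that("stage-wise preservation rates are recovered with coverage", {
  g <- default_stage_grid()
  reg <- regime_piecewise(0.2, 0.1, numeric(), 100, 66)
  h <- simulate_history(reg, seed = 77, min_species = 200,
                        max_species = 450)
  q_true <- rep(2, nrow(g)); q_true[g$stage == "Maastrichtian"] <- 7
  occ <- sample_fossils(h, preservation_model("TPP", q_true, grid = g),
                        seed = 78)
  tt <- true_times(h, taxa = sort(unique(occ$taxon)))
  qs <- sample_preservation_rates(occ, tt, g, iterations = 6000,
                                  sampling_freq = 10, seed = 79)
  prt <- preservation_rate_through_time(qs[-(1:100), , drop = FALSE], g)
  maas <- prt[prt$stage == "Maastrichtian", ]
  expect_gt(maas$mean_q, 6)
  expect_lt(maas$mean_q, 8)
  # stages with real lineage overlap: 95% CI covers the truth
  ov <- fossilbd:::stage_overlap(g, tt$ts, tt$te)
  active <- colSums(ov) > 5
  expect_true(all(prt$ci_low[active] <= q_true[active] + 1e-9 &
                    prt$ci_high[active] >= q_true[active] - 1e-9))
  # degenerate: identical samples give zero-width intervals
  flat <- matrix(2, 50, nrow(g))
  p0 <- preservation_rate_through_time(flat, g)
  expect_true(all(p0$ci_high - p0$ci_low == 0))
})
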