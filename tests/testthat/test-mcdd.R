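test_that("interaction rates: exact per-species percentage semantics", {
  D <- matrix(c(0, 1, 0, 0), 2, 2)      # clade 1 diversity rises by 1
  gl <- matrix(0, 2, 2); gl[2, 1] <- 0.1
  gm <- matrix(0, 2, 2); gm[2, 1] <- 0.2
  ir <- interaction_rates(c(0.3, 0.3), c(0.1, 0.1), gl, gm, D)
  # one added species of clade 1: clade 2 speciation -10%, extinction +20%
  expect_equal(ir$lambda[2, 2], 0.3 * 0.9)
  expect_equal(ir$mu[2, 2], 0.1 * 1.2)
  # zero coefficients leave baselines untouched
  ir0 <- interaction_rates(c(0.3, 0.3), c(0.1, 0.1), matrix(0, 2, 2),
                           matrix(0, 2, 2), D)
  expect_true(all(ir0$lambda == 0.3) && all(ir0$mu == 0.1))
  # truncation at zero once the summed effect reaches 100%
  glx <- matrix(0, 2, 2); glx[2, 1] <- 1.5
  irx <- interaction_rates(c(0.3, 0.3), c(0.1, 0.1), glx,
                           matrix(0, 2, 2), D)
  expect_equal(irx$lambda[2, 2], 0)
})

test_that("one-clade MCDD equals a single-clade diversity-dependent model", {
  h <- fbd_const_clade()$history
  tt <- true_times(h)
  par <- list(lambda0 = 0.25, mu0 = 0.12, g_lambda = 0.01, g_mu = 0.02)
  win <- c(max(tt$ts), min(tt$te))
  got <- mcdd_loglik(list(tt), par, step = 0.1, window = win)
  # independent oracle: same linear diversity dependence written directly
  ages <- seq(win[1], win[2], by = -0.1)
  older <- ages[-length(ages)]; younger <- ages[-1]
  D <- vapply(older, function(a) sum(tt$te <= a & a < tt$ts), 0L)
  lam <- par$lambda0 * pmax(0, 1 - par$g_lambda * D)
  mu <- par$mu0 * pmax(0, 1 + par$g_mu * D)
  A <- vapply(seq_along(older), function(j)
    sum(pmax(0, pmin(tt$ts, older[j]) - pmax(tt$te, younger[j]))), 0.0)
  cell <- function(x) max(1L, min(findInterval(-x, -older), length(older)))
  oracle <- sum(log(lam[vapply(tt$ts, cell, 1L)])) +
    sum(log(mu[vapply(tt$te[!tt$extant], cell, 1L)])) -
    sum((lam + mu) * A)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("clade relabeling permutes the likelihood consistently", {
  sh <- fbd_shift_clade()$history
  cl <- fbd_const_clade()$history
  t1 <- true_times(sh); t2 <- true_times(cl)
  gl <- matrix(c(0.01, 0.004, -0.003, 0.02), 2, 2)
  gm <- matrix(c(0.02, -0.01, 0.015, 0.005), 2, 2)
  par12 <- list(lambda0 = c(0.2, 0.3), mu0 = c(0.1, 0.15),
                g_lambda = gl, g_mu = gm)
  perm <- c(2, 1)
  par21 <- list(lambda0 = par12$lambda0[perm], mu0 = par12$mu0[perm],
                g_lambda = gl[perm, perm], g_mu = gm[perm, perm])
  win <- c(max(t1$ts, t2$ts), min(t1$te, t2$te))
  expect_equal(mcdd_loglik(list(t1, t2), par12, window = win),
               mcdd_loglik(list(t2, t1), par21, window = win),
               tolerance = 1e-10)
})

test_that("competition on speciation slows diversity growth (paired sims)", {
  diff <- numeric(16)
  for (s in seq_along(diff)) {
    h0 <- simulate_history(regime_diversity(0.3, 0.1, 0, 0, 100, 66),
                           seed = 9000 + s, min_species = 2,
                           max_attempts = 50)
    h1 <- simulate_history(regime_diversity(0.3, 0.1, 0.05, 0, 100, 66),
                           seed = 9000 + s, min_species = 2,
                           max_attempts = 50)
    diff[s] <- nrow(h1) - nrow(h0)
  }
  expect_lte(mean(diff), 0)
})

test_that("MCDD sampler: determinism, planted-edge recovery, null safety", {
  s1 <- fbd_mcdd_replicate(1, iterations = 1200)
  s2 <- fbd_mcdd_replicate(1, iterations = 1200)
  expect_identical(s1, s2)

  # planted +15%/species effect of B on A's extinction is found (full
  # 20-replicate loop in the acceptance suite)
  s <- fbd_mcdd_replicate(2)
  row <- s[s$clade_i == "A" & s$clade_j == "B" & s$rate == "mu", ]
  expect_gt(row$median, 0)
  expect_gt(row$p_competition, 0.9)
  # and reported as exactly one cross-clade edge in the network
  net <- interaction_network(s, threshold = 0.95)
  cross <- net[net$clade_i != net$clade_j, ]
  expect_equal(nrow(cross), 1L)
  expect_equal(cross$clade_i, "A")
  expect_equal(cross$clade_j, "B")
  expect_equal(cross$rate, "mu")
  expect_equal(cross$type, "competition")

  # threshold above 1 never reports edges; an all-zero posterior never does
  expect_equal(nrow(interaction_network(s, threshold = 1.01)), 0L)
  z <- s; z$p_competition <- 0; z$p_positive <- 0
  expect_equal(nrow(interaction_network(z)), 0L)

  # non-interacting clades: no spurious off-diagonal signals (scaled:
  # 3 of the acceptance suite's replicates)
  for (r in 1:3) {
    s0 <- fbd_mcdd_replicate(r, g_ab = 0, seed_base = 3000)
    off <- s0[s0$clade_i != s0$clade_j, ]
    expect_true(all(pmax(off$p_competition, off$p_positive) < 0.9))
  }
})
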