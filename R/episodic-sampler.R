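#' Joint Bayesian sampler for lineage times and episodic birth--death rates
#'
#' Samples, from a fixed-age fossil occurrence dataset, the joint posterior
#' of (i) the preservation parameters, (ii) every species' times of
#' speciation and extinction (`Ts`, `Te`), and (iii) piecewise-constant
#' speciation and extinction rates with an unknown number of shifts.  Two
#' trans-dimensional algorithms are available and should agree on shared
#' data: `rjmcmc_sample()` uses reversible-jump moves (add / remove / move
#' a shift) with Green's acceptance ratio; `bdmcmc_sample()` runs a
#' continuous-time birth--death process over shift points whose death rates
#' are likelihood ratios.  Within a configuration the rates are
#' Gibbs-sampled from their Gamma full conditionals and the lineage times
#' are updated by vectorized Metropolis--Hastings sweeps under the hard
#' constraint that `Ts >=` oldest and `Te <=` youngest occurrence of the
#' species.
#'
#' Priors: rates `Gamma(1.1, 1)`; number of shifts `Poisson(eps)` for
#' speciation and extinction independently; shift times uniform over the
#' observed occurrence span; preservation rate(s) `Gamma(1.1, 0.1)`;
#' gamma-heterogeneity shape `Gamma(1, 0.5)`.  Proposal windows are tuned
#' to 20--40% acceptance during burn-in and frozen afterwards.
#'
#' @param data an `age_resampled` dataset (see [resample_ages]) or an
#'   [occurrence_table] with exact ages.
#' @param model preservation flavour: `"HPP"`, `"NHPP"` or `"TPP"`.
#' @param grid [stage_grid] (needed for TPP).
#' @param gamma logical: gamma rate heterogeneity across taxa (shape
#'   sampled).
#' @param iterations,sampling_freq chain length and thinning.
#' @param eps Poisson prior mean on the number of shifts (per rate vector).
#' @param seed integer seed; fixed seeds give identical traces.
#' @param q_fixed optional fixed preservation rate (skips q updates).
#' @param extant_age age (Ma) at which extant/censored species' `Te` is
#'   pinned (0 for recent datasets; the simulation end age for synthetic
#'   clades with survivors).
#' @param burnin fraction of iterations used for proposal tuning.
#' @param update_fraction fraction of species whose times are proposed per
#'   sweep.
#' @param span optional fixed `c(older, younger)` window for the shift-time
#'   prior and output grid (set a common span when pooling age-randomized
#'   replicates); defaults to the observed occurrence span.
#' @return a `bd_trace` object; see [rate_through_time],
#'   [posterior_lineage_times], [combine_replicates].
#' @export
rjmcmc_sample <- function(data, model = "HPP", grid = default_stage_grid(),
                          gamma = FALSE, iterations = 20000,
                          sampling_freq = 20, eps = 1, seed = 1L,
                          q_fixed = NULL, extant_age = 0, burnin = 0.1,
                          update_fraction = 0.2, span = NULL) {
  bd_engine(data, model, grid, gamma, iterations, sampling_freq, eps, seed,
            q_fixed, extant_age, burnin, update_fraction,
            algorithm = "rjmcmc", span = span)
}

#' @rdname rjmcmc_sample
#' @export
bdmcmc_sample <- function(data, model = "HPP", grid = default_stage_grid(),
                          gamma = FALSE, iterations = 20000,
                          sampling_freq = 20, eps = 1, seed = 1L,
                          q_fixed = NULL, extant_age = 0, burnin = 0.1,
                          update_fraction = 0.2, span = NULL) {
  bd_engine(data, model, grid, gamma, iterations, sampling_freq, eps, seed,
            q_fixed, extant_age, burnin, update_fraction,
            algorithm = "bdmcmc", span = span)
}

# per-species BD contributions with separate shift sets for lambda and mu
bd_species_ll2 <- function(ts, te, extant, sl, rl, sm, rm) {
  lam_ts <- step_rate_at(ts, sl, rl)
  mu_te <- step_rate_at(te, sm, rm)
  il <- step_integral_vec(ts, te, sl, rl)
  im <- step_integral_vec(ts, te, sm, rm)
  log(lam_ts) + ifelse(extant, 0, log(mu_te)) - il - im
}

step_integral_vec <- function(ts, te, s, r) {
  if (length(s) == 0L) return(r[1] * (ts - te))
  n <- length(ts)
  older <- c(Inf, s)
  younger <- c(s, -Inf)
  OV <- pmax(pmin(matrix(older, n, length(older), byrow = TRUE), ts) -
               pmax(matrix(younger, n, length(younger), byrow = TRUE), te), 0)
  as.vector(OV %*% r)
}

# B (or D) event counts and S exposures for one rate vector's shift set
event_stats <- function(x_events, ts, te, s) {
  k <- length(s) + 1L
  older <- c(Inf, s)
  younger <- c(s, -Inf)
  E <- S <- numeric(k)
  for (j in seq_len(k)) {
    E[j] <- sum(x_events <= older[j] & x_events > younger[j])
    S[j] <- sum(pmax(0, pmin(ts, older[j]) - pmax(te, younger[j])))
  }
  # events exactly at the youngest te boundary: none below -Inf, fine
  list(E = E, S = S)
}

part_lik <- function(E, S, r) sum(E * log(r) - r * S)

bd_engine <- function(data, model, grid, gamma, iterations, sampling_freq,
                      eps, seed, q_fixed, extant_age, burnin,
                      update_fraction, algorithm, span = NULL) {
  model <- match.arg(model, c("HPP", "NHPP", "TPP"))
  pd <- prepare_pres_data(data, if (model == "TPP") grid else NULL)
  set.seed(seed)
  n <- pd$n
  extant <- pd$extant & !is.na(pd$extant)
  if (is.null(span))
    span <- c(max(pd$oldest),
              if (any(extant)) min(min(pd$youngest), extant_age)
              else min(pd$youngest))
  # state ---------------------------------------------------------------
  ts <- pd$oldest + stats::rexp(n, 2)
  te <- ifelse(extant, extant_age,
               pmax(extant_age, pd$youngest - stats::rexp(n, 2)))
  te <- pmin(te, pd$youngest - ifelse(extant, 0, 1e-6))
  te <- pmax(te, 0)
  sl <- numeric(); sm <- numeric()
  rl <- max(n / max(sum(ts - te), 1), 0.05)
  rm <- rl
  qinit <- pd$n_occ / max(sum(ts - te), 1)
  q <- if (!is.null(q_fixed)) q_fixed
       else if (model == "TPP") rep(max(qinit, 0.05), nrow(grid))
       else max(qinit, 0.05)
  alpha <- if (gamma) 1 else NULL
  ga <- function() if (gamma) alpha else NULL
  pres_ll <- pres_loglik_vec(pd, ts, te, q, model, ga())
  w_t <- 1.5     # proposal window for ts/te (tuned in burn-in)
  n_tune_acc <- 0; n_tune_try <- 0
  nburn <- floor(burnin * iterations)
  n_keep <- floor(iterations / sampling_freq)
  keep <- list(stats = data.frame(iteration = integer(n_keep),
                                  posterior = numeric(n_keep),
                                  likelihood = numeric(n_keep),
                                  prior = numeric(n_keep),
                                  n_shifts_lambda = integer(n_keep),
                                  n_shifts_mu = integer(n_keep),
                                  q_mean = numeric(n_keep),
                                  lambda_mean = numeric(n_keep),
                                  mu_mean = numeric(n_keep)),
               lambda = vector("list", n_keep),
               mu = vector("list", n_keep),
               ts = matrix(NA_real_, n_keep, n),
               te = matrix(NA_real_, n_keep, n),
               q = vector("list", n_keep))
  kk <- 0L
  acc_win <- 0; try_win <- 0
  rate_prior <- function(r) sum(stats::dgamma(r, 1.1, 1, log = TRUE))
  q_prior <- function(q) sum(stats::dgamma(q, 1.1, 0.1, log = TRUE))
  TT <- span[1] - span[2]
  for (it in seq_len(iterations)) {
    # -- 1. lineage-time sweep (vectorized per-species MH) ---------------
    sel <- which(stats::runif(n) < update_fraction)
    if (length(sel)) {
      ts_p <- ts; te_p <- te
      ts_p[sel] <- ts[sel] + stats::runif(length(sel), -w_t, w_t)
      mv_te <- sel[!extant[sel]]
      te_p[mv_te] <- te[mv_te] + stats::runif(length(mv_te), -w_t, w_t)
      ok <- ts_p > pd$oldest & te_p <= pd$youngest & te_p >= 0 &
        (extant | te_p < pd$youngest) & ts_p > te_p
      fix <- !ok
      ts_p[fix] <- ts[fix]; te_p[fix] <- te[fix]
      bd_cur <- bd_species_ll2(ts, te, extant, sl, rl, sm, rm)
      bd_new <- bd_species_ll2(ts_p, te_p, extant, sl, rl, sm, rm)
      pres_new <- pres_loglik_vec(pd, ts_p, te_p, q, model, ga())
      lr <- (bd_new + pres_new) - (bd_cur + pres_ll)
      acc <- sel[ok[sel] & log(stats::runif(length(sel))) < lr[sel]]
      if (length(acc)) {
        ts[acc] <- ts_p[acc]; te[acc] <- te_p[acc]
        pres_ll2 <- pres_loglik_vec(pd, ts, te, q, model, ga())
        pres_ll <- pres_ll2
      }
      try_win <- try_win + sum(ok[sel])
      acc_win <- acc_win + length(acc)
      if (it <= nburn && try_win >= 200) {       # adapt toward 20-40%
        rate <- acc_win / try_win
        if (rate < 0.2) w_t <- w_t * 0.8
        if (rate > 0.4) w_t <- w_t * 1.25
        acc_win <- 0; try_win <- 0
      }
    }
    # -- 2. Gibbs update of rates ---------------------------------------
    stl <- event_stats(ts, ts, te, sl)
    rl <- stats::rgamma(length(sl) + 1L, 1.1 + stl$E, 1 + stl$S)
    stm <- event_stats(te[!extant], ts, te, sm)
    rm <- stats::rgamma(length(sm) + 1L, 1.1 + stm$E, 1 + stm$S)
    rl <- pmax(rl, 1e-8); rm <- pmax(rm, 1e-8)
    # -- 3. trans-dimensional move on each shift set --------------------
    if (algorithm == "rjmcmc") {
      up_l <- rj_move(ts, ts, te, sl, rl, span, eps)
      sl <- up_l$s; rl <- up_l$r
      up_m <- rj_move(te[!extant], ts, te, sm, rm, span, eps)
      sm <- up_m$s; rm <- up_m$r
    } else {
      up_l <- bdmcmc_move(ts, ts, te, sl, rl, span, eps)
      sl <- up_l$s; rl <- up_l$r
      up_m <- bdmcmc_move(te[!extant], ts, te, sm, rm, span, eps)
      sm <- up_m$s; rm <- up_m$r
    }
    # -- 4. preservation updates ----------------------------------------
    if (is.null(q_fixed)) {
      j <- if (model == "TPP") 1L + (it %% length(q)) else 1L
      qp <- q
      qp[j] <- q[j] * exp(stats::rnorm(1, 0, 0.2))
      pres_new <- pres_loglik_vec(pd, ts, te, qp, model, ga())
      lr <- sum(pres_new) - sum(pres_ll) + q_prior(qp) - q_prior(q) +
        log(qp[j] / q[j])
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        q <- qp; pres_ll <- pres_new
      }
    }
    if (gamma) {
      ap <- alpha * exp(stats::rnorm(1, 0, 0.3))
      pres_new <- pres_loglik_vec(pd, ts, te, q, model, ap)
      lr <- sum(pres_new) - sum(pres_ll) +
        stats::dgamma(ap, 1, 0.5, log = TRUE) -
        stats::dgamma(alpha, 1, 0.5, log = TRUE) + log(ap / alpha)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        alpha <- ap; pres_ll <- pres_new
      }
    }
    # -- record ----------------------------------------------------------
    if (it %% sampling_freq == 0L) {
      kk <- kk + 1L
      stl <- event_stats(ts, ts, te, sl)
      stm <- event_stats(te[!extant], ts, te, sm)
      lik <- sum(pres_ll) + part_lik(stl$E, stl$S, rl) +
        part_lik(stm$E, stm$S, rm)
      pri <- rate_prior(rl) + rate_prior(rm) +
        stats::dpois(length(sl), eps, log = TRUE) +
        stats::dpois(length(sm), eps, log = TRUE) +
        (if (is.null(q_fixed)) q_prior(q) else 0)
      keep$stats[kk, ] <- list(it, lik + pri, lik, pri, length(sl),
                               length(sm), mean(q), mean(rl), mean(rm))
      keep$lambda[[kk]] <- list(s = sl, r = rl)
      keep$mu[[kk]] <- list(s = sm, r = rm)
      keep$ts[kk, ] <- ts
      keep$te[kk, ] <- te
      keep$q[[kk]] <- q
    }
  }
  if (try_win + acc_win > 0 && nburn < iterations) {
    final_rate <- acc_win / max(try_win, 1)
    if (final_rate < 0.01)
      warning("lineage-time acceptance below 1%; chain may not be mixing")
  }
  structure(list(stats = keep$stats[seq_len(kk), ],
                 lambda = keep$lambda[seq_len(kk)],
                 mu = keep$mu[seq_len(kk)],
                 ts = keep$ts[seq_len(kk), , drop = FALSE],
                 te = keep$te[seq_len(kk), , drop = FALSE],
                 q = keep$q[seq_len(kk)],
                 taxa = pd$taxa, extant = extant, span = span,
                 algorithm = algorithm, model = model, seed = seed,
                 settings = list(iterations = iterations,
                                 sampling_freq = sampling_freq, eps = eps)),
            class = "bd_trace")
}

rj_move <- function(events, ts, te, s, r, span, eps) {
  k <- length(s)
  u <- stats::runif(1)
  st0 <- event_stats(events, ts, te, s)
  l0 <- part_lik(st0$E, st0$S, r)
  if (u < 1 / 3) {                       # add
    tstar <- stats::runif(1, span[2], span[1])
    j <- findInterval(-tstar, -s) + 1L   # interval being split
    rnew <- stats::rgamma(1, 1.1, 1)
    s2 <- sort(c(s, tstar), decreasing = TRUE)
    r2 <- append(r, rnew, after = j)     # younger half gets the new rate
    st1 <- event_stats(events, ts, te, s2)
    l1 <- part_lik(st1$E, st1$S, r2)
    if (log(stats::runif(1)) < l1 - l0 + log(eps) - log(k + 1))
      return(list(s = s2, r = r2))
  } else if (u < 2 / 3) {                # remove
    if (k == 0) return(list(s = s, r = r))
    j <- sample.int(k, 1L)
    s2 <- s[-j]
    r2 <- r[-(j + 1L)]                   # drop the younger side's rate
    st1 <- event_stats(events, ts, te, s2)
    l1 <- part_lik(st1$E, st1$S, r2)
    if (log(stats::runif(1)) < l1 - l0 + log(k) - log(eps))
      return(list(s = s2, r = r2))
  } else {                               # move a shift between neighbours
    if (k == 0) return(list(s = s, r = r))
    j <- sample.int(k, 1L)
    lo <- if (j == k) span[2] else s[j + 1]
    hi <- if (j == 1) span[1] else s[j - 1]
    s2 <- s
    s2[j] <- stats::runif(1, lo, hi)
    st1 <- event_stats(events, ts, te, s2)
    l1 <- part_lik(st1$E, st1$S, r)
    if (log(stats::runif(1)) < l1 - l0) return(list(s = s2, r = r))
  }
  list(s = s, r = r)
}

# continuous-time birth-death process over shift points (one unit of
# virtual time per call).  With birth intensity eps and new points drawn
# from the prior, detailed balance requires each shift's death rate to be
# the likelihood ratio without/with that shift.
bdmcmc_move <- function(events, ts, te, s, r, span, eps, max_events = 10L) {
  v <- 0
  for (step in seq_len(max_events)) {
    k <- length(s)
    st0 <- event_stats(events, ts, te, s)
    l0 <- part_lik(st0$E, st0$S, r)
    delta <- numeric(k)
    if (k > 0) {
      for (j in seq_len(k)) {
        st1 <- event_stats(events, ts, te, s[-j])
        delta[j] <- exp(min(part_lik(st1$E, st1$S, r[-(j + 1L)]) - l0, 50))
      }
    }
    tot <- eps + sum(delta)
    v <- v + stats::rexp(1, tot)
    if (v > 1) break
    if (stats::runif(1) < eps / tot) {   # birth from the prior
      tstar <- stats::runif(1, span[2], span[1])
      j <- findInterval(-tstar, -s) + 1L
      s <- sort(c(s, tstar), decreasing = TRUE)
      r <- append(r, stats::rgamma(1, 1.1, 1), after = j)
    } else {                              # death proportional to delta
      j <- sample.int(k, 1L, prob = delta)
      s <- s[-j]
      r <- r[-(j + 1L)]
    }
  }
  list(s = s, r = r)
}

#' One Metropolis--Hastings sweep over lineage times
#'
#' Updates each species' `Ts` and `Te` by a sliding-window proposal,
#' respecting `Ts >` oldest occurrence and `Te <=` youngest occurrence,
#' with acceptance governed by the product of the preservation and
#' birth--death likelihoods.  Used internally by the samplers; exposed for
#' testing and custom schemes.
#'
#' @param times a [lineage_times] (taxa must match `data`).
#' @param data an `age_resampled` dataset or exact-age [occurrence_table].
#' @param model a [preservation_model].
#' @param config a [shift_config].
#' @param window proposal half-width (Myr).
#' @param update_fraction fraction of species updated.
#' @return the updated [lineage_times].
#' @export
update_lineage_times <- function(times, data, model, config, window = 1.5,
                                 update_fraction = 1) {
  pd <- prepare_pres_data(data, model$grid)
  tt <- align_times(times, pd$taxa)
  ts <- tt$ts; te <- tt$te; extant <- tt$extant
  q <- model$q
  kind <- model$kind
  sel <- which(stats::runif(pd$n) < update_fraction)
  if (!length(sel)) return(times)
  ts_p <- ts; te_p <- te
  ts_p[sel] <- ts[sel] + stats::runif(length(sel), -window, window)
  mv <- sel[!extant[sel]]
  te_p[mv] <- te[mv] + stats::runif(length(mv), -window, window)
  ok <- ts_p > pd$oldest & te_p <= pd$youngest & te_p >= 0 & ts_p > te_p
  ts_p[!ok] <- ts[!ok]; te_p[!ok] <- te[!ok]
  ll0 <- pres_loglik_vec(pd, ts, te, q, kind, model$gamma_alpha) +
    bd_species_loglik(ts, te, extant, config)
  ll1 <- pres_loglik_vec(pd, ts_p, te_p, q, kind, model$gamma_alpha) +
    bd_species_loglik(ts_p, te_p, extant, config)
  acc <- sel[ok[sel] & log(stats::runif(length(sel))) < (ll1 - ll0)[sel]]
  ts[acc] <- ts_p[acc]; te[acc] <- te_p[acc]
  lineage_times(pd$taxa, ts, te, extant)
}
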