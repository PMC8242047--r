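#' Preservation (fossil sampling) models
#'
#' The preservation process models fossil occurrence times of one taxon as a
#' Poisson process on its true lifespan `[Te, Ts]`, conditioned on at least
#' one occurrence (otherwise the taxon would be unobserved).  Three
#' flavours:
#'
#' * `HPP` — homogeneous: constant rate `q` occurrences/species/Myr.
#' * `NHPP` — lifespan hump: rate `q * 6u(1-u)` with
#'   `u = (Ts - t)/(Ts - Te)`, low near both range ends, integrating to
#'   `q * (Ts - Te)` over the lifespan.
#' * `TPP` — time-variable: one rate per geological stage of `grid`.
#'
#' The gamma model multiplies each taxon's rate by a mean-one
#' Gamma(`gamma_alpha`, `gamma_alpha`) factor, discretized into
#' `n_categories` equal-weight categories (category medians, renormalized
#' to mean one).
#'
#' @param kind `"HPP"`, `"NHPP"` or `"TPP"`.
#' @param q rate (occ/species/Myr); for `TPP` a vector with one rate per
#'   stage of `grid`.
#' @param grid a [stage_grid] (required for `TPP`).
#' @param gamma_alpha optional shape (> 0) of across-taxon rate multipliers.
#' @param n_categories number of discretized gamma categories (default 4).
#' @export
preservation_model <- function(kind = c("HPP", "NHPP", "TPP"), q = 1,
                               grid = NULL, gamma_alpha = NULL,
                               n_categories = 4L) {
  kind <- match.arg(kind)
  if (kind == "TPP") {
    if (is.null(grid)) stop_fbd("TPP model needs a stage grid")
    if (length(q) != nrow(grid))
      stop_fbd("TPP rate vector length must equal the number of stages")
  } else if (length(q) != 1L) stop_fbd(kind, " uses a single rate")
  if (any(q <= 0)) stop_fbd("preservation rates must be > 0")
  if (!is.null(gamma_alpha) && gamma_alpha <= 0)
    stop_fbd("gamma_alpha must be > 0")
  structure(list(kind = kind, q = q, grid = grid, gamma_alpha = gamma_alpha,
                 n_categories = as.integer(n_categories)),
            class = "preservation_model")
}

# mean-one discretized gamma multipliers (category medians, renormalized)
gamma_categories <- function(alpha, n_categories = 4L) {
  m <- stats::qgamma((seq_len(n_categories) - 0.5) / n_categories,
                     shape = alpha, rate = alpha)
  m / mean(m)
}

#' Preservation log-likelihood of one taxon
#'
#' Log-probability of the observed occurrence ages of a single taxon given
#' its (latent) speciation and extinction times, under a conditioned
#' Poisson process (at least one occurrence).  For the homogeneous process
#' with `k` occurrences over lifespan `d = ts - te`:
#' `k*log(q) - q*d - log(1 - exp(-q*d))`.
#'
#' @param occ_ages occurrence ages of the taxon (Ma); all must lie within
#'   `[te, ts]` and `k >= 1`.
#' @param ts,te speciation and extinction times (Ma), `ts > te`.
#' @param model a [preservation_model].
#' @return log-likelihood (scalar).
#' @export
preservation_loglik <- function(occ_ages, ts, te, model) {
  stopifnot(inherits(model, "preservation_model"), length(occ_ages) >= 1)
  if (ts <= te) stop_fbd("ts must exceed te")
  if (any(occ_ages > ts + 1e-12) || any(occ_ages < te - 1e-12))
    stop_fbd("occurrences outside [te, ts]")
  mult <- if (is.null(model$gamma_alpha)) 1
          else gamma_categories(model$gamma_alpha, model$n_categories)
  ll <- vapply(mult, function(m) pres_ll_one(occ_ages, ts, te, model, m),
               0.0)
  log_sum_exp(ll) - log(length(ll))
}

pres_ll_one <- function(occ_ages, ts, te, model, m) {
  d <- ts - te
  k <- length(occ_ages)
  switch(model$kind,
    HPP = {
      q <- model$q * m
      k * log(q) - q * d - log1mexp(q * d)
    },
    NHPP = {
      q <- model$q * m
      u <- (ts - occ_ages) / d
      if (any(u <= 0) || any(u >= 1)) return(-Inf)
      k * log(q) + sum(log(6 * u * (1 - u))) - q * d - log1mexp(q * d)
    },
    TPP = {
      qs <- model$q * m
      idx <- stage_of(model$grid, occ_ages)
      if (anyNA(idx)) stop_fbd("occurrence ages outside the stage grid")
      ov <- stage_overlap(model$grid, ts, te)[1, ]
      lam <- sum(qs * ov)
      sum(log(qs[idx])) - lam - log1mexp(lam)
    })
}

# log(1 - exp(-x)) for x > 0, numerically stable
log1mexp <- function(x) {
  ifelse(x > log(2), log1p(-exp(-x)), log(-expm1(-x)))
}

# ---- vectorized preservation machinery used by the samplers -------------

# Precompute per-taxon occurrence statistics from an age-resampled dataset
# (fixed age per occurrence).
prepare_pres_data <- function(data, grid = NULL) {
  if (inherits(data, "occurrence_table")) {
    if (any(data$min_age != data$max_age))
      stop_fbd("fix occurrence ages first (resample_ages or midpoint_ages)")
    data <- midpoint_ages(data)
  }
  stopifnot(inherits(data, "age_resampled"))
  taxa <- sort(unique(data$taxon))
  sp <- match(data$taxon, taxa)
  k <- tabulate(sp, length(taxa))
  spf <- factor(sp, levels = seq_along(taxa))
  oldest <- vapply(split(data$age, spf), max, 0.0)
  youngest <- vapply(split(data$age, spf), min, 0.0)
  extant <- vapply(split(data$status == "extant", spf), any, NA)
  out <- list(taxa = taxa, n = length(taxa), k = k, oldest = oldest,
              youngest = youngest, ages = data$age, sp = sp,
              extant = extant, n_occ = nrow(data), grid = grid)
  if (!is.null(grid)) {
    idx <- stage_of(grid, data$age)
    if (anyNA(idx)) stop_fbd("occurrence ages outside the stage grid")
    K <- matrix(0L, length(taxa), nrow(grid))
    tab <- table(factor(sp, levels = seq_along(taxa)),
                 factor(idx, levels = seq_len(nrow(grid))))
    K[] <- as.integer(tab)
    out$K <- K
    out$stage_idx <- idx
  }
  out
}

# Per-taxon preservation log-likelihood vector given (ts, te) vectors and a
# rate parameterization.  `q` is scalar (HPP/NHPP) or a per-stage vector
# (TPP with pd$grid).  Gamma heterogeneity is marginalized over categories.
pres_loglik_vec <- function(pd, ts, te, q, kind = "HPP",
                            gamma_alpha = NULL, n_categories = 4L,
                            condition = TRUE) {
  mult <- if (is.null(gamma_alpha)) 1
          else gamma_categories(gamma_alpha, n_categories)
  d <- ts - te
  base <- switch(kind,
    HPP = NULL,
    NHPP = {
      u <- (ts[pd$sp] - pd$ages) / d[pd$sp]
      lg <- rep(-Inf, length(u))
      uok <- u > 0 & u < 1
      lg[uok] <- log(6 * u[uok] * (1 - u[uok]))
      rowsum_vec(lg, pd$sp, pd$n)   # -Inf only for the offending species
    },
    TPP = NULL)
  ll <- matrix(0, pd$n, length(mult))
  for (c in seq_along(mult)) {
    m <- mult[c]
    ll[, c] <- switch(kind,
      HPP = {
        lam <- q * m * d
        pd$k * log(q * m) - lam - if (condition) log1mexp(lam) else 0
      },
      NHPP = {
        lam <- q * m * d
        pd$k * log(q * m) + base - lam - if (condition) log1mexp(lam) else 0
      },
      TPP = {
        ov <- stage_overlap(pd$grid, ts, te)
        lam <- as.vector(ov %*% (q * m))
        as.vector(pd$K %*% log(q * m)) - lam -
          if (condition) log1mexp(lam) else 0
      })
  }
  if (length(mult) == 1) ll[, 1]
  else apply(ll, 1, log_sum_exp) - log(length(mult))
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Compare preservation models by AICc
#'
#' Maximizes each candidate model's likelihood over its rate parameters for
#' fixed lineage times and ranks the models by AICc (small-sample corrected
#' AIC; the sample size is the number of occurrences).  Parameter counts:
#' one rate for HPP/NHPP, one per stage with nonzero lineage overlap for
#' TPP, plus one shape parameter for each gamma variant.
#'
#' @param data an `age_resampled` dataset (or [occurrence_table] with exact
#'   ages).
#' @param times a [lineage_times] with one entry per taxon in `data`.
#' @param grid a [stage_grid] (for the TPP candidate).
#' @param gamma also fit gamma-heterogeneity variants (default TRUE).
#' @return a data frame (model, n_par, logL, AICc, dAICc) sorted by AICc,
#'   with the best model name in `attr(, "best")`.
#' @export
pp_model_test <- function(data, times, grid = default_stage_grid(),
                          gamma = TRUE) {
  pd <- prepare_pres_data(data, grid)
  tt <- align_times(times, pd$taxa)
  ts <- tt$ts; te <- tt$te
  n <- pd$n_occ
  ov <- stage_overlap(grid, ts, te)
  active <- which(colSums(ov) > 0)
  fits <- list()
  fit1 <- function(kind, alpha = NULL) {
    f <- function(lq) -sum(pres_loglik_vec(pd, ts, te, exp(lq), kind,
                                           gamma_alpha = alpha))
    opt <- stats::optimize(f, c(-8, 5))
    list(logL = -opt$objective, par = exp(opt$minimum))
  }
  fit_tpp <- function(alpha = NULL) {
    q0 <- rep(max(pd$n_occ / max(sum(ov), 1e-9), 1e-3), length(active))
    f <- function(lq) {
      q <- rep(1e-10, nrow(grid))
      q[active] <- exp(lq)
      -sum(pres_loglik_vec(pd, ts, te, q, "TPP", gamma_alpha = alpha))
    }
    opt <- stats::optim(log(q0), f, method = "BFGS",
                        control = list(maxit = 300))
    list(logL = -opt$value, par = exp(opt$par))
  }
  fit_gamma <- function(kind) {
    if (kind == "TPP") {
      f <- function(la) fit_tpp(exp(la))$logL
    } else {
      f <- function(la) fit1(kind, exp(la))$logL
    }
    opt <- stats::optimize(function(la) -f(la), c(log(0.05), log(50)))
    list(logL = -opt$objective, alpha = exp(opt$minimum))
  }
  rows <- list()
  add <- function(model, np, logL) {
    aicc <- -2 * logL + 2 * np + if (n - np - 1 > 0) 2 * np * (np + 1) / (n - np - 1) else Inf
    rows[[length(rows) + 1L]] <<- data.frame(model = model, n_par = np,
                                             logL = logL, AICc = aicc)
  }
  add("HPP", 1L, fit1("HPP")$logL)
  add("NHPP", 1L, fit1("NHPP")$logL)
  add("TPP", length(active), fit_tpp()$logL)
  if (gamma) {
    add("HPP+G", 2L, fit_gamma("HPP")$logL)
    add("NHPP+G", 2L, fit_gamma("NHPP")$logL)
    add("TPP+G", length(active) + 1L, fit_gamma("TPP")$logL)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$AICc), ]
  out$dAICc <- out$AICc - out$AICc[1]
  rownames(out) <- NULL
  attr(out, "best") <- out$model[1]
  out
}

#' Posterior sampling of stage-wise preservation rates
#'
#' Metropolis sampling of the per-stage preservation rates of a TPP model
#' for fixed lineage times, with independent Gamma(1.1, 0.1) priors.
#'
#' @param data an `age_resampled` dataset or exact-age [occurrence_table].
#' @param times a [lineage_times].
#' @param grid a [stage_grid].
#' @param iterations,sampling_freq chain length and thinning.
#' @param seed integer seed.
#' @param gamma_alpha optional fixed across-taxon heterogeneity shape.
#' @return matrix of sampled rates (samples x stages), stage names as
#'   column names.
#' @export
sample_preservation_rates <- function(data, times, grid = default_stage_grid(),
                                      iterations = 10000, sampling_freq = 10,
                                      seed = 1L, gamma_alpha = NULL) {
  pd <- prepare_pres_data(data, grid)
  tt <- align_times(times, pd$taxa)
  ts <- tt$ts; te <- tt$te
  set.seed(seed)
  J <- nrow(grid)
  ov <- stage_overlap(grid, ts, te)
  active <- which(colSums(ov) > 0)
  q <- rep(max(pd$n_occ / max(sum(ov), 1e-9), 1e-2), J)
  ll <- sum(pres_loglik_vec(pd, ts, te, q, "TPP", gamma_alpha))
  lp <- sum(stats::dgamma(q[active], 1.1, 0.1, log = TRUE))
  keep <- matrix(NA_real_, floor(iterations / sampling_freq), J)
  colnames(keep) <- grid$stage
  kk <- 0L
  for (it in seq_len(iterations)) {
    j <- active[1L + (it %% length(active))]
    qp <- q
    qp[j] <- q[j] * exp(stats::rnorm(1, 0, 0.25))
    llp <- sum(pres_loglik_vec(pd, ts, te, qp, "TPP", gamma_alpha))
    lpp <- sum(stats::dgamma(qp[active], 1.1, 0.1, log = TRUE))
    # multiplicative proposal: Jacobian log(qp/q)
    if (log(stats::runif(1)) < llp + lpp - ll - lp + log(qp[j] / q[j])) {
      q <- qp; ll <- llp; lp <- lpp
    }
    if (it %% sampling_freq == 0L) {
      kk <- kk + 1L
      keep[kk, ] <- q
    }
  }
  keep[seq_len(kk), , drop = FALSE]
}

#' Per-stage preservation summary (mean and 95% CI)
#'
#' Summarizes posterior samples of stage-wise preservation rates into the
#' mean number of occurrences per species per Myr and its 95% credible
#' interval, per geological stage.
#'
#' @param q_samples samples x stages matrix (e.g. from
#'   [sample_preservation_rates]).
#' @param grid the matching [stage_grid].
#' @export
preservation_rate_through_time <- function(q_samples, grid) {
  stopifnot(ncol(q_samples) == nrow(grid))
  ci <- apply(q_samples, 2, ci95)
  data.frame(stage = grid$stage, base = grid$base, top = grid$top,
             mean_q = colMeans(q_samples),
             ci_low = ci[1, ], ci_high = ci[2, ])
}
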