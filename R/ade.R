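#' Weibull age-dependent extinction hazard
#'
#' Under age-dependent extinction (ADE), a species' longevity follows a
#' Weibull distribution with shape `phi` and scale (Myr), so the extinction
#' hazard at taxon age `t` is
#' `h(t) = (phi/scale) * (t/scale)^(phi - 1)`.
#' `phi = 1` recovers age-independent (constant-hazard, exponential)
#' extinction; `phi > 1` means older species face higher extinction risk.
#' The hazard ratio between two ages is `h(t2)/h(t1) = (t2/t1)^(phi - 1)`
#' for any positive ages, independent of the scale.
#'
#' @param t taxon age(s) in Myr (> 0).
#' @param shape Weibull shape `phi` (> 0).
#' @param scale Weibull scale in Myr (> 0).
#' @return hazard in events/lineage/Myr.
#' @examples
#' ade_hazard(1, shape = 1, scale = 4)          # constant 0.25
#' s <- ade_scale_for_hazard(1.733, hazard = 0.1705, t_ref = 1)
#' ade_hazard(c(0.1, 1, 10), 1.733, s)
#' @export
ade_hazard <- function(t, shape, scale) {
  if (any(t <= 0)) stop_fbd("taxon age must be > 0")
  stopifnot(shape > 0, scale > 0)
  (shape / scale) * (t / scale)^(shape - 1)
}

#' @rdname ade_hazard
#' @param hazard target hazard value at age `t_ref`.
#' @param t_ref reference taxon age (Myr).
#' @return `ade_scale_for_hazard()`: the scale such that
#'   `ade_hazard(t_ref, shape, scale) == hazard`.
#' @export
ade_scale_for_hazard <- function(shape, hazard, t_ref = 1) {
  stopifnot(shape > 0, hazard > 0, t_ref > 0)
  (shape * t_ref^(shape - 1) / hazard)^(1 / shape)
}

#' @rdname ade_hazard
#' @return `ade_mean_longevity()`: `scale * gamma(1 + 1/shape)`, the mean
#'   species longevity in Myr.
#' @export
ade_mean_longevity <- function(shape, scale) scale * gamma(1 + 1 / shape)

# P(species with Weibull(shape, scale) longevity is sampled at least once
# under HPP rate q) = 1 - E[exp(-q * d)].  The expectation is computed by
# the trapezoid rule after the substitution d = scale * exp(t), under which
# the integrand is smooth and decays (double-)exponentially at both ends,
# so a fixed grid is accurate to ~1e-10 for shapes in (0.1, 10).
ade_p_observed <- function(shape, scale, q) {
  t <- seq(-45 / min(shape, 1), 5, by = 0.05)
  et <- exp(t)
  g <- shape * exp(shape * t - exp(shape * t) - q * scale * et)
  1 - sum(g) * 0.05
}

#' ADE longevity log-likelihood
#'
#' Log-likelihood of species longevities (`Ts - Te`) under the Weibull ADE
#' model, optionally combined with the preservation process.  Uncensored
#' longevities contribute the Weibull log-density; species still alive at
#' the dataset's younger edge contribute the log-survival
#' `-(d/scale)^shape`; species whose `Ts` precedes the analysis window are
#' left-truncated at their age on window entry (the survival to that age is
#' divided out).
#'
#' @param times a [lineage_times]; `extant` entries are treated as
#'   right-censored.
#' @param shape,scale Weibull parameters.
#' @param window optional `c(older, younger)` ages (Ma) delimiting the
#'   analysis window (used only for left truncation of `Ts` older than the
#'   window base).
#' @return log-likelihood (scalar).
#' @export
ade_loglik <- function(times, shape, scale, window = NULL) {
  stopifnot(inherits(times, "lineage_times"), shape > 0, scale > 0)
  d <- times$ts - times$te
  if (any(d <= 0)) stop_fbd("non-positive longevity")
  ll <- ifelse(times$extant,
               -(d / scale)^shape,
               stats::dweibull(d, shape, scale, log = TRUE))
  if (!is.null(window)) {
    a <- pmax(0, times$ts - window[1])
    ll <- ll + (a / scale)^shape       # divide out S(truncation age)
  }
  sum(ll)
}

#' Joint MCMC for age-dependent extinction
#'
#' Samples the posterior of the Weibull shape `phi`, scale and the
#' homogeneous preservation rate `q`, jointly with every species' latent
#' `Ts` and `Te`, from a fixed-age occurrence dataset.  The likelihood is
#' the Weibull longevity density (with censoring/truncation as in
#' [ade_loglik]) times the preservation likelihood, normalized
#' for the fact that only species with at least one fossil are observed
#' (short-lived species are under-sampled, which would otherwise bias
#' `phi` upward).  ADE is declared when the 95% CI of `phi` excludes 1.
#'
#' Priors: `phi ~ LogNormal(0, 1)` (centred on age-independence),
#' `scale ~ Gamma(1.1, 0.1)`, `q ~ Gamma(1.1, 0.1)`.
#'
#' @param data an `age_resampled` dataset or exact-age [occurrence_table].
#' @param window optional analysis window `c(older, younger)` in Ma;
#'   species are assigned by their (provisional) extinction time and
#'   species entering the window already alive are left-truncated.  With
#'   `times` supplied, assignment uses those estimates.
#' @param times optional [lineage_times] (e.g. global posterior means) used
#'   only to assign species to the window.
#' @param iterations,sampling_freq chain length and thinning.
#' @param seed integer seed.
#' @param q_fixed optional fixed preservation rate.
#' @param extant_age censoring age for extant species (Ma).
#' @param correct_sampling include the `P(observed)` correction (default
#'   TRUE).
#' @return an `ade_trace` data frame (`phi`, `scale`, `q` samples);
#'   summarize with [ade_summary].
#' @export
ade_sample <- function(data, window = NULL, times = NULL,
                       iterations = 10000, sampling_freq = 10, seed = 1L,
                       q_fixed = NULL, extant_age = 0,
                       correct_sampling = TRUE) {
  pd <- prepare_pres_data(data)
  if (!is.null(window)) {
    prov <- if (!is.null(times)) align_times(times, pd$taxa)
            else lineage_times(pd$taxa, pd$oldest + 1e-6, pd$youngest - 1e-6,
                               extant = pd$extant & !is.na(pd$extant))
    inw <- prov$te <= window[1] & prov$te > window[2] & !prov$extant
    if (sum(inw) < 10)
      warning("fewer than 10 species in the analysis window")
    keep_taxa <- pd$taxa[inw]
    df <- as.data.frame(data)
    df <- df[df$taxon %in% keep_taxa, , drop = FALSE]
    class(df) <- class(data)
    attr(df, "name") <- attr(data, "name")
    pd <- prepare_pres_data(df)
  }
  set.seed(seed)
  n <- pd$n
  extant <- pd$extant & !is.na(pd$extant)
  ts <- pd$oldest + stats::rexp(n, 2)
  te <- ifelse(extant, extant_age, pmax(0, pd$youngest - stats::rexp(n, 2)))
  te <- pmin(te, pd$youngest - ifelse(extant, 0, 1e-6))
  phi <- 1; scl <- max(mean(ts - te), 0.5)
  q <- if (!is.null(q_fixed)) q_fixed
       else max(pd$n_occ / max(sum(ts - te), 1), 0.05)
  weib_ll <- function(ts, te, phi, scl) {
    d <- ts - te
    ll <- ifelse(extant, -(d / scl)^phi,
                 stats::dweibull(d, phi, scl, log = TRUE))
    if (!is.null(window)) ll <- ll + (pmax(0, ts - window[1]) / scl)^phi
    ll
  }
  n_uncens <- sum(!extant)
  # the P(observed) normalization applies to the extinct (fully observable)
  # species; censored survivors keep the conditioned preservation term on
  # their truncated exposure instead
  corr <- function(phi, scl, q)
    if (correct_sampling) -n_uncens * log(ade_p_observed(phi, scl, q)) else 0
  pres_fn <- function(ts, te, q) {
    if (!correct_sampling)
      return(pres_loglik_vec(pd, ts, te, q, "HPP"))
    ll <- pres_loglik_vec(pd, ts, te, q, "HPP", condition = FALSE)
    ll[extant] <- ll[extant] - log1mexp(q * (ts - te)[extant])
    ll
  }
  pres_ll <- pres_fn(ts, te, q)
  w_ll <- weib_ll(ts, te, phi, scl)
  w_t <- 1.0
  acc_w <- 0; try_w <- 0
  nburn <- floor(0.1 * iterations)
  n_keep <- floor(iterations / sampling_freq)
  out <- matrix(NA_real_, n_keep, 3,
                dimnames = list(NULL, c("phi", "scale", "q")))
  kk <- 0L
  lp_par <- function(phi, scl, q)
    stats::dlnorm(phi, 0, 1, log = TRUE) +
    stats::dgamma(scl, 1.1, 0.1, log = TRUE) +
    (if (is.null(q_fixed)) stats::dgamma(q, 1.1, 0.1, log = TRUE) else 0)
  for (it in seq_len(iterations)) {
    # lineage times (vectorized per-species MH; factorizes across species)
    sel <- which(stats::runif(n) < 0.3)
    if (length(sel)) {
      ts_p <- ts; te_p <- te
      ts_p[sel] <- ts[sel] + stats::runif(length(sel), -w_t, w_t)
      mv <- sel[!extant[sel]]
      te_p[mv] <- te[mv] + stats::runif(length(mv), -w_t, w_t)
      ok <- ts_p > pd$oldest & te_p <= pd$youngest & te_p >= 0 &
        ts_p > te_p & (extant | te_p < pd$youngest)
      if (!is.null(window)) ok <- ok & te_p <= window[1] & te_p > window[2]
      ts_p[!ok] <- ts[!ok]; te_p[!ok] <- te[!ok]
      pres_new <- pres_fn(ts_p, te_p, q)
      w_new <- weib_ll(ts_p, te_p, phi, scl)
      lr <- (pres_new + w_new) - (pres_ll + w_ll)
      acc <- sel[ok[sel] & log(stats::runif(length(sel))) < lr[sel]]
      if (length(acc)) {
        ts[acc] <- ts_p[acc]; te[acc] <- te_p[acc]
        pres_ll <- pres_fn(ts, te, q)
        w_ll <- weib_ll(ts, te, phi, scl)
      }
      try_w <- try_w + sum(ok[sel]); acc_w <- acc_w + length(acc)
      if (it <= nburn && try_w >= 200) {
        r <- acc_w / try_w
        if (r < 0.2) w_t <- w_t * 0.8
        if (r > 0.4) w_t <- w_t * 1.25
        acc_w <- 0; try_w <- 0
      }
    }
    # (phi, scale, q) log-scale random-walk updates
    for (par in c("phi", "scale", "q")) {
      if (par == "q" && !is.null(q_fixed)) next
      phi2 <- phi; scl2 <- scl; q2 <- q
      fac <- exp(stats::rnorm(1, 0, 0.1))
      if (par == "phi") phi2 <- phi * fac
      if (par == "scale") scl2 <- scl * fac
      if (par == "q") q2 <- q * fac
      w_new <- weib_ll(ts, te, phi2, scl2)
      pres_new <- if (par == "q") pres_fn(ts, te, q2) else pres_ll
      lr <- sum(w_new) - sum(w_ll) + sum(pres_new) - sum(pres_ll) +
        corr(phi2, scl2, q2) - corr(phi, scl, q) +
        lp_par(phi2, scl2, q2) - lp_par(phi, scl, q) + log(fac)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        phi <- phi2; scl <- scl2; q <- q2
        w_ll <- w_new; pres_ll <- pres_new
      }
    }
    if (it %% sampling_freq == 0L) {
      kk <- kk + 1L
      out[kk, ] <- c(phi, scl, q)
    }
  }
  structure(as.data.frame(out[seq_len(kk), , drop = FALSE]),
            class = c("ade_trace", "data.frame"),
            window = window, seed = seed, n_species = n)
}

#' Summarize an ADE posterior
#'
#' @param trace an `ade_trace`.
#' @param burnin fraction discarded.
#' @return one-row data frame: posterior mean and 95% CI of `phi` and
#'   `scale`, mean `q`, and whether ADE is supported (CI of `phi`
#'   excludes 1).
#' @export
ade_summary <- function(trace, burnin = 0.1) {
  keep <- post_burnin(nrow(trace), burnin)
  tr <- trace[keep, , drop = FALSE]
  ci_phi <- ci95(tr$phi); ci_s <- ci95(tr$scale)
  data.frame(n_species = attr(trace, "n_species"),
             phi_mean = mean(tr$phi), phi_low = ci_phi[1],
             phi_high = ci_phi[2],
             scale_mean = mean(tr$scale), scale_low = ci_s[1],
             scale_high = ci_s[2],
             q_mean = mean(tr$q),
             ade_supported = ci_phi[1] > 1 || ci_phi[2] < 1)
}
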