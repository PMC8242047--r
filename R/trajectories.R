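#' Rates through time from a posterior trace
#'
#' Evaluates every post-burn-in sampled rate configuration on a regular age
#' grid and summarizes the speciation, extinction and net diversification
#' (`r = lambda - mu`, computed per sample, so the identity holds exactly)
#' rates by their posterior mean and 95% credible interval.
#'
#' @param trace a `bd_trace` (from [rjmcmc_sample] / [bdmcmc_sample]) or a
#'   list of sampled configurations as stored in one.
#' @param step grid step in Myr (default 0.1).
#' @param burnin fraction of samples discarded (default 0.1).
#' @return a data frame (age, lambda/mu/net mean and CI columns) of class
#'   `rtt_summary`, with the per-sample rate matrices in
#'   `attr(, "samples")`.
#' @export
rate_through_time <- function(trace, step = 0.1, burnin = 0.1) {
  stopifnot(inherits(trace, "bd_trace"))
  keep <- post_burnin(length(trace$lambda), burnin)
  ages <- seq(trace$span[1], trace$span[2], by = -step)
  L <- t(vapply(trace$lambda[keep],
                function(s) step_rate_at(ages, s$s, s$r), numeric(length(ages))))
  M <- t(vapply(trace$mu[keep],
                function(s) step_rate_at(ages, s$s, s$r), numeric(length(ages))))
  N <- L - M
  out <- data.frame(age = ages,
                    lambda_mean = colMeans(L),
                    lambda_low = apply(L, 2, function(x) ci95(x)[1]),
                    lambda_high = apply(L, 2, function(x) ci95(x)[2]),
                    mu_mean = colMeans(M),
                    mu_low = apply(M, 2, function(x) ci95(x)[1]),
                    mu_high = apply(M, 2, function(x) ci95(x)[2]),
                    net_mean = colMeans(N),
                    net_low = apply(N, 2, function(x) ci95(x)[1]),
                    net_high = apply(N, 2, function(x) ci95(x)[2]))
  class(out) <- c("rtt_summary", "data.frame")
  attr(out, "samples") <- list(lambda = L, mu = M)
  out
}

post_burnin <- function(n, burnin) {
  from <- floor(n * burnin) + 1L
  seq.int(from, n)
}

#' Posterior mean lineage times
#'
#' @param trace a `bd_trace`.
#' @param burnin fraction of samples discarded.
#' @return a [lineage_times] of posterior mean `Ts`/`Te` per species.
#' @export
posterior_lineage_times <- function(trace, burnin = 0.1) {
  keep <- post_burnin(nrow(trace$ts), burnin)
  lineage_times(trace$taxa,
                colMeans(trace$ts[keep, , drop = FALSE]),
                colMeans(trace$te[keep, , drop = FALSE]),
                extant = trace$extant)
}

#' Credible intervals of per-species times
#'
#' @param trace a `bd_trace`.
#' @param burnin fraction discarded.
#' @return data frame with per-species mean and 95% CI of `Ts` and `Te`.
#' @export
lineage_time_ci <- function(trace, burnin = 0.1) {
  keep <- post_burnin(nrow(trace$ts), burnin)
  TS <- trace$ts[keep, , drop = FALSE]
  TE <- trace$te[keep, , drop = FALSE]
  data.frame(taxon = trace$taxa,
             ts_mean = colMeans(TS),
             ts_low = apply(TS, 2, function(x) ci95(x)[1]),
             ts_high = apply(TS, 2, function(x) ci95(x)[2]),
             te_mean = colMeans(TE),
             te_low = apply(TE, 2, function(x) ci95(x)[1]),
             te_high = apply(TE, 2, function(x) ci95(x)[2]))
}

# standing diversity D(t) = #{te <= t < ts} on a vector of ages
count_diversity <- function(ts, te, ages) {
  sts <- sort(ts); ste <- sort(te)
  n <- length(ts)
  (n - findInterval(ages, sts)) - (n - findInterval(ages, ste))
}

#' Diversity trajectories from lineage times
#'
#' Computes the number of living species at every grid age from one or more
#' sets of per-species speciation/extinction times (typically the posterior
#' mean times of each age-randomized replicate), and summarizes across
#' replicates by mean and 95% interval.
#'
#' @param times_list a [lineage_times] or list of them (one per replicate).
#' @param step grid step in Myr.
#' @param span optional `c(older, younger)` grid limits; defaults to the
#'   overall span of the times.
#' @return data frame (age, mean, ci_low, ci_high) of class
#'   `diversity_trajectory`; the per-replicate count matrix is in
#'   `attr(, "replicates")`.
#' @export
diversity_trajectory <- function(times_list, step = 0.1, span = NULL) {
  if (inherits(times_list, "lineage_times")) times_list <- list(times_list)
  stopifnot(length(times_list) >= 1)
  if (is.null(span))
    span <- c(max(vapply(times_list, function(t) max(t$ts), 0)),
              min(vapply(times_list, function(t) min(t$te), 0)))
  ages <- seq(span[1], span[2], by = -step)
  D <- t(vapply(times_list,
                function(t) count_diversity(t$ts, t$te, ages),
                numeric(length(ages))))
  out <- data.frame(age = ages, mean = colMeans(D),
                    ci_low = apply(D, 2, function(x) ci95(x)[1]),
                    ci_high = apply(D, 2, function(x) ci95(x)[2]))
  class(out) <- c("diversity_trajectory", "data.frame")
  attr(out, "replicates") <- D
  out
}

#' Pool posterior traces across age-randomized replicates
#'
#' Concatenates the post-burn-in samples of several traces (which must share
#' the same analysis span) and summarizes rates through time from the
#' pooled posterior, plus a diversity trajectory built from each
#' replicate's posterior-mean lineage times.
#'
#' @param traces list of `bd_trace` objects.
#' @param step grid step (Myr).
#' @param burnin per-trace burn-in fraction.
#' @return list with elements `rates` (an `rtt_summary`) and `diversity`
#'   (a `diversity_trajectory`).
#' @export
combine_replicates <- function(traces, step = 0.1, burnin = 0.1) {
  stopifnot(length(traces) >= 1)
  spans <- vapply(traces, function(t) t$span, numeric(2))
  if (any(abs(spans - spans[, 1]) > 1e-9))
    stop_fbd("replicate traces have mismatched spans/grids")
  pooled <- traces[[1]]
  pooled$lambda <- do.call(c, lapply(traces, function(t)
    t$lambda[post_burnin(length(t$lambda), burnin)]))
  pooled$mu <- do.call(c, lapply(traces, function(t)
    t$mu[post_burnin(length(t$mu), burnin)]))
  rates <- rate_through_time(pooled, step = step, burnin = 0)
  div <- diversity_trajectory(lapply(traces, posterior_lineage_times,
                                     burnin = burnin), step = step)
  list(rates = rates, diversity = div)
}

#' @rdname rate_through_time
#' @param path output TSV path.
#' @param x an `rtt_summary` or `bd_trace`.
#' @export
write_trace <- function(x, path) {
  if (inherits(x, "bd_trace")) write_tsv(x$stats, path)
  else write_tsv(as.data.frame(x), path)
}

#' @export
print.bd_trace <- function(x, ...) {
  cat(sprintf("bd_trace (%s, %s preservation): %d samples, %d taxa\n",
              x$algorithm, x$model, nrow(x$stats), length(x$taxa)))
  cat(sprintf("  span %.2f - %.2f Ma; mean #shifts lambda %.2f, mu %.2f\n",
              x$span[1], x$span[2], mean(x$stats$n_shifts_lambda),
              mean(x$stats$n_shifts_mu)))
  invisible(x)
}
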