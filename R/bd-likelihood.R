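#' Per-species lineage times
#'
#' Holds each species' (estimated or true) time of speciation `ts` and
#' extinction `te` in Ma, with an extant flag.  In the augmented-data
#' birth--death likelihood these are the latent variables bracketing all of
#' the species' fossil occurrences: `ts >=` oldest occurrence age and
#' `te <=` youngest occurrence age.
#'
#' @param taxon species names.
#' @param ts,te speciation/extinction times (Ma), `ts > te >= 0`.
#' @param extant logical; extant species' `te` is the dataset's younger
#'   edge (0 for recent data sets).
#' @export
lineage_times <- function(taxon, ts, te, extant = rep(FALSE, length(ts))) {
  stopifnot(length(taxon) == length(ts), length(ts) == length(te))
  if (any(te < 0) || any(ts <= te))
    stop_fbd("need ts > te >= 0 for every species")
  structure(data.frame(taxon = as.character(taxon), ts = ts, te = te,
                       extant = extant, stringsAsFactors = FALSE),
            class = c("lineage_times", "data.frame"))
}

#' @rdname lineage_times
#' @param path TSV with columns `taxon`, `ts`, `te` and optional `extant`.
#' @export
read_lineage_times <- function(path) {
  df <- read_tsv(path)
  lineage_times(df$taxon, df$ts, df$te,
                extant = as.logical(df$extant %||% FALSE))
}

align_times <- function(times, taxa) {
  stopifnot(inherits(times, "lineage_times"))
  i <- match(taxa, times$taxon)
  if (anyNA(i)) stop_fbd("lineage times missing for taxa: ",
                         paste(utils::head(taxa[is.na(i)], 5), collapse = ", "))
  times[i, , drop = FALSE]
}

#' Piecewise-constant rate configurations
#'
#' A shift configuration holds speciation and extinction rates that are
#' constant within intervals delimited by shift times.  Interval 1 is the
#' oldest; with `k` shift times there are `k + 1` intervals.
#'
#' @param shift_times shift ages (Ma), any order (stored decreasing).
#' @param lambda,mu per-interval rates (> 0), old to young, length
#'   `length(shift_times) + 1`.
#' @export
shift_config <- function(lambda, mu, shift_times = numeric()) {
  if (length(lambda) != length(shift_times) + 1 ||
      length(mu) != length(shift_times) + 1)
    stop_fbd("need |lambda| = |mu| = |shift_times| + 1")
  if (any(lambda <= 0) || any(mu <= 0)) stop_fbd("rates must be > 0")
  structure(list(shift_times = sort(shift_times, decreasing = TRUE),
                 lambda = lambda, mu = mu),
            class = "shift_config")
}

# sufficient statistics per interval: B (speciation events), D (extinction
# events) and S (summed lineage durations).  Interval j spans
# (edges[j+1], edges[j]] in Ma; an event exactly on a shift time belongs to
# the younger interval (half-open [older, younger) convention).
bd_interval_stats <- function(ts, te, extant, shift_times,
                              span = c(Inf, -Inf)) {
  edges <- c(max(span[1], max(ts)), sort(shift_times, decreasing = TRUE),
             min(span[2], min(te)))
  k <- length(edges) - 1L
  older <- edges[-length(edges)]
  younger <- edges[-1]
  B <- D <- S <- numeric(k)
  for (j in seq_len(k)) {
    B[j] <- sum(ts <= older[j] & ts > younger[j])
    D[j] <- sum(!extant & te <= older[j] & te > younger[j])
    S[j] <- sum(pmax(0, pmin(ts, older[j]) - pmax(te, younger[j])))
  }
  # youngest extinction exactly on the bottom edge counts in the last bin
  D[k] <- D[k] + sum(!extant & te == edges[length(edges)])
  list(B = B, D = D, S = S, edges = edges)
}

#' Augmented-data birth--death log-likelihood
#'
#' For piecewise-constant rates, the log-likelihood of the augmented data
#' (every species' `ts` and `te`) is
#' `sum_j [ B_j log(lambda_j) + D_j log(mu_j) - (lambda_j + mu_j) S_j ]`,
#' where `B_j` and `D_j` count the speciation and extinction events falling
#' in interval `j` and `S_j` is the total lineage lifetime in it.  Every
#' `ts` (including the clade's origin) is treated as a speciation event;
#' extant species contribute exposure but no extinction event.  The
#' likelihood is additive under interval refinement: splitting an interval
#' without changing the rates leaves it unchanged.
#'
#' @param times a [lineage_times].
#' @param config a [shift_config].
#' @return log-likelihood (scalar).
#' @export
bd_loglik <- function(times, config) {
  stopifnot(inherits(times, "lineage_times"), inherits(config, "shift_config"))
  st <- bd_interval_stats(times$ts, times$te, times$extant,
                          config$shift_times)
  sum(st$B * log(config$lambda) + st$D * log(config$mu) -
        (config$lambda + config$mu) * st$S)
}

# fast per-species birth-death log-likelihood contributions for a given
# step-function rate pair; rate_at(x, edges, rates): edges decreasing ages.
step_rate_at <- function(x, shift_times, rates) {
  # an age equal to a shift time takes the younger interval's rate
  idx <- findInterval(-x, -shift_times) + 1L
  rates[idx]
}

# cumulative integral of a step rate from age `a` down to age `b` (a >= b)
step_rate_integral <- function(a, b, shift_times, rates) {
  if (length(shift_times) == 0L) return(rates[1] * (a - b))
  edges_older <- c(Inf, shift_times)
  edges_younger <- c(shift_times, -Inf)
  ov <- pmax(0, pmin(a, edges_older) - pmax(b, edges_younger))
  sum(rates * ov)
}

# vectorized per-species contributions: log lambda(ts) + [death] log mu(te)
# - int_{te}^{ts} (lambda+mu)
bd_species_loglik <- function(ts, te, extant, config) {
  stt <- config$shift_times
  lam_ts <- step_rate_at(ts, stt, config$lambda)
  mu_te <- step_rate_at(te, stt, config$mu)
  tot <- config$lambda + config$mu
  if (length(stt) == 0L) {
    integ <- tot[1] * (ts - te)
  } else {
    older <- c(Inf, stt)
    younger <- c(stt, -Inf)
    n <- length(ts)
    OV <- pmax(pmin(matrix(older, n, length(older), byrow = TRUE), ts) -
                 pmax(matrix(younger, n, length(younger), byrow = TRUE), te), 0)
    integ <- as.vector(OV %*% tot)
  }
  log(lam_ts) + ifelse(extant, 0, log(mu_te)) - integ
}
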