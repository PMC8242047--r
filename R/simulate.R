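#' Simulation regimes for clade histories
#'
#' Constructors for the generative regimes under which synthetic clade
#' histories are simulated: piecewise-constant rates with shifts,
#' covariate-linked rates, (multi-clade) diversity-dependent rates, and
#' age-dependent extinction with Weibull-distributed species longevities.
#' Ages are Ma before present; simulation runs from `origin_age` forward in
#' time to `end_age`.
#'
#' @param shift_times ages (Ma) of rate shifts, strictly inside
#'   `(end_age, origin_age)`.
#' @param lambda,mu speciation/extinction rates per interval
#'   (events/lineage/Myr); one more rate than shift times, ordered old to
#'   young.
#' @param origin_age,end_age simulation span (Ma), `origin_age > end_age`.
#' @return a `sim_regime` object.
#' @export
regime_piecewise <- function(lambda, mu, shift_times = numeric(),
                             origin_age = 100, end_age = 66) {
  stopifnot(length(lambda) == length(shift_times) + 1,
            length(mu) == length(shift_times) + 1,
            all(lambda >= 0), all(mu >= 0), origin_age > end_age)
  if (length(shift_times) &&
      (any(shift_times >= origin_age) || any(shift_times <= end_age)))
    stop_fbd("shift times must lie inside (end_age, origin_age)")
  structure(list(kind = "piecewise", lambda = lambda, mu = mu,
                 shift_times = sort(shift_times, decreasing = TRUE),
                 origin_age = origin_age, end_age = end_age),
            class = "sim_regime")
}

#' @rdname regime_piecewise
#' @param lambda0,mu0 baseline rates.
#' @param g_lambda,g_mu correlation parameters per covariate.
#' @param covariates a [covariate_curve] or list of curves (standardized
#'   internally over the simulation span).
#' @param link `"exponential"` or `"linear"` covariate link.
#' @param step grid step (Myr) on which covariate-linked rates are updated.
#' @export
regime_covariate <- function(lambda0, mu0, g_lambda, g_mu, covariates,
                             link = c("exponential", "linear"),
                             origin_age = 100, end_age = 66, step = 0.1) {
  link <- match.arg(link)
  stopifnot(lambda0 >= 0, mu0 >= 0, origin_age > end_age)
  V <- covariate_matrix(covariates, c(origin_age, end_age), step)
  stopifnot(length(g_lambda) == ncol(V), length(g_mu) == ncol(V))
  structure(list(kind = "covariate_linked", lambda0 = lambda0, mu0 = mu0,
                 g_lambda = g_lambda, g_mu = g_mu, V = V, link = link,
                 origin_age = origin_age, end_age = end_age, step = step),
            class = "sim_regime")
}

#' @rdname regime_piecewise
#' @param g_lambda_dd,g_mu_dd within-clade diversity-dependence coefficients:
#'   each living species changes the clade's speciation rate by
#'   `-g_lambda_dd` and its extinction rate by `+g_mu_dd`, as fractions of
#'   the baselines (rates truncated at 0).
#' @export
regime_diversity <- function(lambda0, mu0, g_lambda_dd = 0, g_mu_dd = 0,
                             origin_age = 100, end_age = 66) {
  stopifnot(lambda0 >= 0, mu0 >= 0, origin_age > end_age)
  structure(list(kind = "diversity_dependent", lambda0 = lambda0, mu0 = mu0,
                 g_lambda_dd = g_lambda_dd, g_mu_dd = g_mu_dd,
                 origin_age = origin_age, end_age = end_age),
            class = "sim_regime")
}

#' @rdname regime_piecewise
#' @param shape,scale Weibull shape and scale (Myr) of species longevities;
#'   `shape = 1` recovers age-independent (exponential) extinction.
#' @export
regime_age_dependent <- function(lambda0, shape, scale,
                                 origin_age = 100, end_age = 66) {
  stopifnot(lambda0 >= 0, shape > 0, scale > 0, origin_age > end_age)
  structure(list(kind = "age_dependent", lambda0 = lambda0, shape = shape,
                 scale = scale, origin_age = origin_age, end_age = end_age),
            class = "sim_regime")
}

new_history <- function(ts, te, parent, extant, clade_id, seed, regime) {
  structure(data.frame(species = paste0(clade_id, "_t", seq_along(ts)),
                       ts = ts, te = te, parent = parent, extant = extant,
                       stringsAsFactors = FALSE),
            class = c("true_history", "data.frame"),
            clade_id = clade_id, seed = seed, regime = regime)
}

#' Forward-simulate a clade history
#'
#' Event-driven (Gillespie) simulation of a birth--death process under a
#' [simulation regime][regime_piecewise], starting from one lineage at
#' `origin_age`.  For covariate-linked regimes the rates follow a
#' piecewise-constant discretization of the covariates (default 0.1 Myr);
#' for diversity-dependent regimes the rates are recomputed after every
#' event; for age-dependent extinction each species draws its longevity at
#' birth from the Weibull (exact, non-Markovian).  The history is accepted
#' only if the clade reaches at least `min_species` total species
#' (rejection, at most `max_attempts` re-simulations).
#'
#' @param regime a `sim_regime`.
#' @param seed integer seed; identical `(regime, seed)` gives identical
#'   histories.
#' @param min_species,max_species accepted range for the total number of
#'   simulated species (rejection sampling).
#' @param max_attempts maximum number of re-simulations.
#' @param cap abort if standing diversity exceeds this (runaway rates).
#' @param clade_id label for the simulated clade.
#' @return a `true_history` data frame with columns `species`, `ts`, `te`,
#'   `parent`, `extant`; extinct species have `ts > te >= end_age`, species
#'   alive at `end_age` carry `te = end_age` and `extant = TRUE`.
#' @export
simulate_history <- function(regime, seed = 1L, min_species = 2L,
                             max_species = Inf, max_attempts = 1000L,
                             cap = 1e4, clade_id = "clade") {
  stopifnot(inherits(regime, "sim_regime"))
  seeds <- child_seeds(seed, max_attempts)
  for (a in seq_len(max_attempts)) {
    set.seed(seeds[a])
    h <- sim_once(regime, cap)
    if (nrow(h$df) >= min_species && nrow(h$df) <= max_species)
      return(new_history(h$df$ts, h$df$te, h$df$parent, h$df$extant,
                         clade_id, seed, regime))
  }
  stop_fbd("no accepted history in ", max_attempts, " attempts")
}

sim_once <- function(regime, cap) {
  switch(regime$kind,
         piecewise = sim_piecewise(regime$lambda, regime$mu,
                                   regime$shift_times, regime$origin_age,
                                   regime$end_age, cap),
         covariate_linked = {
           V <- regime$V
           eta_l <- as.vector(V %*% regime$g_lambda)
           eta_m <- as.vector(V %*% regime$g_mu)
           lam <- link_rate(regime$lambda0, eta_l, regime$link)
           mu <- link_rate(regime$mu0, eta_m, regime$link)
           ages <- attr(V, "ages")
           # grid ages are interval left (older) edges; shifts at interior ages
           sim_piecewise(lam, mu, ages[-1], regime$origin_age,
                         regime$end_age, cap)
         },
         diversity_dependent = sim_dd(regime, cap),
         age_dependent = sim_ade(regime, cap),
         stop_fbd("unknown regime kind"))
}

link_rate <- function(baseline, eta, link) {
  if (link == "exponential") baseline * exp(eta) else baseline * pmax(0, 1 + eta)
}

# piecewise-constant rates shared by all lineages
sim_piecewise <- function(lambda, mu, shift_times, origin, end, cap) {
  brk <- c(sort(shift_times, decreasing = TRUE), end)
  k <- 1L
  t <- origin
  ts <- origin; te <- NA_real_; parent <- 0L
  alive <- 1L
  n <- 1L
  while (length(alive) > 0 && t > end) {
    D <- length(alive)
    if (D > cap) stop_fbd("diversity exceeded cap (", cap, "); runaway rates")
    tot <- D * (lambda[k] + mu[k])
    t_next <- if (tot > 0) t - stats::rexp(1, tot) else -Inf
    if (t_next <= brk[k]) {        # cross into next (younger) interval
      t <- brk[k]
      k <- k + 1L
      if (t <= end) break
      next
    }
    t <- t_next
    if (stats::runif(1) < lambda[k] / (lambda[k] + mu[k])) {
      n <- n + 1L
      ts[n] <- t; te[n] <- NA_real_
      parent[n] <- alive[sample.int(length(alive), 1L)]
      alive <- c(alive, n)
    } else {
      i <- alive[sample.int(length(alive), 1L)]
      te[i] <- t
      alive <- setdiff(alive, i)
    }
  }
  extant <- is.na(te)
  te[extant] <- end
  list(df = data.frame(ts = ts, te = te, parent = parent, extant = extant))
}

sim_dd <- function(regime, cap) {
  t <- regime$origin_age; end <- regime$end_age
  ts <- t; te <- NA_real_; parent <- 0L
  alive <- 1L; n <- 1L
  while (length(alive) > 0 && t > end) {
    D <- length(alive)
    if (D > cap) stop_fbd("diversity exceeded cap (", cap, "); runaway rates")
    lam <- regime$lambda0 * max(0, 1 - regime$g_lambda_dd * D)
    mu <- regime$mu0 * max(0, 1 + regime$g_mu_dd * D)
    tot <- D * (lam + mu)
    if (tot <= 0) break
    t <- t - stats::rexp(1, tot)
    if (t <= end) break
    if (stats::runif(1) < lam / (lam + mu)) {
      n <- n + 1L
      ts[n] <- t; te[n] <- NA_real_
      parent[n] <- alive[sample.int(length(alive), 1L)]
      alive <- c(alive, n)
    } else {
      i <- alive[sample.int(length(alive), 1L)]
      te[i] <- t
      alive <- setdiff(alive, i)
    }
  }
  extant <- is.na(te)
  te[extant] <- end
  list(df = data.frame(ts = ts, te = te, parent = parent, extant = extant))
}

# age-dependent extinction: longevities drawn at birth (exact sampling of
# the non-Markovian process); speciation is a constant per-lineage rate.
sim_ade <- function(regime, cap) {
  t <- regime$origin_age; end <- regime$end_age
  lam <- regime$lambda0
  draw_death <- function(birth)
    birth - stats::rweibull(1, shape = regime$shape, scale = regime$scale)
  ts <- t; te_sched <- draw_death(t); parent <- 0L
  alive <- 1L; n <- 1L
  te <- NA_real_
  while (length(alive) > 0 && t > end) {
    D <- length(alive)
    if (D > cap) stop_fbd("diversity exceeded cap (", cap, "); runaway rates")
    t_spec <- if (lam > 0) t - stats::rexp(1, lam * D) else -Inf
    i_death <- alive[which.max(te_sched[alive])]
    t_death <- te_sched[i_death]
    if (t_death >= t_spec) {        # death happens first (older age)
      t <- t_death
      if (t <= end) break
      te[i_death] <- t
      alive <- setdiff(alive, i_death)
    } else {
      t <- t_spec
      if (t <= end) break
      n <- n + 1L
      ts[n] <- t; te[n] <- NA_real_; te_sched[n] <- draw_death(t)
      parent[n] <- alive[sample.int(length(alive), 1L)]
      alive <- c(alive, n)
    }
  }
  extant <- is.na(te)
  te[extant] <- end
  list(df = data.frame(ts = ts, te = te, parent = parent, extant = extant))
}

#' Jointly simulate interacting clades
#'
#' Multi-clade diversity dependence: clade `i`'s per-lineage rates are
#' `lambda0[i] * max(0, 1 - sum_j g_lambda[i,j] * D_j(t))` and
#' `mu0[i] * max(0, 1 + sum_j g_mu[i,j] * D_j(t))`, where `D_j(t)` is clade
#' `j`'s standing diversity.  Positive coefficients are competition,
#' negative ones positive interaction; diagonal entries are within-clade
#' diversity dependence.
#'
#' @param lambda0,mu0 baseline rate vectors (one per clade).
#' @param g_lambda,g_mu interaction matrices (clade i row, clade j column).
#' @param origin_age,end_age simulation span (Ma).
#' @param seed integer seed.
#' @param min_species,max_species accepted per-clade species-count range
#'   (rejection; runaway attempts that hit `cap` are rejected and retried).
#' @param max_attempts,cap as in [simulate_history].
#' @param clade_ids labels.
#' @return list of `true_history` objects, one per clade.
#' @export
simulate_clades <- function(lambda0, mu0, g_lambda, g_mu,
                            origin_age = 100, end_age = 66, seed = 1L,
                            min_species = 2L, max_species = Inf,
                            max_attempts = 1000L, cap = 1e4,
                            clade_ids = NULL) {
  C <- length(lambda0)
  g_lambda <- matrix(g_lambda, C, C)
  g_mu <- matrix(g_mu, C, C)
  clade_ids <- clade_ids %||% paste0("clade", seq_len(C))
  seeds <- child_seeds(seed, max_attempts)
  for (a in seq_len(max_attempts)) {
    set.seed(seeds[a])
    res <- tryCatch(sim_clades_once(lambda0, mu0, g_lambda, g_mu,
                                    origin_age, end_age, cap),
                    fossilbd_error = function(e) NULL)
    if (is.null(res)) next      # runaway attempt: reject and retry
    sizes <- vapply(res, nrow, 0L)
    if (all(sizes >= min_species) && all(sizes <= max_species))
      return(lapply(seq_len(C), function(i)
        new_history(res[[i]]$ts, res[[i]]$te, res[[i]]$parent,
                    res[[i]]$extant, clade_ids[i], seed, NULL)))
  }
  stop_fbd("no accepted multi-clade history in ", max_attempts, " attempts")
}

sim_clades_once <- function(lambda0, mu0, gl, gm, origin, end, cap) {
  C <- length(lambda0)
  ts <- vector("list", C); te <- vector("list", C); parent <- vector("list", C)
  alive <- vector("list", C)
  for (i in seq_len(C)) {
    ts[[i]] <- origin; te[[i]] <- NA_real_; parent[[i]] <- 0L; alive[[i]] <- 1L
  }
  t <- origin
  repeat {
    D <- vapply(alive, length, 0L)
    if (sum(D) == 0L || t <= end) break
    if (any(D > cap)) stop_fbd("diversity exceeded cap (", cap, ")")
    lam <- lambda0 * pmax(0, 1 - as.vector(gl %*% D))
    mu <- mu0 * pmax(0, 1 + as.vector(gm %*% D))
    w <- D * (lam + mu)
    tot <- sum(w)
    if (tot <= 0) break
    t <- t - stats::rexp(1, tot)
    if (t <= end) break
    i <- sample.int(C, 1L, prob = w)
    if (stats::runif(1) < lam[i] / (lam[i] + mu[i])) {
      n <- length(ts[[i]]) + 1L
      ts[[i]][n] <- t; te[[i]][n] <- NA_real_
      parent[[i]][n] <- alive[[i]][sample.int(D[i], 1L)]
      alive[[i]] <- c(alive[[i]], n)
    } else {
      j <- alive[[i]][sample.int(D[i], 1L)]
      te[[i]][j] <- t
      alive[[i]] <- setdiff(alive[[i]], j)
    }
  }
  lapply(seq_len(C), function(i) {
    extant <- is.na(te[[i]])
    te[[i]][extant] <- end
    data.frame(ts = ts[[i]], te = te[[i]], parent = parent[[i]],
               extant = extant)
  })
}

#' Sample a fossil record from a true history
#'
#' Draws fossil occurrence times for each species from the preservation
#' model's Poisson process over the species' `[Te, Ts]` interval.  With the
#' gamma model, each taxon's rate is multiplied by an i.i.d. mean-one
#' Gamma(`alpha`, `alpha`) factor.  Species with zero occurrences are
#' dropped (unobserved).  Ages are returned exact
#' (`min_age == max_age`); use [impose_age_uncertainty] to coarsen them to
#' stage-level intervals.
#'
#' @param history a `true_history`.
#' @param model a [preservation_model].
#' @param seed integer seed.
#' @return an [occurrence_table] with exact ages, carrying the simulated
#'   history in `attr(, "truth")`.
#' @export
sample_fossils <- function(history, model, seed = 1L) {
  stopifnot(inherits(history, "true_history"),
            inherits(model, "preservation_model"))
  clade_id <- attr(history, "clade_id") %||% "clade"
  set.seed(seed)
  n <- nrow(history)
  mult <- if (!is.null(model$gamma_alpha))
    stats::rgamma(n, shape = model$gamma_alpha, rate = model$gamma_alpha)
  else rep(1, n)
  occ <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- history$ts[i]; te <- history$te[i]
    d <- ts - te
    ages <- switch(model$kind,
      HPP = {
        k <- stats::rpois(1, model$q * mult[i] * d)
        if (k > 0) stats::runif(k, te, ts) else numeric()
      },
      NHPP = {
        k <- stats::rpois(1, model$q * mult[i] * d)
        if (k > 0) ts - d * stats::rbeta(k, 2, 2) else numeric()
      },
      TPP = {
        ov <- stage_overlap(model$grid, ts, te)[1, ]
        ks <- stats::rpois(length(ov), model$q * mult[i] * ov)
        unlist(lapply(which(ks > 0), function(j) {
          lo <- max(te, model$grid$top[j]); hi <- min(ts, model$grid$base[j])
          stats::runif(ks[j], lo, hi)
        }))
      })
    if (length(ages))
      occ[[i]] <- data.frame(taxon = history$species[i], age = ages,
                             extant = history$extant[i])
  }
  occ <- do.call(rbind, occ)
  if (is.null(occ))
    occ <- data.frame(taxon = character(), age = numeric(), extant = logical())
  out <- occurrence_table(taxon = occ$taxon, min_age = occ$age,
                          max_age = occ$age,
                          status = ifelse(occ$extant, "extant", "extinct"),
                          clade = clade_id, name = clade_id)
  attr(out, "truth") <- history
  out
}

#' Replace exact occurrence ages by stage-level age intervals
#'
#' Each occurrence's exact age is replaced by the `(max_age, min_age)` =
#' `(base, top)` bounds of the geological stage containing it, emulating
#' stage-level dating uncertainty.  An age exactly on a boundary is assigned
#' to the younger stage.  The true age is always inside the reported
#' interval.
#'
#' @param table an [occurrence_table] with exact ages.
#' @param grid a [stage_grid] spanning all ages.
#' @export
impose_age_uncertainty <- function(table, grid = default_stage_grid()) {
  stopifnot(inherits(table, "occurrence_table"))
  if (any(table$max_age != table$min_age))
    stop_fbd("impose_age_uncertainty expects exact ages (min_age == max_age)")
  idx <- stage_of(grid, table$min_age)
  if (anyNA(idx))
    stop_fbd("occurrence ages outside the stage grid: rows ",
             paste(which(is.na(idx)), collapse = ", "))
  out <- table
  out$min_age <- grid$top[idx]
  out$max_age <- grid$base[idx]
  out
}

#' Extract the true lineage times from a simulated history
#'
#' @param history a `true_history`.
#' @param taxa optional subset/order of species names.
#' @return a [lineage_times] object.
#' @export
true_times <- function(history, taxa = NULL) {
  stopifnot(inherits(history, "true_history"))
  df <- as.data.frame(history)
  if (!is.null(taxa)) {
    df <- df[match(taxa, df$species), , drop = FALSE]
    if (anyNA(df$ts)) stop_fbd("unknown taxa requested")
  }
  lineage_times(taxon = df$species, ts = df$ts, te = df$te,
                extant = df$extant)
}

#' @rdname true_times
#' @param path output TSV path (columns `taxon`, `ts`, `te`, `extant`).
#' @export
write_history <- function(history, path) {
  df <- as.data.frame(history)
  write_tsv(data.frame(taxon = df$species, ts = df$ts, te = df$te,
                       extant = df$extant), path)
}
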