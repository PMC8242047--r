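#' Geological stage grids
#'
#' A stage grid partitions the time axis (ages in Ma before present,
#' increasing into the past) into named geological stages.  Bins follow the
#' half-open convention `[base, top)`: an age equal to a bin's (older) base
#' belongs to that bin, an age equal to its (younger) top belongs to the next
#' younger bin.  Consequently an occurrence dated exactly on a stage boundary
#' is assigned to the younger stage.
#'
#' @param stage character vector of stage names, ordered old to young.
#' @param base older boundary of each stage (Ma), strictly decreasing.
#' @param top younger boundary of each stage (Ma); must equal the next
#'   stage's base.
#' @return a `stage_grid` data frame with columns `stage`, `base`, `top`.
#' @examples
#' g <- default_stage_grid()
#' stage_of(g, c(72.1, 70, 66))   # boundary ages fall in the younger stage
#' @export
stage_grid <- function(stage, base, top) {
  stopifnot(length(stage) == length(base), length(base) == length(top))
  if (any(!is.finite(base)) || any(!is.finite(top)))
    stop_fbd("stage boundaries must be finite")
  if (any(top >= base)) stop_fbd("each stage must have top < base")
  if (any(top < 0)) stop_fbd("stage boundaries must be >= 0")
  if (length(base) > 1) {
    if (any(diff(base) >= 0)) stop_fbd("stage bases must be strictly decreasing")
    if (any(abs(top[-length(top)] - base[-1]) > 1e-9))
      stop_fbd("stages must be contiguous: top[i] == base[i+1]")
  }
  structure(data.frame(stage = as.character(stage), base = base, top = top,
                       stringsAsFactors = FALSE),
            class = c("stage_grid", "data.frame"))
}

#' @rdname stage_grid
#' @details `default_stage_grid()` returns the ICS 2020 Cretaceous stage
#'   boundaries plus the Danian top, the bins used by default for stage-level
#'   preservation rates and age uncertainty.
#' @export
default_stage_grid <- function() {
  stage_grid(
    stage = c("Berriasian", "Valanginian", "Hauterivian", "Barremian",
              "Aptian", "Albian", "Cenomanian", "Turonian", "Coniacian",
              "Santonian", "Campanian", "Maastrichtian", "Danian"),
    base = c(145.0, 139.8, 132.9, 129.4, 125.0, 113.0, 100.5, 93.9, 89.8,
             86.3, 83.6, 72.1, 66.0),
    top  = c(139.8, 132.9, 129.4, 125.0, 113.0, 100.5, 93.9, 89.8, 86.3,
             83.6, 72.1, 66.0, 61.6))
}

#' @rdname stage_grid
#' @param path TSV file with columns `stage`, `base_age`, `top_age`.
#' @export
read_stage_grid <- function(path) {
  df <- read_tsv(path)
  need <- c("stage", "base_age", "top_age")
  if (!all(need %in% names(df)))
    stop_fbd("stage table must have columns: ", paste(need, collapse = ", "))
  o <- order(df$base_age, decreasing = TRUE)
  stage_grid(df$stage[o], df$base_age[o], df$top_age[o])
}

#' @rdname stage_grid
#' @param grid a `stage_grid`.
#' @param ages numeric ages (Ma).
#' @return `stage_of()`: integer bin index per age (row of `grid`), `NA` for
#'   ages outside the grid span.
#' @export
stage_of <- function(grid, ages) {
  # bin j contains a iff top_j < a <= base_j  (boundary -> younger stage)
  J <- nrow(grid)
  idx <- findInterval(-ages, -grid$base)
  res <- rep(NA_integer_, length(ages))
  ok <- which(idx >= 1L & idx <= J)
  ok <- ok[ages[ok] > grid$top[idx[ok]]]
  res[ok] <- idx[ok]
  res
}

# overlap (Myr) of the interval [te, ts] with each stage bin; returns an
# n x n_stage matrix.  Vectorized: used inside MCMC loops.
stage_overlap <- function(grid, ts, te) {
  n <- length(ts)
  J <- nrow(grid)
  B <- matrix(grid$base, n, J, byrow = TRUE)
  T2 <- matrix(grid$top, n, J, byrow = TRUE)
  pmax(pmin(B, ts) - pmax(T2, te), 0)
}
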