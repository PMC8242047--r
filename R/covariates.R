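#' Time-continuous covariate curves
#'
#' A covariate curve is a measured palaeoenvironmental time series (global
#' temperature proxy, sea level, continental fragmentation index, relative
#' plant diversities, or a precomputed diversity trajectory) sampled on a
#' grid of ages (Ma).  Curves are stored with strictly decreasing ages.
#'
#' @param age ages in Ma, strictly monotone.
#' @param value finite measurements at those ages.
#' @param name curve label.
#' @export
covariate_curve <- function(age, value, name = "covariate") {
  stopifnot(length(age) == length(value), length(age) >= 2)
  if (any(!is.finite(age)) || any(!is.finite(value)))
    stop_fbd("covariate ages and values must be finite")
  d <- diff(age)
  if (!(all(d > 0) || all(d < 0))) stop_fbd("covariate ages must be strictly monotone")
  o <- order(age, decreasing = TRUE)
  structure(data.frame(age = age[o], value = value[o]),
            class = c("covariate_curve", "data.frame"), name = name,
            standardized = FALSE)
}

#' @rdname covariate_curve
#' @param path TSV file with columns `age`, `value`.
#' @export
read_covariate <- function(path, name = NULL) {
  df <- read_tsv(path)
  if (!all(c("age", "value") %in% names(df)))
    stop_fbd("covariate file must have columns age, value")
  covariate_curve(df$age, df$value,
                  name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Interpolate a covariate at arbitrary ages
#'
#' @param curve a [covariate_curve].
#' @param ages ages (Ma) within the curve's support.
#' @export
covariate_at <- function(curve, ages) {
  rng <- range(curve$age)
  if (any(ages < rng[1] - 1e-9) || any(ages > rng[2] + 1e-9))
    stop_fbd("requested ages outside covariate support [",
             rng[1], ", ", rng[2], "]")
  stats::approx(curve$age, curve$value, xout = ages, rule = 2)$y
}

#' Regrid and standardize a covariate over an analysis window
#'
#' Linearly interpolates the curve onto a regular age grid of the given step
#' and z-score standardizes it over the window (sample mean 0, sd 1).
#' Standardization makes correlation parameters comparable across covariates
#' with different native units.  A constant curve has zero variance; it is
#' returned as all zeros with a warning.
#'
#' @param curve a [covariate_curve].
#' @param window `c(older, younger)` ages in Ma, inside the curve support.
#' @param step grid step in Myr (default 0.1, the analysis time step).
#' @return a standardized [covariate_curve] on the regular grid.
#' @export
rescale_covariate <- function(curve, window, step = 0.1) {
  stopifnot(length(window) == 2)
  window <- sort(window, decreasing = TRUE)
  rng <- range(curve$age)
  if (window[1] > rng[2] + 1e-9 || window[2] < rng[1] - 1e-9)
    stop_fbd("window [", window[2], ", ", window[1],
             "] outside covariate support")
  ages <- seq(window[1], window[2], by = -step)
  v <- covariate_at(curve, ages)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    warning("covariate '", attr(curve, "name"),
            "' has zero variance over the window; returning zeros")
    v <- rep(0, length(v))
  } else {
    v <- (v - mean(v)) / s
  }
  out <- covariate_curve(ages, v, name = attr(curve, "name"))
  attr(out, "standardized") <- TRUE
  out
}

# assemble a (n_grid x p) standardized covariate matrix on a common grid
covariate_matrix <- function(curves, window, step = 0.1) {
  if (inherits(curves, "covariate_curve")) curves <- list(curves)
  std <- lapply(curves, rescale_covariate, window = window, step = step)
  V <- vapply(std, function(c) c$value, numeric(nrow(std[[1]])))
  V <- matrix(V, nrow = nrow(std[[1]]))
  colnames(V) <- vapply(std, attr, "", "name")
  attr(V, "ages") <- std[[1]]$age
  attr(V, "step") <- step
  V
}
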