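#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fbd <- function(..., class = "fossilbd_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Deterministic child seeds
#'
#' Derives a reproducible stream of 32-bit integer seeds from one master seed,
#' so that replicate analyses can be seeded independently.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is_number(seed), is_number(n), n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rinvgamma1 <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# quantile-based 95% interval, returned as c(low, high)
ci95 <- function(x) unname(stats::quantile(x, c(0.025, 0.975), names = FALSE))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
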