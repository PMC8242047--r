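#' Fossil occurrence tables
#'
#' An occurrence table holds one row per fossil occurrence: the taxon
#' (species) it is assigned to and the minimum/maximum plausible age of the
#' occurrence in Ma before present.  Optional columns carry a specimen
#' identifier, a region label (`new_world`, `old_world`, `other`) and a
#' clade (family) label.  A taxon known from a single occurrence is a
#' *singleton*.
#'
#' @param taxon character vector of species names (non-empty).
#' @param min_age,max_age age bounds in Ma, `max_age >= min_age >= 0`.
#' @param status `"extinct"` or `"extant"` per occurrence (taxon-level flag).
#' @param specimen_id,region,clade optional character vectors.
#' @param name dataset label.
#' @return an `occurrence_table` (a data frame).
#' @export
occurrence_table <- function(taxon, min_age, max_age, status = "extinct",
                             specimen_id = NA_character_,
                             region = NA_character_, clade = NA_character_,
                             name = "dataset") {
  n <- length(taxon)
  df <- data.frame(taxon = as.character(taxon),
                   status = rep_len(as.character(status), n),
                   min_age = as.numeric(min_age),
                   max_age = as.numeric(max_age),
                   specimen_id = rep_len(as.character(specimen_id), n),
                   region = rep_len(as.character(region), n),
                   clade = rep_len(as.character(clade), n),
                   stringsAsFactors = FALSE)
  bad <- validate_occurrence_rows(df)
  if (length(bad$format))
    stop_fbd("invalid occurrence rows (", paste(bad$why, collapse = "; "),
             "): rows ", paste(bad$format, collapse = ", "),
             class = "fossilbd_validation_error")
  reg <- df$region[!is.na(df$region)]
  if (length(reg) && !all(reg %in% c("new_world", "old_world", "other")))
    stop_fbd("region must be one of new_world, old_world, other",
             class = "fossilbd_validation_error")
  structure(df, class = c("occurrence_table", "data.frame"), name = name)
}

validate_occurrence_rows <- function(df) {
  why <- character()
  bad <- integer()
  b1 <- which(is.na(df$taxon) | !nzchar(df$taxon))
  if (length(b1)) why <- c(why, "empty taxon")
  b2 <- which(!is.finite(df$min_age) | !is.finite(df$max_age) |
                df$min_age < 0)
  if (length(b2)) why <- c(why, "non-finite or negative age")
  b3 <- which(is.finite(df$min_age) & is.finite(df$max_age) &
                df$max_age < df$min_age)
  if (length(b3)) why <- c(why, "min_age > max_age")
  list(format = sort(unique(c(b1, b2, b3))), why = why)
}

#' Read a fossil occurrence table
#'
#' Reads a tab-separated occurrence file.  The `generic_tsv` dialect expects
#' columns `taxon`, `status`, `min_age`, `max_age` and optional
#' `specimen_id`, `region`, `clade`; the `pyrate_style` dialect accepts the
#' conventional `Species`/`Status`/`min_age`/`max_age` header (matched
#' case-insensitively).  Rows violating the invariants (empty taxon,
#' negative ages, `min_age > max_age`) abort with the offending row numbers.
#'
#' @param path file path.
#' @param dialect `"generic_tsv"` (default) or `"pyrate_style"`.
#' @param name dataset label; defaults to the file name.
#' @return an [occurrence_table].
#' @export
read_occurrences <- function(path, dialect = c("generic_tsv", "pyrate_style"),
                             name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fbd("file not found: ", path)
  df <- read_tsv(path)
  nm <- tolower(names(df))
  pick <- function(keys) {
    i <- which(nm %in% keys)
    if (length(i)) df[[i[1]]] else NULL
  }
  taxon <- pick(if (dialect == "pyrate_style") c("species", "taxon")
                else c("taxon", "species"))
  min_age <- pick(c("min_age", "minage"))
  max_age <- pick(c("max_age", "maxage"))
  if (is.null(taxon) || is.null(min_age) || is.null(max_age))
    stop_fbd("missing required columns (taxon/species, min_age, max_age) in ",
             path, class = "fossilbd_format_error")
  occurrence_table(
    taxon = taxon, min_age = as.numeric(min_age), max_age = as.numeric(max_age),
    status = pick("status") %||% "extinct",
    specimen_id = pick("specimen_id") %||% NA_character_,
    region = pick("region") %||% NA_character_,
    clade = pick("clade") %||% NA_character_,
    name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_occurrences
#' @param table an [occurrence_table].
#' @export
write_occurrences <- function(table, path) {
  stopifnot(inherits(table, "occurrence_table"))
  write_tsv(as.data.frame(table), path)
}

#' Summarize an occurrence table
#'
#' @param table an [occurrence_table].
#' @return a list with `n_occurrences`, `n_taxa`, `n_singletons`,
#'   `mean_occ_per_taxon` and the per-taxon occurrence counts.
#' @export
occ_summary <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  if (nrow(table) == 0) stop_fbd("empty occurrence table")
  counts <- table(table$taxon)
  out <- list(name = attr(table, "name"),
              n_occurrences = nrow(table),
              n_taxa = length(counts),
              n_singletons = sum(counts == 1L),
              mean_occ_per_taxon = nrow(table) / length(counts),
              occ_per_taxon = c(counts))
  class(out) <- "occ_summary"
  out
}

#' @export
print.occ_summary <- function(x, ...) {
  cat("Occurrence data set:", x$name, "\n")
  cat(sprintf("  %d occurrences, %d taxa (%d singletons), %.2f occ/taxon\n",
              x$n_occurrences, x$n_taxa, x$n_singletons,
              x$mean_occ_per_taxon))
  invisible(x)
}

#' @export
summary.occurrence_table <- function(object, ...) occ_summary(object)

#' Subset an occurrence table by region or clade
#'
#' Filtering by region partitions the table: the `new_world`, `old_world`
#' and `other` subsets together hold every occurrence (missing region counts
#' as `other`).
#'
#' @param table an [occurrence_table].
#' @param region,clade optional labels to keep.
#' @export
filter_occurrences <- function(table, region = NULL, clade = NULL) {
  stopifnot(inherits(table, "occurrence_table"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(region)) {
    reg <- ifelse(is.na(table$region), "other", table$region)
    keep <- keep & reg %in% region
  }
  if (!is.null(clade)) keep <- keep & !is.na(table$clade) & table$clade %in% clade
  out <- table[keep, , drop = FALSE]
  attr(out, "name") <- paste0(attr(table, "name"),
                              if (!is.null(region)) paste0("_", paste(region, collapse = "+")),
                              if (!is.null(clade)) paste0("_", paste(clade, collapse = "+")))
  class(out) <- class(table)
  out
}

#' Resample occurrence ages within their stratigraphic bounds
#'
#' Draws, for every occurrence independently, one fixed age uniformly on
#' `[min_age, max_age]`.  Replicated resampling propagates stage-level age
#' uncertainty through all downstream analyses; the study design uses ten
#' such age-randomized replicates.
#'
#' @param table an [occurrence_table].
#' @param n_replicates number of replicates (default 10).
#' @param seed integer seed; replicate `i` uses a child seed derived from it,
#'   so results are bit-reproducible given `seed`.
#' @return a list of `age_resampled` data frames (the table plus an `age`
#'   column), each carrying `replicate_index` and `seed` attributes.
#' @export
resample_ages <- function(table, n_replicates = 10L, seed = 1L) {
  stopifnot(inherits(table, "occurrence_table"), n_replicates >= 1)
  seeds <- child_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(i) {
    set.seed(seeds[i])
    age <- stats::runif(nrow(table), table$min_age, table$max_age)
    out <- as.data.frame(table)
    out$age <- age
    structure(out, class = c("age_resampled", "data.frame"),
              replicate_index = i, seed = seeds[i],
              name = attr(table, "name"))
  })
}

#' Fix occurrence ages without resampling
#'
#' Returns an `age_resampled` data set whose ages are the interval
#' midpoints, useful when ages are exact (`min_age == max_age`) or as a
#' deterministic baseline.
#'
#' @param table an [occurrence_table].
#' @export
midpoint_ages <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  out <- as.data.frame(table)
  out$age <- (table$min_age + table$max_age) / 2
  structure(out, class = c("age_resampled", "data.frame"),
            replicate_index = 0L, seed = NA_integer_,
            name = attr(table, "name"))
}
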