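#' Observed site frequency spectrum
#'
#' Groups mutations by their carrier counts: `S(k)` is the number of mutations
#' carried by exactly `k` of the `n` cells, for `k = 1, ..., n - 1`. Only
#' segregating sites enter the spectrum: extinct mutations (count 0) are
#' always dropped and fixed (truncal) mutations (count `n`) are dropped unless
#' `include_fixed = TRUE`, in which case they are reported in `S(n)`.
#'
#' @param carriers Integer carrier counts per mutation, or the tibble returned
#'   by [carrier_counts()], or a `tugwar_pop` (its carrier counts are used).
#' @param n Sample size (number of cells).
#' @param include_fixed Keep mutations carried by all `n` cells?
#' @param min_count Drop mutations carried by fewer than `min_count` cells
#'   (low-frequency variants are routinely pruned in sequencing data; default
#'   keeps singletons).
#' @return A `tugwar_sfs` object: list with `n` and `counts` (integer vector
#'   `S(1), ..., S(n - 1)` or `..., S(n)`).
#' @examples
#' observed_sfs(c(rep(1, 7), rep(3, 3), rep(6, 2), 17), n = 20)
#' @export
observed_sfs <- function(carriers, n, include_fixed = FALSE, min_count = 1) {
  if (inherits(carriers, "tugwar_pop")) {
    n <- carriers$N
    carriers <- carrier_counts(carriers)
  }
  if (is.data.frame(carriers)) carriers <- carriers$carriers
  carriers <- as.integer(carriers)
  if (any(carriers > n)) abort("carrier counts cannot exceed `n`.")
  if (any(carriers < 0)) abort("carrier counts must be non-negative.")
  kmax <- if (include_fixed) n else n - 1L
  carriers <- carriers[carriers >= max(1L, min_count) & carriers <= kmax]
  structure(list(n = as.integer(n),
                 counts = tabulate(carriers, nbins = kmax)),
            class = "tugwar_sfs")
}

#' @method print tugwar_sfs
#' @export
print.tugwar_sfs <- function(x, ...) {
  cat(sprintf("<tugwar_sfs> n = %d, %d segregating mutations\n",
              x$n, sum(x$counts)))
  nz <- which(x$counts > 0)
  if (length(nz)) {
    cat(paste0("  S(", nz, ") = ", x$counts[nz], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @method tidy tugwar_sfs
#' @export
tidy.tugwar_sfs <- function(x, ...) {
  tibble(k = seq_along(x$counts), frequency = seq_along(x$counts) / x$n,
         count = x$counts)
}

#' Mutation frequencies of a spectrum
#'
#' The multiset `{k / n}`, one entry per mutation.
#'
#' @param sfs A `tugwar_sfs`.
#' @return Numeric vector of frequencies in `(0, 1]`.
#' @export
sfs_frequencies <- function(sfs) {
  rep(seq_along(sfs$counts) / sfs$n, sfs$counts)
}

#' Cumulative tail of a frequency spectrum
#'
#' Discrete evaluation of the cumulative tail `T(x)` = mass of the spectrum at
#' frequencies `>= x` (weak inequality). With `normalized = TRUE` (default)
#' the tail is divided by the total mutation count so all curves are
#' inscribed in the unit square, the standard convention for comparing
#' models.
#'
#' @param freqs Frequencies in `(0, 1]` (one per mutation), or a `tugwar_sfs`.
#' @param grid Evaluation points; default the sorted distinct observed
#'   frequencies.
#' @param normalized Divide by the total count?
#' @return A `tugwar_tail`: tibble with columns `x` and `T` (non-increasing),
#'   with attribute `normalized`.
#' @examples
#' cumulative_tail(c(rep(0.05, 7), rep(0.15, 3), rep(0.30, 2), 0.85))
#' @export
cumulative_tail <- function(freqs, grid = NULL, normalized = TRUE) {
  if (inherits(freqs, "tugwar_sfs")) freqs <- sfs_frequencies(freqs)
  if (any(freqs <= 0 | freqs > 1)) abort("frequencies must lie in (0, 1].")
  if (length(freqs) == 0 && normalized) {
    abort("cannot normalize the tail of an empty spectrum.")
  }
  if (is.null(grid)) grid <- sort(unique(freqs))
  grid <- sort(grid)
  counts <- length(freqs) - findInterval(grid, sort(freqs), left.open = TRUE)
  T_val <- if (normalized) counts / length(freqs) else as.numeric(counts)
  out <- tibble(x = as.numeric(grid), T = T_val)
  class(out) <- c("tugwar_tail", class(out))
  attr(out, "normalized") <- normalized
  out
}

#' Mean cumulative tail over replicate runs
#'
#' Evaluates each run's (normalized) tail on a common grid and averages
#' point-wise, the convention used to compare model ensembles to data.
#'
#' @param freq_list List of frequency vectors, one per run (runs with no
#'   segregating mutations are skipped).
#' @param grid Common evaluation grid; default the pooled distinct
#'   frequencies.
#' @param normalized Normalize each run's tail before averaging?
#' @return A `tugwar_tail` tibble on `grid`.
#' @export
mean_cumulative_tail <- function(freq_list, grid = NULL, normalized = TRUE) {
  freq_list <- purrr::keep(freq_list, ~ length(.x) > 0)
  if (length(freq_list) == 0) abort("no non-empty spectra supplied.")
  if (is.null(grid)) grid <- sort(unique(unlist(freq_list)))
  mats <- purrr::map(freq_list,
                     ~ cumulative_tail(.x, grid = grid,
                                       normalized = normalized)$T)
  out <- tibble(x = as.numeric(sort(grid)),
                T = Reduce(`+`, mats) / length(mats))
  class(out) <- c("tugwar_tail", class(out))
  attr(out, "normalized") <- normalized
  out
}

#' Variant allele frequencies of a variant table
#'
#' Per-site `variant_reads / total_reads`, the empirical analogue of the SFS
#' frequency `k / n`. Sites with zero total reads are dropped (their number is
#' reported in a message).
#'
#' @param table A variant table: data frame with columns `total_reads` and
#'   `variant_reads` (see [read_variants()]).
#' @param quiet Suppress the dropped-site message?
#' @return Numeric vector of VAFs in `[0, 1]`.
#' @export
vaf_frequencies <- function(table, quiet = FALSE) {
  stopifnot(all(c("total_reads", "variant_reads") %in% names(table)))
  if (any(table$variant_reads > table$total_reads)) {
    abort("`variant_reads` cannot exceed `total_reads`.")
  }
  drop <- table$total_reads == 0
  if (any(drop) && !quiet) {
    rlang::inform(sprintf("dropped %d site(s) with zero total reads.",
                          sum(drop)))
  }
  table$variant_reads[!drop] / table$total_reads[!drop]
}

#' Tail table for plotting / export
#'
#' Adds the logarithmic columns used by the semi-logarithmic (`log10 T` vs
#' `x`) or log-log (`log10 T` vs `log10 x`) tail plots. `T = 0` rows get
#' `-Inf`.
#'
#' @param tail A `tugwar_tail`.
#' @param scale `"semilog"` (default) or `"loglog"`.
#' @return Tibble with columns `x`, `T`, `log10_T` and, for `"loglog"`,
#'   `log10_x`.
#' @export
tail_table <- function(tail, scale = c("semilog", "loglog")) {
  scale <- match.arg(scale)
  out <- tibble(x = tail$x, T = tail$T,
                log10_T = ifelse(tail$T > 0, log10(tail$T), -Inf))
  if (scale == "loglog") out$log10_x <- log10(out$x)
  out
}

#' Write a tail table as TSV
#'
#' @inheritParams tail_table
#' @param path Output file.
#' @return The written tibble, invisibly.
#' @export
write_tail <- function(tail, path, scale = c("semilog", "loglog")) {
  out <- tail_table(tail, scale)
  readr::write_tsv(out, path)
  invisible(out)
}

#' Read a tail table written by [write_tail()]
#'
#' @param path TSV file with at least columns `x` and `T`.
#' @return A `tugwar_tail` tibble.
#' @export
read_tail <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("x", "T") %in% names(dat)))
  out <- tibble(x = dat$x, T = dat$T)
  class(out) <- c("tugwar_tail", class(out))
  attr(out, "normalized") <- max(dat$T) <= 1
  out
}
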