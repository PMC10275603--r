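# Independent oracles used across the test files. These deliberately avoid the
# package's own code paths (Stirling tables, subtree sums, log-space binomials).

# All partitions of n as allele-size spectra a = (a_1, ..., a_n),
# a_j = number of parts equal to j.
partitions_as_spectra <- function(n) {
  parts <- list()
  recurse <- function(remaining, max_part, acc) {
    if (remaining == 0) {
      parts[[length(parts) + 1]] <<- acc
      return(invisible())
    }
    for (p in seq_len(min(remaining, max_part))) {
      recurse(remaining - p, p, c(acc, p))
    }
  }
  recurse(n, n, integer(0))
  lapply(parts, function(pp) tabulate(pp, nbins = n))
}

# Ewens partition weight with theta^k cancelled: w(a) = n! / (prod j^a_j a_j!)
esf_partition_weight <- function(a) {
  n <- sum(seq_along(a) * a)
  exp(lgamma(n + 1) - sum(a * log(seq_along(a))) - sum(lgamma(a + 1)))
}

# Conditional mean allele-size spectrum by exhaustive enumeration over
# partitions with exactly k parts (theta cancels in the conditional).
esf_conditional_mean_oracle <- function(n, k) {
  specs <- Filter(function(a) sum(a) == k, partitions_as_spectra(n))
  w <- vapply(specs, esf_partition_weight, numeric(1))
  mat <- do.call(rbind, specs)
  colSums(mat * w) / sum(w)
}

# Exact unsigned Stirling numbers of the first kind by the integer recurrence;
# values stay below 2^53 for n <= 18 (row sums are n!), so doubles are exact.
stirling1_exact <- function(nmax) {
  S <- matrix(0, nmax + 1, nmax + 1)
  S[1, 1] <- 1
  for (n in seq_len(nmax)) {
    for (k in seq_len(n)) {
      S[n + 1, k + 1] <- (n - 1) * S[n, k + 1] + S[n, k]
    }
  }
  S
}

# Per-cell recount of mutation carriers: expand each live clone into its cells,
# give every cell the mutation set on its clone's root path, and tally.
carrier_counts_brute <- function(clones) {
  idx <- match(clones$parent_id, clones$id)
  counts <- setNames(integer(nrow(clones)), as.character(clones$id))
  for (row in seq_len(nrow(clones))) {
    if (clones$live_cells[row] == 0) next
    path <- integer(0)
    j <- row
    while (!is.na(j)) {
      if (clones$origin[j] != "root") path <- c(path, clones$id[j])
      j <- idx[j]
    }
    for (cell in seq_len(clones$live_cells[row])) {
      counts[as.character(path)] <- counts[as.character(path)] + 1L
    }
  }
  counts[as.character(clones$id[clones$origin != "root"])]
}

# Small hand-built clone table
make_clones <- function(id, parent_id, live, origin = NULL, alpha = 0,
                        beta = 0, fitness = 1, birth = 0) {
  n <- length(id)
  tibble::tibble(
    id = as.integer(id), parent_id = as.integer(parent_id),
    alpha = as.integer(rep_len(alpha, n)), beta = as.integer(rep_len(beta, n)),
    origin = origin %||% ifelse(is.na(parent_id), "root", "passenger"),
    fitness = rep_len(fitness, n), live_cells = as.integer(live),
    birth_time = rep_len(birth, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
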