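#' Read a variant read-count table
#'
#' Reads per-site total and variant read counts for one sequenced sample,
#' either from a TSV (canonical interchange format) or from a VCF carrying
#' per-sample allelic depths. TSV columns may be (`site`, `total_reads`,
#' `variant_reads`) or (`site`, `ref_reads`, `alt_reads`) -- in the latter
#' case `total_reads = ref_reads + alt_reads`. VCF parsing uses the standard
#' `AD` FORMAT field (reference and per-alt depths); multiallelic sites are
#' split into one row per alternate allele, with the site's total depth taken
#' as the sum of the AD entries. Malformed rows (missing or inconsistent
#' depths) are skipped with a message.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tsv"`, or `"vcf"`.
#' @param sample For VCF: sample name (default: first sample).
#' @param label Sample label stored on the table (default: file name).
#' @param quiet Suppress the skipped-row message?
#' @return A `tugwar_variants` tibble with columns `site`, `total_reads`,
#'   `variant_reads` and attribute `label`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf"),
                          sample = NULL, label = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- if (format == "tsv") read_variants_tsv(path) else
    read_variants_vcf(path, sample)
  bad <- is.na(tab$total_reads) | is.na(tab$variant_reads) |
    tab$variant_reads > tab$total_reads | tab$total_reads < 0 |
    tab$variant_reads < 0
  if (any(bad) && !quiet) {
    rlang::inform(sprintf("skipped %d malformed row(s).", sum(bad)))
  }
  tab <- tab[!bad, ]
  if (anyDuplicated(tab$site)) abort("site ids must be unique within a sample.")
  new_variant_table(tab, label %||% basename(path))
}

new_variant_table <- function(tab, label) {
  out <- tibble(site = as.character(tab$site),
                total_reads = as.integer(tab$total_reads),
                variant_reads = as.integer(tab$variant_reads))
  class(out) <- c("tugwar_variants", class(out))
  attr(out, "label") <- label
  out
}

read_variants_tsv <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(dat)
  if (all(c("total_reads", "variant_reads") %in% nm)) {
    tibble(site = dat[[1]], total_reads = dat$total_reads,
           variant_reads = dat$variant_reads)
  } else if (all(c("ref_reads", "alt_reads") %in% nm)) {
    tibble(site = dat[[1]], total_reads = dat$ref_reads + dat$alt_reads,
           variant_reads = dat$alt_reads)
  } else {
    abort("TSV needs columns (total_reads, variant_reads) or (ref_reads, alt_reads).")
  }
}

read_variants_vcf <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || ncol(ad) == 0) {
    abort("VCF has no per-sample AD (allelic depth) field.")
  }
  col <- if (is.null(sample)) 1L else {
    if (!sample %in% colnames(ad)) abort(sprintf("sample %s not in VCF.", sample))
    match(sample, colnames(ad))
  }
  fix <- vcfR::getFIX(vcf)
  rows <- purrr::map_dfr(seq_len(nrow(ad)), function(i) {
    parts <- suppressWarnings(as.integer(strsplit(ad[i, col], ",")[[1]]))
    alts <- strsplit(fix[i, "ALT"], ",")[[1]]
    if (length(parts) != length(alts) + 1 || anyNA(parts)) {
      return(tibble(site = sprintf("%s:%s_%s", fix[i, "CHROM"], fix[i, "POS"],
                                   fix[i, "ALT"]),
                    total_reads = NA_integer_, variant_reads = NA_integer_))
    }
    total <- sum(parts)
    tibble(site = sprintf("%s:%s_%s>%s", fix[i, "CHROM"], fix[i, "POS"],
                          fix[i, "REF"], alts),
           total_reads = total, variant_reads = parts[-1])
  })
  rows
}

#' Write a variant table as TSV
#'
#' @param table A `tugwar_variants` tibble.
#' @param path Output file.
#' @export
write_variants <- function(table, path) {
  readr::write_tsv(tibble(site = table$site, total_reads = table$total_reads,
                          variant_reads = table$variant_reads), path)
  invisible(table)
}

# Freedman-Diaconis bin width on the pooled total-read counts, floored at 1
fd_bin_width <- function(x) {
  w <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  max(1, ceiling(w))
}

#' Total-count histogram equalization of two paired variant tables
#'
#' Differences in sequencing coverage between two samples of the same
#' individual (e.g. primary tumor and lymph-node metastasis) bias the shape of
#' their VAF spectra. This resampling correction makes the two total-read
#' histograms identical: (1) both samples are binned by total read count with
#' a common bin width; (2) each bin's target is the lower of the two counts;
#' (3) variants are sorted by total reads and assigned to the bins; (4) in
#' each bin, the larger subset is pruned by uniform random sampling without
#' replacement down to the target. Retained rows are unchanged. Reproducible
#' under `set.seed()`.
#'
#' @param a,b Variant tables (data frames with `total_reads`,
#'   `variant_reads`).
#' @param bin_width Histogram bin width in reads; default: Freedman--Diaconis
#'   width of the pooled total-read counts (at least 1).
#' @return List with elements `a` and `b` (pruned `tugwar_variants`),
#'   `bin_width`, and `bins` (tibble of per-bin counts before/after).
#' @export
histogram_equalize <- function(a, b, bin_width = NULL) {
  if (is.null(bin_width)) {
    bin_width <- fd_bin_width(c(a$total_reads, b$total_reads))
  }
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  hi <- max(a$total_reads, b$total_reads, 0)
  breaks <- seq(0, hi + bin_width, by = bin_width)
  bin_of <- function(x) findInterval(x, breaks, left.open = FALSE)
  ba <- bin_of(a$total_reads)
  bb <- bin_of(b$total_reads)
  nb <- length(breaks) - 1
  ca <- tabulate(ba, nbins = nb)
  cb <- tabulate(bb, nbins = nb)
  target <- pmin(ca, cb)
  prune <- function(tab, bins, counts) {
    keep <- logical(nrow(tab))
    ord <- order(tab$total_reads)  # sort by total reads, then bin-partition
    for (bi in which(counts > 0)) {
      in_bin <- ord[bins[ord] == bi]
      if (length(in_bin) <= target[bi]) {
        keep[in_bin] <- TRUE
      } else {
        keep[sample(in_bin, target[bi])] <- TRUE
      }
    }
    tab[keep, ]
  }
  a2 <- prune(a, ba, ca)
  b2 <- prune(b, bb, cb)
  list(
    a = a2, b = b2, bin_width = bin_width,
    bins = tibble(bin_lo = breaks[seq_len(nb)], bin_hi = breaks[-1],
                  count_a = ca, count_b = cb, target = target)
  )
}

#' Synthesize paired tumor variant tables
#'
#' Emulates a pair of bulk-sequenced samples (primary tumor and metastasis)
#' from underlying mutation frequency multisets: per-site sequencing depth is
#' drawn from an over-dispersed negative binomial, and variant reads are
#' binomial in the depth at the site's true frequency. A `shared_fraction` of
#' the primary sites also appear in the second table with the same underlying
#' frequency (same site ids); `freqs_met` supplies the metastasis-private
#' sites. Matched patient read-count tables are typically controlled-access,
#' so this generator stands in for them; tables are synthetic and labelled as
#' such.
#'
#' @param freqs_primary Frequencies in \[0, 1\] of the primary sample's sites
#'   (a zero-frequency site always yields zero variant reads).
#' @param freqs_met Frequencies of metastasis-private sites (may be empty).
#' @param depth_mean Mean sequencing depth.
#' @param depth_dispersion Negative-binomial size parameter (smaller = more
#'   over-dispersed); depth variance is `m + m^2 / size`.
#' @param shared_fraction Fraction of primary sites shared by both samples.
#' @return List of two `tugwar_variants` tibbles, `primary` and `met`.
#' @examples
#' set.seed(1)
#' synthesize_paired_tables(runif(50, 0.05, 0.5), runif(10, 0.05, 0.5))
#' @export
synthesize_paired_tables <- function(freqs_primary, freqs_met = numeric(0),
                                     depth_mean = 100, depth_dispersion = 5,
                                     shared_fraction = 0.5) {
  if (any(c(freqs_primary, freqs_met) < 0) ||
      any(c(freqs_primary, freqs_met) > 1)) {
    abort("frequencies must lie in [0, 1].")
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must lie in [0, 1].")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0) {
    abort("depth parameters must be positive.")
  }
  np <- length(freqs_primary)
  n_shared <- round(shared_fraction * np)
  shared_idx <- seq_len(n_shared)
  draw <- function(freqs, ids) {
    depth <- rnbinom(length(freqs), mu = depth_mean, size = depth_dispersion)
    tibble(site = ids, total_reads = depth,
           variant_reads = rbinom(length(freqs), depth, freqs))
  }
  ids_p <- c(sprintf("shared_%d", shared_idx),
             if (np > n_shared) sprintf("primary_%d", seq_len(np - n_shared)))
  prim <- draw(freqs_primary, ids_p)
  freqs_b <- c(freqs_primary[shared_idx], freqs_met)
  ids_b <- c(sprintf("shared_%d", shared_idx),
             if (length(freqs_met)) sprintf("met_%d", seq_along(freqs_met)))
  met <- draw(freqs_b, ids_b)
  list(primary = new_variant_table(prim, "synthetic_primary"),
       met = new_variant_table(met, "synthetic_met"))
}

#' Distance between a data tail and model tails
#'
#' Quantifies the visual tail comparison: for each model curve, the
#' sup-distance between `log10 T` of the data and of the model over the
#' common grid (points where both tails are positive), plus the area between
#' the `log10` curves (trapezoidal) as a tie-breaking secondary metric.
#' Smaller is better. Both tails are step functions; they are evaluated on
#' the union of their grids restricted to the overlapping frequency range.
#'
#' @param data_tail A normalized `tugwar_tail`.
#' @param model_tails A single tail or (possibly named) list of tails.
#' @return Tibble with columns `model`, `sup_distance`, `area_between`,
#'   `n_grid` (common grid points used).
#' @export
compare_tails <- function(data_tail, model_tails) {
  if (inherits(model_tails, "tugwar_tail")) model_tails <- list(model_tails)
  nms <- names(model_tails) %||% paste0("model_", seq_along(model_tails))
  # right-continuous step evaluation: T(x) = T at the next grid atom >= x
  eval_tail <- function(tl, xout) {
    if (nrow(tl) == 1) return(rep(tl$T, length(xout)))
    stats::approx(tl$x, tl$T, xout, method = "constant", f = 1, rule = 2)$y
  }
  purrr::map2_dfr(model_tails, nms, function(mt, nm) {
    lo <- max(min(data_tail$x), min(mt$x))
    hi <- min(max(data_tail$x), max(mt$x))
    grid <- sort(unique(c(data_tail$x, mt$x)))
    grid <- grid[grid >= lo & grid <= hi]
    if (length(grid) == 0) abort("tail grids do not overlap.")
    d <- eval_tail(data_tail, grid)
    m <- eval_tail(mt, grid)
    ok <- d > 0 & m > 0
    if (!any(ok)) abort("no common grid points with positive tail mass.")
    x <- grid[ok]
    dv <- abs(log10(d[ok]) - log10(m[ok]))
    area <- if (length(x) > 1) {
      sum(diff(x) * (head(dv, -1) + tail(dv, -1)) / 2)
    } else 0
    tibble(model = nm, sup_distance = max(dv), area_between = area,
           n_grid = sum(ok))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
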