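test_that("TSV variant tables read under both column conventions", {
  path1 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(site = c("s1", "s2", "s3"),
                                  total_reads = c(50L, 30L, 40L),
                                  variant_reads = c(5L, 0L, 10L)), path1)
  tab1 <- read_variants(path1)
  expect_equal(nrow(tab1), 3)
  expect_equal(tab1$variant_reads, c(5L, 0L, 10L))

  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(site = c("s1", "s2"),
                                  ref_reads = c(45L, 27L),
                                  alt_reads = c(5L, 3L)), path2)
  tab2 <- read_variants(path2)
  expect_equal(tab2$total_reads, c(50L, 30L))
  expect_equal(tab2$variant_reads, c(5L, 3L))

  # inconsistent rows are skipped with a message
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(site = c("ok", "bad"),
                                  total_reads = c(10L, 5L),
                                  variant_reads = c(2L, 9L)), path3)
  expect_message(tab3 <- read_variants(path3), "skipped 1")
  expect_equal(tab3$site, "ok")

  # duplicate site ids violate the table invariant
  path4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(site = c("s", "s"),
                                  total_reads = c(10L, 10L),
                                  variant_reads = c(1L, 2L)), path4)
  expect_error(read_variants(path4), "unique")
})

test_that("VCF allelic depths are parsed and multiallelic sites split", {
  path <- test_path("fixtures", "sample_pair.vcf")
  expect_message(tab <- read_variants(path), "skipped 1")  # the ./. row
  # 4 usable records, one with two alts -> 5 rows
  expect_equal(nrow(tab), 5)
  expect_equal(tab$variant_reads[tab$site == "chr1:10100_A>G"], 5L)
  # multiallelic: totals shared, per-alt variant reads
  multi <- tab[grepl("chr1:30300", tab$site), ]
  expect_equal(nrow(multi), 2)
  expect_equal(multi$total_reads, c(40L, 40L))
  expect_equal(sort(multi$variant_reads), c(4L, 6L))
  # round trip through the canonical TSV
  out <- withr::local_tempfile(fileext = ".tsv")
  write_variants(tab, out)
  expect_equal(read_variants(out)$site, tab$site)
})

test_that("histogram equalization enforces the per-bin minimum rule", {
  # a has bins {5, 2}, b has bins {3, 4} with bin width 10
  a <- tibble::tibble(site = paste0("a", 1:7),
                      total_reads = c(1L, 3L, 5L, 7L, 9L, 12L, 15L),
                      variant_reads = 0L)
  b <- tibble::tibble(site = paste0("b", 1:7),
                      total_reads = c(2L, 4L, 6L, 11L, 13L, 15L, 17L),
                      variant_reads = 0L)
  set.seed(1)
  eq <- histogram_equalize(a, b, bin_width = 10)
  expect_equal(eq$bins$target[1:2], c(3L, 2L))
  expect_equal(sum(eq$a$total_reads < 10), 3)
  expect_equal(sum(eq$a$total_reads >= 10), 2)
  expect_equal(sum(eq$b$total_reads < 10), 3)
  expect_equal(sum(eq$b$total_reads >= 10), 2)
  # retained rows are verbatim subsets of the input
  expect_true(all(eq$a$site %in% a$site))
  expect_true(all(eq$b$site %in% b$site))

  # identical tables come back unchanged (up to order)
  set.seed(2)
  eq2 <- histogram_equalize(a, a, bin_width = 10)
  expect_setequal(eq2$a$site, a$site)
  expect_setequal(eq2$b$site, a$site)

  # a bin empty on one side empties the other side too
  c1 <- tibble::tibble(site = paste0("c", 1:4),
                       total_reads = c(25L, 26L, 27L, 28L), variant_reads = 0L)
  set.seed(3)
  eq3 <- histogram_equalize(a, c1, bin_width = 10)
  expect_equal(nrow(eq3$a), 0)
  expect_equal(nrow(eq3$b), 0)
})

test_that("equalization is idempotent and never increases a bin", {
  set.seed(9)
  a <- tibble::tibble(site = paste0("a", 1:200),
                      total_reads = as.integer(rnbinom(200, mu = 80, size = 5)),
                      variant_reads = 0L)
  b <- tibble::tibble(site = paste0("b", 1:150),
                      total_reads = as.integer(rnbinom(150, mu = 120, size = 5)),
                      variant_reads = 0L)
  eq1 <- histogram_equalize(a, b, bin_width = 20)
  bins <- function(tab) tabulate(findInterval(tab$total_reads,
                                              seq(0, 400, 20)), nbins = 20)
  expect_true(all(bins(eq1$a) <= bins(a)))
  expect_true(all(bins(eq1$b) <= bins(b)))
  expect_equal(bins(eq1$a), bins(eq1$b))
  eq2 <- histogram_equalize(eq1$a, eq1$b, bin_width = 20)
  expect_equal(bins(eq2$a), bins(eq1$a))
  expect_equal(bins(eq2$b), bins(eq1$b))
  # Freedman-Diaconis default yields a usable width
  eqfd <- histogram_equalize(a, b)
  expect_gte(eqfd$bin_width, 1)
})

test_that("synthetic paired tables reproduce their generating frequencies", {
  set.seed(5)
  tabs <- synthesize_paired_tables(rep(0.3, 10000), numeric(0),
                                   depth_mean = 100, depth_dispersion = 5,
                                   shared_fraction = 0)
  v <- vaf_frequencies(tabs$primary, quiet = TRUE)
  expect_equal(mean(v), 0.3, tolerance = 0.01)  # binomial mean

  # a zero-frequency site never produces variant reads
  set.seed(6)
  z <- synthesize_paired_tables(rep(0, 50), numeric(0), shared_fraction = 0)
  expect_true(all(z$primary$variant_reads == 0))

  # full sharing with no private metastasis sites: identical site sets
  set.seed(7)
  sh <- synthesize_paired_tables(runif(40, 0.1, 0.9), numeric(0),
                                 shared_fraction = 1)
  expect_setequal(sh$primary$site, sh$met$site)

  # deterministic given the seed
  set.seed(8); t1 <- synthesize_paired_tables(runif(20, 0.1, 0.5), runif(5, 0.1, 0.5))
  set.seed(8); t2 <- synthesize_paired_tables(runif(20, 0.1, 0.5), runif(5, 0.1, 0.5))
  expect_identical(t1$primary, t2$primary)
  expect_identical(t1$met, t2$met)

  expect_error(synthesize_paired_tables(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(synthesize_paired_tables(0.5, shared_fraction = 2), "\\[0, 1\\]")
})

test_that("deep sequencing recovers the underlying frequency tail", {
  set.seed(10)
  freqs <- runif(2000, 0.05, 0.95)
  tabs <- synthesize_paired_tables(freqs, numeric(0), depth_mean = 1e4,
                                   depth_dispersion = 1e4, shared_fraction = 0)
  v <- vaf_frequencies(tabs$primary, quiet = TRUE)
  grid <- seq(0.1, 0.9, by = 0.05)
  t_true <- cumulative_tail(freqs, grid = grid)
  t_vaf <- cumulative_tail(v, grid = grid)
  expect_lt(max(abs(t_true$T - t_vaf$T)), 0.03)
})

test_that("tail distances quantify vertical log-offsets", {
  tl <- cumulative_tail(c(0.1, 0.2, 0.4, 0.8), grid = c(0.1, 0.2, 0.4, 0.8))
  same <- compare_tails(tl, list(self = tl))
  expect_equal(same$sup_distance, 0)
  expect_equal(same$area_between, 0)

  # a constant vertical offset of delta in log10 T
  off <- tl
  off$T <- off$T * 10^(-0.3)
  d <- compare_tails(tl, list(lower = off))
  expect_equal(d$sup_distance, 0.3, tolerance = 1e-12)

  far <- cumulative_tail(c(0.91, 0.95), grid = c(0.91, 0.95))
  expect_error(compare_tails(tl, list(far = far)), "overlap")
})
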