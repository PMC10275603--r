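# Log-space table of unsigned Stirling numbers of the first kind,
# |S_n^k| for 0 <= k <= n <= nmax, via the recurrence
# |S_{n+1}^k| = n |S_n^k| + |S_n^{k-1}| carried with log-sum-exp.
# Row/col are 1-based offsets of n/k (entry [n+1, k+1]); log(0) = -Inf.
lstirling1_table <- function(nmax) {
  L <- matrix(-Inf, nmax + 1, nmax + 1)
  L[1, 1] <- 0  # |S_0^0| = 1
  for (n in seq_len(nmax)) {
    for (k in seq_len(n)) {
      a <- if (k <= n - 1) log(n - 1) + L[n, k + 1] else -Inf
      b <- L[n, k]
      m <- max(a, b)
      L[n + 1, k + 1] <- if (is.infinite(m)) -Inf else
        m + log(exp(a - m) + exp(b - m))
    }
  }
  L
}

# grow-only cache: the table for nmax contains all smaller ones
.tw_cache <- new.env(parent = emptyenv())
get_lstirling_table <- function(nmax) {
  tab <- .tw_cache$lstirling
  if (is.null(tab) || nrow(tab) < nmax + 1) {
    tab <- lstirling1_table(nmax)
    .tw_cache$lstirling <- tab
  }
  tab
}

#' Log of an unsigned Stirling number of the first kind
#'
#' `|S_n^k|` is the coefficient of `theta^k` in the rising factorial
#' `theta (theta + 1) ... (theta + n - 1)`; it is computed by the standard
#' recurrence carried in log space so that large `n` do not overflow.
#'
#' @param n,k Integers with `1 <= k <= n`.
#' @return `log |S_n^k|` (scalar; `n`, `k` may be equal-length vectors).
#' @examples
#' exp(log_stirling1(5, 1)) # 4! = 24
#' exp(log_stirling1(4, 2)) # 11
#' @export
log_stirling1 <- function(n, k) {
  if (any(k < 1) || any(k > n) || any(n < 1)) {
    abort("`log_stirling1` requires 1 <= k <= n.")
  }
  L <- get_lstirling_table(max(n))
  L[cbind(n + 1, k + 1)]
}

#' Ewens sampling formula: distribution of the number of alleles
#'
#' Under selective neutrality and mutation--drift equilibrium (infinite allele
#' model), the number of distinct alleles `K` in a sample of `n` cells follows
#' `P(K = k) = |S_n^k| theta^k / S_n(theta)` with
#' `S_n(theta) = theta (theta + 1) ... (theta + n - 1)`. Computed in log
#' space.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate, `theta > 0` (see [theta_from_model()]).
#' @return Tibble with columns `k = 1..n` and `prob` (sums to 1).
#' @examples
#' ewens_pmf_K(2, theta = 1) # P(K = 1) = 1 / (1 + theta) = 0.5
#' @export
ewens_pmf_K <- function(n, theta) {
  if (theta <= 0) abort("`theta` must be positive.")
  stopifnot(n >= 1)
  k <- seq_len(n)
  lS <- log_stirling1(rep(n, n), k)
  lnorm <- sum(log(theta + 0:(n - 1)))
  tibble(k = k, prob = exp(lS + k * log(theta) - lnorm))
}

# CDF helper for the K-S test (vectorised over q)
ewens_cdf_K <- function(q, n, theta) {
  pmf <- ewens_pmf_K(n, theta)
  cum <- cumsum(pmf$prob)
  idx <- pmin(pmax(floor(q), 0), n)
  ifelse(idx < 1, 0, cum[pmax(idx, 1)])
}

#' Conditional mean allele-size spectrum given the allele count
#'
#' Under the Ewens sampling formula, conditional on observing `k` alleles in
#' `n` cells, the expected number of alleles carried by exactly `j` cells is
#' `E(A_j | k, n) = n! / (j (n - j)!) * |S_{n-j}^{k-1}| / |S_n^k|`
#' (zero where the Stirling number is undefined, i.e. `k - 1 > n - j`). The
#' `j = 1` entry is the expected singleton count.
#'
#' @param n Sample size; `k` observed allele count, `1 <= k <= n`.
#' @param k See above.
#' @return Numeric vector `E(A_1 | k, n), ..., E(A_n | k, n)`; satisfies
#'   `sum(j * E(A_j)) = n`.
#' @examples
#' conditional_mean_spectrum(4, 2)[1] # 8/11
#' @export
conditional_mean_spectrum <- function(n, k) {
  if (k < 1 || k > n) abort("`k` must satisfy 1 <= k <= n.")
  L <- get_lstirling_table(n)
  lSnk <- L[n + 1, k + 1]
  vapply(seq_len(n), function(j) {
    nj <- n - j
    if (k - 1 > nj) return(0)
    lS <- L[nj + 1, k]  # log |S_{n-j}^{k-1}|; |S_0^0| = 1 covers k = 1, j = n
    if (is.infinite(lS)) return(0)
    exp(lgamma(n + 1) - log(j) - lgamma(nj + 1) + lS - lSnk)
  }, numeric(1))
}

# Ewens sampling formula for a full allele-size configuration a = (a_1..a_n):
# P(A = a) = n! / S_n(theta) * prod_j (theta / j)^{a_j} / a_j!
# Internal: used as the partition-probability oracle in the test suite.
ewens_partition_prob <- function(a, theta) {
  n <- sum(seq_along(a) * a)
  j <- seq_along(a)
  exp(lgamma(n + 1) - sum(log(theta + 0:(n - 1))) +
        sum(a * (log(theta) - log(j))) - sum(lgamma(a + 1)))
}

#' Scaled mutation rate for the Ewens null
#'
#' `theta = N * mu / lambda`, where `lambda` is the allele fitness correction
#' accounting for cell generation length (inversely proportional to fitness);
#' `lambda = 1` in the neutral case.
#'
#' @param N Population size (the Ewens sample here is the whole population,
#'   `n = N`).
#' @param mu Mutation rate per cell per time unit.
#' @param lam Fitness correction, `lambda > 0`.
#' @return `theta`.
#' @examples
#' theta_from_model(100, 0.1, 1) # 10
#' @export
theta_from_model <- function(N, mu, lam = 1) {
  if (lam <= 0) abort("`lam` must be positive.")
  theta <- N * mu / lam
  if (theta <= 0) {
    warn("theta = 0: the Ewens allele-count distribution is degenerate (K = 1).")
  }
  theta
}

#' Allele-count neutrality test (one-sample Kolmogorov--Smirnov)
#'
#' Tests whether the allele counts `k` observed across an ensemble of
#' simulation runs follow the Ewens distribution [ewens_pmf_K()] with the
#' given `theta`. The null distribution is discrete, so the K-S statistic is
#' the supremum over the support of the distance between the empirical and the
#' null CDF, `D = max_k |F_m(k) - F(k)|` (both step functions compared at the
#' atoms; the continuous-data convention of also comparing against the
#' left-hand empirical limit would inflate `D` by the largest atom mass and
#' reject even under the exact null). The p-value uses the asymptotic
#' Kolmogorov distribution, which is conservative for a discrete null; a
#' parametric-bootstrap p-value, obtained by re-drawing ensembles of the same
#' size from the null pmf and recomputing `D`, is reported alongside as an
#' exactly calibrated companion.
#'
#' @param ks Integer allele counts, one per run.
#' @param n Sample size (cells per run).
#' @param theta Scaled mutation rate of the null.
#' @param n_boot Bootstrap replicates for the companion p-value (0 to skip).
#' @return A `tugwar_neutrality` tibble (one row): `test`, `statistic`,
#'   `p_value`, `p_boot`, `n_runs`, `theta_used`.
#' @export
allele_count_test <- function(ks, n, theta, n_boot = 500) {
  if (length(ks) == 0) abort("`ks` must be non-empty.")
  if (any(ks < 1 | ks > n)) abort("allele counts must lie in 1..n.")
  m <- length(ks)
  F_null <- cumsum(ewens_pmf_K(n, theta)$prob)
  d_stat <- function(x) {
    F_emp <- cumsum(tabulate(x, nbins = n)) / length(x)
    max(abs(F_emp - F_null))
  }
  D <- d_stat(ks)
  # asymptotic Kolmogorov tail: P(sqrt(m) D > x) = 2 sum (-1)^(j-1) exp(-2 j^2 x^2)
  x <- sqrt(m) * D
  j <- 1:100
  p_asym <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))))
  p_boot <- NA_real_
  if (n_boot > 0) {
    pmf <- ewens_pmf_K(n, theta)
    d_null <- vapply(seq_len(n_boot), function(b) {
      d_stat(sample(pmf$k, m, replace = TRUE, prob = pmf$prob))
    }, numeric(1))
    p_boot <- mean(d_null >= D)
  }
  out <- tibble(test = "allele_count_KS", statistic = D,
                p_value = p_asym, p_boot = p_boot,
                n_runs = m, theta_used = theta)
  class(out) <- c("tugwar_neutrality", class(out))
  out
}

#' Singleton neutrality test (two-sample Wilcoxon)
#'
#' Builds the semi-empirical null sample of expected singleton counts
#' `E(A_1 | k_i, n)` (un-rounded) from the observed allele count of every run,
#' and compares it to the observed singleton counts with a two-sample
#' two-sided Wilcoxon rank-sum test -- sensitive to shifts in central
#' tendency, less so to shape.
#'
#' @param singletons Observed singleton counts, one per run.
#' @param ks Observed allele counts, same length.
#' @param n Sample size (cells per run).
#' @return A `tugwar_neutrality` tibble (one row).
#' @export
singleton_test <- function(singletons, ks, n) {
  if (length(singletons) != length(ks)) {
    abort("`singletons` and `ks` must have equal length.")
  }
  if (length(ks) == 0) abort("inputs must be non-empty.")
  e1 <- vapply(ks, function(k) conditional_mean_spectrum(n, k)[1], numeric(1))
  wt <- suppressWarnings(wilcox.test(singletons, e1, alternative = "two.sided"))
  out <- tibble(test = "singleton_wilcoxon",
                statistic = unname(wt$statistic),
                p_value = wt$p.value, p_boot = NA_real_,
                n_runs = length(ks), theta_used = NA_real_)
  class(out) <- c("tugwar_neutrality", class(out))
  out
}
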