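#' Expected SFS in the Griffiths--Tavare coalescent framework
#'
#' Expected number of mutant sites with `k` copies in a sample of `n` cells
#' from a population whose size changed deterministically in the past:
#' `ES(k) = theta * sum_{j=2}^{n-k+1} j * p_nj(k) * ET_j`, with combinatorial
#' weights `p_nj(k) = C(n-k-1, j-2) / C(n-1, j-1)` evaluated in log space and
#' `ET_j` the expected time during which the coalescent has `j` lineages.
#'
#' @param n Sample size, `n >= 2`.
#' @param theta Mutation rate per lineage per time unit.
#' @param ET Expected coalescence-time durations `ET_2, ..., ET_n`
#'   (length `n - 1`), in the same time units as `theta`.
#' @return Tibble with columns `k` (1 to `n - 1`) and `ES`.
#' @examples
#' # constant-size coalescent: ES(k) proportional to 1/k
#' n <- 10
#' gt_expected_sfs(n, 1, ET = 2 / ((2:n) * (1:(n - 1))))
#' @export
gt_expected_sfs <- function(n, theta, ET) {
  stopifnot(n >= 2, theta >= 0)
  if (length(ET) != n - 1) {
    abort("`ET` must have length n - 1 (expectations for j = 2, ..., n).")
  }
  if (any(ET <= 0)) abort("`ET` must be positive.")
  ES <- vapply(seq_len(n - 1), function(k) {
    j <- 2:(n - k + 1)
    lw <- lchoose(n - k - 1, j - 2) - lchoose(n - 1, j - 1)
    theta * sum(j * exp(lw) * ET[j - 1])
  }, numeric(1))
  tibble(k = seq_len(n - 1), ES = ES)
}

#' Combinatorial weight of the Griffiths--Tavare spectrum
#'
#' `p_nj(k) = C(n-k-1, j-2) / C(n-1, j-1)`: probability that a mutation on a
#' branch while `j` lineages remain is inherited by exactly `k` of the `n`
#' sampled cells.
#'
#' @param n Sample size; `j` number of ancestral lineages; `k` copy number.
#' @param j,k See above.
#' @return Numeric probability.
#' @export
gt_pnj <- function(n, j, k) {
  exp(lchoose(n - k - 1, j - 2) - lchoose(n - 1, j - 1))
}

#' Monte-Carlo expected coalescence times under exponential growth
#'
#' Simulates the coalescent of `n` lineages in a population that grew
#' exponentially at rate `r` to present size `N_pop` (backwards in time the
#' size is `N_pop * exp(-r * t)`, so the pair-coalescence rate while `j`
#' lineages remain is `choose(j, 2) / N(t)`). Exact expectations are hard to
#' obtain analytically for general growth, so they are estimated by
#' simulation; `r = 0` gives the constant-size coalescent, for which the
#' closed form `ET_j = 2 * N_pop / (j * (j - 1))` is returned exactly.
#'
#' @param n Sample size.
#' @param r Exponential growth rate (per time unit); `r = 0` for constant
#'   size.
#' @param N_pop Present population size.
#' @param n_reps Monte-Carlo replicates.
#' @return Numeric vector `ET_2, ..., ET_n` (length `n - 1`).
#' @export
expected_coalescent_times <- function(n, r, N_pop, n_reps = 5000) {
  stopifnot(n >= 2, r >= 0, N_pop > 0)
  j_seq <- n:2
  if (r == 0) {
    return(rev(2 * N_pop / (j_seq * (j_seq - 1))))
  }
  acc <- numeric(n - 1)  # durations indexed by j = 2..n
  for (rep in seq_len(n_reps)) {
    t_cur <- 0
    for (j in j_seq) {
      rate <- choose(j, 2)
      e <- rexp(1)
      # solve rate/N_pop * int_t^{t+w} exp(r u) du = e
      w <- log(exp(r * t_cur) + r * N_pop * e / rate) / r - t_cur
      acc[j - 1] <- acc[j - 1] + w
      t_cur <- t_cur + w
    }
  }
  acc / n_reps
}

#' Durrett approximation of the expected SFS under exponential growth
#'
#' Large-population approximations for a sample of `n` cells from a population
#' growing exponentially at rate `r`:
#' `ES(k) = theta * n / (r * k * (k - 1))` for `k >= 2`, and the singleton
#' count `ES(1) ~ theta * n * log(r * N_pop) / r` (only computed when `N_pop`
#' is supplied).
#'
#' @param n Sample size.
#' @param theta Mutation rate per cell per time unit.
#' @param r Exponential growth rate, `r > 0`.
#' @param N_pop Present population size (needed for the singleton term).
#' @return Tibble with columns `k` and `ES`; `k` starts at 1 when `N_pop` is
#'   given, at 2 otherwise.
#' @examples
#' durrett_sfs(n = 200, theta = 6, r = 1)
#' @export
durrett_sfs <- function(n, theta, r, N_pop = NULL) {
  stopifnot(n >= 2, theta >= 0)
  if (r <= 0) abort("`r` must be positive.")
  k <- 2:(n - 1)
  out <- tibble(k = k, ES = theta * n / (r * k * (k - 1)))
  if (!is.null(N_pop)) {
    out <- dplyr::bind_rows(
      tibble(k = 1L, ES = theta * n * log(r * N_pop) / r), out)
  }
  out
}

#' Total non-singleton mutation count under the Durrett approximation
#'
#' Closed form of the sum of `ES(k)` for `k = 2, ..., n - 1`:
#' `(n * theta / r) * (1 - 1 / (n - 1))`.
#'
#' @inheritParams durrett_sfs
#' @return A single number.
#' @export
durrett_total_A <- function(n, theta, r) {
  (n * theta / r) * (1 - 1 / (n - 1))
}

#' Expected SFS of the multiclone (binomial-hump) model
#'
#' Composite expected spectrum of a tumor containing `m` derived clones that
#' swept on the background of a founder clone. Each clone contributes a
#' neutral `1/(k(k-1))` component weighted by its cell fraction, and each
#' derived clone `i` adds a binomial hump of mass `K_i` (the ancestral
#' mutations marking its founding lineage) centred at `P_i`:
#' `Q_nk = sum_i p_i A_i / (k(k-1)) + sum_{i>=1} K_i C(n,k) (1-P_i)^(n-k) P_i^k`.
#'
#' Direct mode takes the hump parameters as given: `A` is either the total
#' neutral-tail area (scalar, already fraction-weighted) or the per-clone
#' areas `A_i` together with fractions `p`. Hierarchy mode derives them from
#' branch times, growth and mutation rates: clone fractions
#' `p_i = exp(r_i (t_diag - t_i)) / sum_l exp(r_l (t_diag - t_l))`, ancestral
#' counts `K_i = theta_{j_i} (t_i - t_{j_i})` (kept real-valued, an
#' expected-value quantity), and `A_i = n * theta_i / r_i`. The hump centroid
#' `P_i` is taken as the summed fraction of clone `i` and all its descendants
#' (the cells whose reads carry the `K_i` marker mutations).
#'
#' @param n Sample size.
#' @param A Total neutral area (scalar) or per-clone areas (length `m + 1`).
#' @param K Hump masses `K_1, ..., K_m` (derived clones only).
#' @param P Hump centroids `P_1, ..., P_m`, each in (0, 1).
#' @param p Clone fractions (length `m + 1`, summing to 1); only needed when
#'   `A` is per-clone.
#' @param hierarchy Alternatively, a list with elements `parent` (`j_i` for
#'   `i = 1..m`, 0-based clone indices, `j_i < i`), `t` (branch times
#'   `t_1..t_m` plus diagnosis time `t_{m+1}`, increasing), `theta` and `r`
#'   (length `m + 1`, clones `0..m`).
#' @return A `tugwar_hump_sfs`: list with `n`, `Q` (tibble `k = 2..n-1`,
#'   `Q`), and the resolved parameters `A_total`, `K`, `P`, `p`.
#' @examples
#' # two-clone toy: n = 30, K1 = 8, P1 = 0.4, A = 3.4
#' multiclone_sfs(n = 30, A = 3.4, K = 8, P = 0.4)
#' @export
multiclone_sfs <- function(n, A = NULL, K = NULL, P = NULL, p = NULL,
                           hierarchy = NULL) {
  stopifnot(n >= 3)
  if (!is.null(hierarchy)) {
    h <- hierarchy
    m <- length(h$parent)
    stopifnot(length(h$t) == m + 1, length(h$theta) == m + 1,
              length(h$r) == m + 1)
    if (any(h$parent >= seq_len(m)) || any(h$parent < 0)) {
      abort("hierarchy parents must satisfy 0 <= j_i < i.")
    }
    if (is.unsorted(h$t, strictly = TRUE)) {
      abort("branch times must increase to the diagnosis time.")
    }
    t_diag <- h$t[m + 1]
    t_clone <- c(0, h$t[seq_len(m)])          # clone 0 founded at time 0
    w <- exp(h$r * (t_diag - t_clone))
    p <- w / sum(w)
    K <- h$theta[h$parent + 1] * (h$t[seq_len(m)] - t_clone[h$parent + 1])
    A_i <- n * h$theta / h$r
    A_total <- sum(p * A_i)
    # centroid: fraction of clone i plus all its descendants
    P <- vapply(seq_len(m), function(i) {
      desc <- i
      repeat {
        more <- which(h$parent %in% desc & !(seq_len(m) %in% desc))
        if (length(more) == 0) break
        desc <- c(desc, more)
      }
      sum(p[desc + 1])
    }, numeric(1))
  } else {
    if (is.null(A) || is.null(K) || is.null(P)) {
      abort("supply either `hierarchy` or (`A`, `K`, `P`).")
    }
    if (length(A) == 1 && is.null(p)) {
      A_total <- A
    } else {
      if (is.null(p) || length(p) != length(A)) {
        abort("per-clone `A` requires matching fractions `p`.")
      }
      if (abs(sum(p) - 1) > 1e-8) abort("clone fractions must sum to 1.")
      A_total <- sum(p * A)
    }
  }
  if (length(K) != length(P)) abort("`K` and `P` must have equal length.")
  if (any(K < 0)) abort("`K` must be non-negative.")
  if (length(P) && any(P <= 0 | P >= 1)) abort("`P` must lie in (0, 1).")
  k <- 2:(n - 1)
  neutral <- A_total / (k * (k - 1))
  hump <- rep(0, length(k))
  for (i in seq_along(K)) {
    # binomial term in log space
    lterm <- lchoose(n, k) + (n - k) * log1p(-P[i]) + k * log(P[i])
    hump <- hump + K[i] * exp(lterm)
  }
  structure(list(n = as.integer(n), Q = tibble(k = k, Q = neutral + hump),
                 A_total = A_total, K = K, P = P,
                 p = if (exists("p") && !is.null(p)) p else NULL),
            class = "tugwar_hump_sfs")
}

#' @method print tugwar_hump_sfs
#' @export
print.tugwar_hump_sfs <- function(x, ...) {
  cat(sprintf("<tugwar_hump_sfs> n = %d, neutral area %.4g, %d hump(s)\n",
              x$n, x$A_total, length(x$K)))
  invisible(x)
}

#' @method tidy tugwar_hump_sfs
#' @export
tidy.tugwar_hump_sfs <- function(x, ...) x$Q

#' Power-law comparison spectrum
#'
#' SFS density `c * f^(-alpha)` with exponent `alpha = lambda0 / lambda1`, the
#' form arising in the two-type birth--death model where the founder type
#' grows at rate `lambda0` and the selected type at `lambda1 > lambda0`. The
#' cumulative tail is the analytic integral over `[x, 1]`:
#' `c * (1 - x^(1 - alpha)) / (1 - alpha)` for `alpha != 1`, `-c * log(x)` for
#' `alpha = 1`.
#'
#' @param c Multiplicative constant of the density.
#' @param lambda0,lambda1 Growth rates with `0 < lambda0 < lambda1`.
#' @param grid Frequencies in (0, 1] at which to evaluate.
#' @param normalized Divide the tail by its value at `min(grid)` so the curve
#'   fits the unit square?
#' @return Tibble with columns `x`, `density`, `T`.
#' @examples
#' power_law_tail(1, 0.5, 1, grid = c(0.01, 0.1, 0.5, 1))
#' @export
power_law_tail <- function(c = 1, lambda0, lambda1,
                           grid = seq(0.01, 1, by = 0.01),
                           normalized = FALSE) {
  if (lambda0 <= 0 || lambda0 >= lambda1) {
    abort("growth rates must satisfy 0 < lambda0 < lambda1.")
  }
  alpha <- lambda0 / lambda1
  grid <- sort(grid)
  if (any(grid <= 0 | grid > 1)) abort("grid must lie in (0, 1].")
  dens <- c * grid^(-alpha)
  T_val <- if (abs(alpha - 1) < 1e-12) {
    -c * log(grid)
  } else {
    c * (1 - grid^(1 - alpha)) / (1 - alpha)
  }
  if (normalized && max(T_val) > 0) T_val <- T_val / max(T_val)
  tibble(x = grid, density = dens, T = T_val)
}
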