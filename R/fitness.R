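#' Multiplicative cell fitness from mutation counts
#'
#' Fitness of a cell carrying `alpha` driver and `beta` passenger mutations is
#' `(1 + s)^alpha * (1 - d)^beta`: multiplicative across mutations, i.e. no
#' epistatic interaction.
#'
#' @param alpha Non-negative integer driver count (vectorised).
#' @param beta Non-negative integer passenger count (vectorised).
#' @param s Driver selection coefficient, `s >= 0`.
#' @param d Passenger selection coefficient, `0 <= d < 1`.
#' @return Numeric vector of strictly positive fitness values.
#' @examples
#' compute_fitness(2, 1, s = 0.1, d = 0.01) # 1.21 * 0.99
#' @export
compute_fitness <- function(alpha, beta, s, d) {
  if (s < 0) abort("`s` must be non-negative.")
  if (d < 0 || d >= 1) abort("`d` must lie in [0, 1).")
  if (any(alpha < 0) || any(beta < 0)) abort("mutation counts must be >= 0")
  (1 + s)^alpha * (1 - d)^beta
}

#' Exact expected fitness increment of one death--replacement event
#'
#' Enumerates all ordered (dying i, replacing j) cell pairs with the model's
#' sampling probabilities and returns the expectation of `f_j - f_i`. Under
#' Model A both cells are drawn proportionally to fitness, and the expectation
#' vanishes identically; under Model B the dying cell is uniform while the
#' replacing cell is fitness-biased, giving a non-negative expectation that is
#' zero exactly when all cells share the same fitness (it equals
#' `sum(f^2)/sum(f) - mean(f)`).
#'
#' @param fitnesses Positive fitness values, one per cell.
#' @param model `"A"` or `"B"`.
#' @return The expected one-event change in total population fitness divided
#'   by nothing -- i.e. the expected `f_replacing - f_dying`.
#' @examples
#' expected_fitness_increment(c(1, 2, 3), "A") # 0
#' expected_fitness_increment(c(1, 2), "B")    # 1/6
#' @export
expected_fitness_increment <- function(fitnesses, model = c("A", "B")) {
  model <- match.arg(model)
  if (length(fitnesses) == 0) abort("`fitnesses` must be non-empty.")
  if (any(fitnesses <= 0)) abort("all fitnesses must be positive.")
  f <- as.numeric(fitnesses)
  n <- length(f)
  sigma <- sum(f)
  p_die <- if (model == "A") f / sigma else rep(1 / n, n)
  p_rep <- f / sigma
  # expectation over all ordered pairs of f_j - f_i
  diff <- outer(f, f, function(fi, fj) fj - fi)  # rows i (dying), cols j
  sum((p_die %o% p_rep) * diff)
}

#' Sampling distributions of the dying and replacing cell over clones
#'
#' For a clone-structured population, returns the probability mass functions
#' (over clones) from which the dying and the replacing cell are drawn at a
#' death--replacement event. The replacing pmf is proportional to
#' `live_cells * fitness` in both models; the dying pmf is the same under
#' Model A and proportional to `live_cells` (uniform over cells) under
#' Model B. The replacing cell may coincide with the dying cell.
#'
#' @param pop A `tugwar_pop` population, or a tibble of clones with columns
#'   `fitness` and `live_cells`.
#' @param model `"A"` or `"B"`.
#' @return A tibble with one row per clone and columns `id`, `p_die`, `p_rep`.
#' @examples
#' pop <- init_homogeneous(tugwar_params(N = 10))
#' death_replacement_pmfs(pop, "A")
#' @export
death_replacement_pmfs <- function(pop, model = c("A", "B")) {
  model <- match.arg(model)
  clones <- if (inherits(pop, "tugwar_pop")) pop$clones else as_tibble(pop)
  w_rep <- clones$live_cells * clones$fitness
  sigma <- sum(w_rep)
  if (sigma <= 0) abort("total fitness must be positive.")
  n <- sum(clones$live_cells)
  tibble(
    id = if ("id" %in% names(clones)) clones$id else seq_len(nrow(clones)),
    p_die = if (model == "A") w_rep / sigma else clones$live_cells / n,
    p_rep = w_rep / sigma
  )
}
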