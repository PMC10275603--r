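#' Tug-of-war model parameters
#'
#' Bundle and validate the parameters of the constant-population tug-of-war
#' Moran models. A population of `N` cells evolves by two kinds of events:
#' death--replacement (total rate equal to the summed fitness of all live
#' cells) and mutation (total rate `N * mu`). A mutation is a driver with
#' probability `p` (multiplying the cell's fitness by `1 + s`) and a passenger
#' otherwise (multiplying it by `1 - d`), so a cell with `alpha` drivers and
#' `beta` passengers has fitness `(1 + s)^alpha * (1 - d)^beta`.
#'
#' The two model variants differ only in how the dying cell is chosen:
#' Model `"A"` draws it proportionally to fitness, Model `"B"` uniformly.
#' The replacing cell is drawn proportionally to fitness in both. Model A
#' preserves expected fitness under drift; Model B is biased upward.
#'
#' @param N Population size (number of cells), constant over time.
#' @param mu Mutation rate per cell per model time unit.
#' @param p Probability that a mutation is a driver, in (0, 1).
#' @param s Selective advantage of a driver, `s >= 0`.
#' @param d Selective disadvantage of a passenger, `0 <= d < 1`.
#' @param model `"A"` or `"B"`.
#' @param t_max Simulation horizon in model time units.
#' @param max_events Safety cap on the number of events per run; a run that
#'   reaches it stops with a condition carrying the partial result.
#'
#' @return An object of class `tugwar_params` (a validated named list).
#' @examples
#' tugwar_params(N = 100, mu = 0.1, p = 0.0909, s = 0.1, d = 0.01)
#' @export
tugwar_params <- function(N, mu = 0, p = 0.5, s = 0, d = 0,
                          model = c("A", "B"), t_max = 100,
                          max_events = 5e6) {
  model <- match.arg(model)
  stopifnot(length(N) == 1, length(mu) == 1, length(p) == 1,
            length(s) == 1, length(d) == 1, length(t_max) == 1)
  if (N < 1 || N != round(N)) abort("`N` must be a positive integer.")
  if (mu < 0) abort("`mu` must be non-negative.")
  if (mu > 0 && (p <= 0 || p >= 1)) {
    abort("`p` must lie strictly in (0, 1) when `mu > 0`.")
  }
  if (s < 0) abort("`s` must be non-negative.")
  if (d < 0 || d >= 1) abort("`d` must lie in [0, 1).")
  if (t_max <= 0) abort("`t_max` must be positive.")
  if (max_events < 1) abort("`max_events` must be at least 1.")
  structure(
    list(N = as.integer(N), mu = mu, p = p, s = s, d = d, model = model,
         t_max = t_max, max_events = max_events),
    class = "tugwar_params"
  )
}

#' @method print tugwar_params
#' @export
print.tugwar_params <- function(x, ...) {
  cat(sprintf(
    "<tugwar_params> Model %s: N = %d, mu = %g, p = %g, s = %g, d = %g, t_max = %g\n",
    x$model, x$N, x$mu, x$p, x$s, x$d, x$t_max))
  invisible(x)
}
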