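#' Population states
#'
#' A population is stored as a multiset over clones, where a clone is a set of
#' cells sharing an identical mutation history. Clones form a rooted genealogy
#' with exactly one new clone per mutation event (infinite-allele /
#' infinite-site bookkeeping), so per-cell storage is redundant: `live_cells`
#' summed over clones equals the constant population size `N`.
#'
#' @param time Current model time.
#' @param clones Tibble with columns `id`, `parent_id` (`NA` for initial
#'   clones), `alpha`, `beta`, `origin` (`"root"`, `"driver"` or
#'   `"passenger"`), `fitness`, `live_cells`, `birth_time`.
#' @param N Population size.
#' @return A `tugwar_pop` object.
#' @keywords internal
new_population <- function(time, clones, N) {
  stopifnot(sum(clones$live_cells) == N, all(clones$live_cells >= 0))
  structure(list(time = time, clones = clones, N = as.integer(N)),
            class = "tugwar_pop")
}

#' @method print tugwar_pop
#' @export
print.tugwar_pop <- function(x, ...) {
  alive <- sum(x$clones$live_cells > 0)
  cat(sprintf("<tugwar_pop> t = %g, N = %d, %d clones recorded (%d alive), mean fitness %.4f\n",
              x$time, x$N, nrow(x$clones), alive, sigma_total(x) / x$N))
  invisible(x)
}

# total fitness of the N live cells
sigma_total <- function(pop) {
  sum(pop$clones$live_cells * pop$clones$fitness)
}

#' Homogeneous initial population
#'
#' One root clone with no driver or passenger mutations and fitness 1 carried
#' by all `N` cells.
#'
#' @param params A [tugwar_params()] object.
#' @return A `tugwar_pop`.
#' @examples
#' init_homogeneous(tugwar_params(N = 100))
#' @export
init_homogeneous <- function(params) {
  clones <- tibble(
    id = 1L, parent_id = NA_integer_, alpha = 0L, beta = 0L,
    origin = "root", fitness = 1, live_cells = params$N, birth_time = 0
  )
  new_population(0, clones, params$N)
}

#' Heterogeneous initial population from exponential draws
#'
#' Each of the `N` cells receives independent initial driver and passenger
#' counts drawn from exponential distributions and rounded half-up to the
#' nearest integer. By default the exponential parameters `10 * p` (drivers)
#' and `10 * (1 - p)` (passengers) are interpreted as the distribution means;
#' set `interpretation = "rate"` to treat them as rates instead. Cells drawing
#' identical `(alpha, beta)` pairs are collapsed into one initial clone.
#'
#' @param params A [tugwar_params()] object.
#' @param scale_driver,scale_passenger Exponential parameters; defaults
#'   `10 * p` and `10 * (1 - p)`.
#' @param interpretation Whether the parameters are means (default) or rates.
#' @return A `tugwar_pop` with one clone per distinct `(alpha, beta)` pair,
#'   all flagged `origin = "root"` (they predate the mutation process).
#' @examples
#' set.seed(1)
#' init_exponential_draw(tugwar_params(N = 100, p = 0.5))
#' @export
init_exponential_draw <- function(params,
                                  scale_driver = 10 * params$p,
                                  scale_passenger = 10 * (1 - params$p),
                                  interpretation = c("mean", "rate")) {
  interpretation <- match.arg(interpretation)
  if (scale_driver <= 0 || scale_passenger <= 0) {
    abort("exponential parameters must be positive.")
  }
  rate_d <- if (interpretation == "mean") 1 / scale_driver else scale_driver
  rate_p <- if (interpretation == "mean") 1 / scale_passenger else scale_passenger
  # half-up rounding of the raw draws
  a <- floor(rexp(params$N, rate_d) + 0.5)
  b <- floor(rexp(params$N, rate_p) + 0.5)
  cells <- tibble(alpha = as.integer(a), beta = as.integer(b))
  clones <- cells |>
    dplyr::count(.data$alpha, .data$beta, name = "live_cells") |>
    dplyr::mutate(
      id = dplyr::row_number(), parent_id = NA_integer_, origin = "root",
      fitness = compute_fitness(.data$alpha, .data$beta, params$s, params$d),
      birth_time = 0
    ) |>
    dplyr::select("id", "parent_id", "alpha", "beta", "origin", "fitness",
                  "live_cells", "birth_time")
  new_population(0, clones, params$N)
}

#' Mutation carrier counts from the clone genealogy
#'
#' Each non-initial clone corresponds to exactly one mutation; the number of
#' cells carrying that mutation is the number of live cells in the clone's
#' descendant subtree (inclusive), because every descendant clone inherits the
#' mutation.
#'
#' @param pop A `tugwar_pop`, or its clone tibble.
#' @return A tibble with columns `id` (mutation / clone id), `origin`, and
#'   `carriers` in `[0, N]`, one row per non-initial clone.
#' @examples
#' p <- tugwar_params(N = 100, mu = 0.1, t_max = 5)
#' set.seed(1)
#' carrier_counts(sim_run(p)$final)
#' @export
carrier_counts <- function(pop) {
  clones <- if (inherits(pop, "tugwar_pop")) pop$clones else as_tibble(pop)
  n <- nrow(clones)
  idx <- match(clones$parent_id, clones$id)  # row index of each parent
  carriers <- numeric(n)
  for (k in seq_len(n)) {
    if (clones$live_cells[k] == 0) next
    j <- k
    steps <- 0L
    while (!is.na(j)) {
      carriers[j] <- carriers[j] + clones$live_cells[k]
      j <- idx[j]
      steps <- steps + 1L
      if (steps > n) abort("cycle detected in clone parent links.")
    }
  }
  keep <- clones$origin != "root"
  tibble(id = clones$id[keep], origin = clones$origin[keep],
         carriers = as.integer(carriers[keep]))
}

#' Allele-size summary of a population (infinite allele model)
#'
#' Under the infinite allele model every mutation creates a new allele, so the
#' alleles present in the population are exactly the clones with at least one
#' live cell. Returns the observed number of alleles `k` and the allele-size
#' spectrum `a[j]` = number of alleles carried by exactly `j` cells.
#'
#' @param pop A `tugwar_pop`.
#' @return A list with elements `n` (cells), `k` (alleles), and `a` (integer
#'   vector of length `n` with `sum(j * a[j]) = n`, `sum(a) = k`).
#' @examples
#' allele_summary(init_homogeneous(tugwar_params(N = 10)))
#' @export
allele_summary <- function(pop) {
  stopifnot(inherits(pop, "tugwar_pop"))
  sizes <- pop$clones$live_cells[pop$clones$live_cells > 0]
  n <- pop$N
  a <- tabulate(sizes, nbins = n)
  list(n = n, k = length(sizes), a = a)
}

#' Genealogy as an edge list
#'
#' @param pop A `tugwar_pop`.
#' @return Tibble with columns `child_id`, `parent_id`, `origin_kind`,
#'   `alpha`, `beta`, `birth_time`, `live_cells_at_end` (one row per clone;
#'   initial clones have `parent_id = NA`).
#' @export
genealogy_edges <- function(pop) {
  cl <- pop$clones
  tibble(child_id = cl$id, parent_id = cl$parent_id, origin_kind = cl$origin,
         alpha = cl$alpha, beta = cl$beta, birth_time = cl$birth_time,
         live_cells_at_end = cl$live_cells)
}

#' Genealogy in Newick format
#'
#' Serialises the clone genealogy with clone ids as node labels. When the
#' population has several initial clones the forest is joined under a label-
#' less artificial root.
#'
#' @param pop A `tugwar_pop`.
#' @return A single Newick string (terminated by `;`).
#' @export
genealogy_newick <- function(pop) {
  cl <- pop$clones
  n <- nrow(cl)
  idx <- match(cl$parent_id, cl$id)
  depth <- integer(n)
  for (k in seq_len(n)) {
    j <- idx[k]
    dpt <- 0L
    while (!is.na(j)) {
      dpt <- dpt + 1L
      j <- idx[j]
      if (dpt > n) abort("cycle detected in clone parent links.")
    }
    depth[k] <- dpt
  }
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  lab <- as.character(cl$id)
  node_str <- character(n)
  for (k in order(depth, decreasing = TRUE)) {
    kids <- children[[k]]
    node_str[k] <- if (length(kids) == 0) {
      lab[k]
    } else {
      paste0("(", paste(node_str[kids], collapse = ","), ")", lab[k])
    }
  }
  roots <- which(is.na(idx))
  if (length(roots) == 1) {
    paste0(node_str[roots], ";")
  } else {
    paste0("(", paste(node_str[roots], collapse = ","), ");")
  }
}
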