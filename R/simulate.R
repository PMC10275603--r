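#' Advance a population by one event (reference implementation)
#'
#' Pure-R single transition of the tug-of-war Markov chain, used as the
#' readable reference for the compiled event loop in [sim_run()]. Time is
#' advanced by an exponential draw with total rate `sigma_P + N * mu`; with
#' probability `sigma_P / (sigma_P + N * mu)` a death--replacement is applied
#' (dying and replacing clone drawn from [death_replacement_pmfs()],
#' independently, so self-replacement is a legal no-op), otherwise a uniformly
#' chosen cell founds a new clone by gaining a driver (probability `p`) or a
#' passenger (probability `1 - p`).
#'
#' @param pop A `tugwar_pop`.
#' @param params A [tugwar_params()] object.
#' @return The updated `tugwar_pop`.
#' @examples
#' set.seed(1)
#' sim_step(init_homogeneous(tugwar_params(N = 10, mu = 0.1)),
#'          tugwar_params(N = 10, mu = 0.1))
#' @export
sim_step <- function(pop, params) {
  stopifnot(inherits(pop, "tugwar_pop"))
  cl <- pop$clones
  sigma <- sigma_total(pop)
  if (sigma <= 0) abort("total fitness must be positive.")
  total <- sigma + params$N * params$mu
  pop$time <- pop$time + rexp(1, rate = total)
  if (runif(1) * total < sigma) {
    pm <- death_replacement_pmfs(pop, params$model)
    i <- sample.int(nrow(cl), 1, prob = pm$p_die)
    j <- sample.int(nrow(cl), 1, prob = pm$p_rep)
    if (i != j) {
      cl$live_cells[i] <- cl$live_cells[i] - 1L
      cl$live_cells[j] <- cl$live_cells[j] + 1L
    }
  } else {
    i <- sample.int(nrow(cl), 1, prob = cl$live_cells)
    driver <- runif(1) < params$p
    a <- cl$alpha[i] + as.integer(driver)
    b <- cl$beta[i] + as.integer(!driver)
    cl$live_cells[i] <- cl$live_cells[i] - 1L
    cl <- dplyr::bind_rows(cl, tibble(
      id = max(cl$id) + 1L, parent_id = cl$id[i], alpha = a, beta = b,
      origin = if (driver) "driver" else "passenger",
      fitness = compute_fitness(a, b, params$s, params$d),
      live_cells = 1L, birth_time = pop$time
    ))
  }
  pop$clones <- cl
  pop
}

#' Run a tug-of-war simulation
#'
#' Event-driven (Gillespie-style) simulation of the time-continuous Markov
#' chain until `t_max`, with trajectory and snapshot recorders. The
#' population-average fitness is recorded on `record_grid` by carrying the
#' state forward between events; full clone-size snapshots are stored at
#' `snapshot_times` for succession analysis. Reproducible under `set.seed()`.
#'
#' @param params A [tugwar_params()] object.
#' @param init `"homogeneous"` (default) or `"expdraw"`
#'   ([init_exponential_draw()] with its default scales), or supply `init_pop`.
#' @param init_pop Optional `tugwar_pop` to start from (overrides `init`).
#' @param record_grid Times at which to record population-average fitness;
#'   default `seq(0, t_max)`.
#' @param snapshot_times Times at which to store full clone-size snapshots.
#' @return A `tugwar_run` object: list with elements `params`, `final`
#'   (`tugwar_pop` at `t_max`), `trajectory` (tibble `time`, `mean_fitness`),
#'   `snapshots` (list of `time` + live-cell vectors), `clone_total` (clones
#'   ever created, initial clones included), and `event_counts` (named vector:
#'   `death_replacement`, `mutation_driver`, `mutation_passenger`).
#' @examples
#' set.seed(42)
#' run <- sim_run(tugwar_params(N = 100, mu = 0.1, p = 0.0909,
#'                              s = 0.1, d = 0.01, t_max = 10))
#' glance(run)
#' @export
sim_run <- function(params, init = c("homogeneous", "expdraw"),
                    init_pop = NULL,
                    record_grid = seq(0, params$t_max),
                    snapshot_times = numeric(0)) {
  stopifnot(inherits(params, "tugwar_params"))
  if (is.null(init_pop)) {
    init <- match.arg(init)
    init_pop <- switch(init,
      homogeneous = init_homogeneous(params),
      expdraw = init_exponential_draw(params))
  }
  record_grid <- sort(record_grid)
  snapshot_times <- sort(snapshot_times)
  if (length(record_grid) && (min(record_grid) < 0 ||
                              max(record_grid) > params$t_max)) {
    abort("`record_grid` must lie within [0, t_max].")
  }
  cl0 <- init_pop$clones
  res <- sim_core(params$N, params$mu, params$p, params$s, params$d,
                  model = match(params$model, c("A", "B")) - 1L,
                  t_max = params$t_max, max_events = params$max_events,
                  init_alpha = cl0$alpha, init_beta = cl0$beta,
                  init_live = cl0$live_cells,
                  record_grid = as.numeric(record_grid),
                  snapshot_times = as.numeric(snapshot_times))
  n_tot <- length(res$alpha)
  n0 <- nrow(cl0)
  clones <- tibble(
    id = seq_len(n_tot),
    parent_id = res$parent,
    alpha = res$alpha, beta = res$beta,
    origin = c("root", "driver", "passenger")[res$origin + 1L],
    fitness = res$fitness, live_cells = res$live,
    birth_time = res$birth
  )
  final <- new_population(res$time, clones, params$N)
  out <- structure(list(
    params = params,
    final = final,
    trajectory = tibble(time = as.numeric(record_grid),
                        mean_fitness = res$trajectory),
    snapshots = list(time = snapshot_times, live = res$snapshots),
    clone_total = n_tot,
    event_counts = c(death_replacement = res$n_death_replacement,
                     mutation_driver = res$n_mut_driver,
                     mutation_passenger = res$n_mut_passenger),
    n_initial_clones = n0,
    capped = res$capped
  ), class = "tugwar_run")
  if (res$capped) {
    abort(sprintf("event cap (%g) exceeded at t = %g; partial result attached as `result`.",
                  params$max_events, res$time),
          class = "tugwar_cap_error", result = out)
  }
  out
}

#' @method print tugwar_run
#' @export
print.tugwar_run <- function(x, ...) {
  cat(sprintf("<tugwar_run> Model %s, N = %d, t = %g: %d clones ever created, %g events\n",
              x$params$model, x$params$N, x$final$time, x$clone_total,
              sum(x$event_counts)))
  invisible(x)
}

#' @describeIn sim_run Clone-level tibble of the final state (genealogy edge
#'   list with fitness and final cell counts).
#' @param x A `tugwar_run`.
#' @param ... Unused.
#' @method tidy tugwar_run
#' @export
tidy.tugwar_run <- function(x, ...) {
  dplyr::mutate(genealogy_edges(x$final), fitness = x$final$clones$fitness)
}

#' @describeIn sim_run One-row run summary.
#' @method glance tugwar_run
#' @export
glance.tugwar_run <- function(x, ...) {
  tibble(
    model = x$params$model, N = x$params$N, t_final = x$final$time,
    clone_total = x$clone_total,
    clones_alive = sum(x$final$clones$live_cells > 0),
    death_replacements = unname(x$event_counts["death_replacement"]),
    driver_mutations = unname(x$event_counts["mutation_driver"]),
    passenger_mutations = unname(x$event_counts["mutation_passenger"]),
    mean_fitness = sigma_total(x$final) / x$params$N
  )
}

#' @method glance tugwar_pop
#' @export
glance.tugwar_pop <- function(x, ...) {
  tibble(time = x$time, N = x$N, clones_alive = sum(x$clones$live_cells > 0),
         mean_fitness = sigma_total(x) / x$N)
}

#' Clone succession grouped by driver haplotype
#'
#' Groups clones by the set of driver mutations on their path to the root
#' (keyed by the most recent driver-origin ancestor, since drivers accumulate
#' along a lineage) and reports, for every stored snapshot, each group's cell
#' fraction and its cell-weighted mean fitness across the passenger subclones
#' sharing that driver haplotype.
#'
#' @param run A `tugwar_run` produced with non-empty `snapshot_times`, or a
#'   `tugwar_pop` (treated as a single snapshot at its current time).
#' @return Tibble with columns `time`, `driver_group` (clone id of the most
#'   recent driver ancestor; `0` for the driver-free background), `fraction`,
#'   `mean_fitness`. Fractions sum to 1 within each snapshot.
#' @examples
#' set.seed(7)
#' run <- sim_run(tugwar_params(N = 50, mu = 0.2, p = 0.2, s = 0.2,
#'                              t_max = 20), snapshot_times = c(10, 20))
#' succession_by_driver(run)
#' @export
succession_by_driver <- function(run) {
  if (inherits(run, "tugwar_pop")) {
    cl <- run$clones
    snaps <- list(time = run$time, live = list(cl$live_cells))
    N <- run$N
  } else {
    stopifnot(inherits(run, "tugwar_run"))
    cl <- run$final$clones
    snaps <- run$snapshots
    N <- run$params$N
    if (length(snaps$live) == 0) {
      snaps <- list(time = run$final$time, live = list(cl$live_cells))
    }
  }
  n <- nrow(cl)
  idx <- match(cl$parent_id, cl$id)
  group <- integer(n)  # most recent driver-origin ancestor (incl. self), 0 if none
  for (k in seq_len(n)) {
    j <- k
    g <- 0L
    while (!is.na(j)) {
      if (cl$origin[j] == "driver") { g <- cl$id[j]; break }
      j <- idx[j]
    }
    group[k] <- g
  }
  purrr::map2_dfr(snaps$time, snaps$live, function(tm, live) {
    m <- length(live)
    tibble(time = tm, driver_group = group[seq_len(m)],
           live = live, fitness = cl$fitness[seq_len(m)]) |>
      dplyr::filter(.data$live > 0) |>
      dplyr::group_by(.data$time, .data$driver_group) |>
      dplyr::summarise(
        fraction = sum(.data$live) / N,
        mean_fitness = sum(.data$live * .data$fitness) / sum(.data$live),
        .groups = "drop")
  })
}
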