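test_that("identical seeds give identical runs", {
  p <- tugwar_params(N = 50, mu = 0.2, p = 0.3, s = 0.2, d = 0.05, t_max = 20)
  set.seed(123)
  r1 <- sim_run(p, snapshot_times = c(10, 20))
  set.seed(123)
  r2 <- sim_run(p, snapshot_times = c(10, 20))
  expect_identical(r1$final$clones, r2$final$clones)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$event_counts, r2$event_counts)
  expect_identical(r1$snapshots$live, r2$snapshots$live)
})

test_that("without mutation the composition of a homogeneous population is frozen", {
  p <- tugwar_params(N = 100, mu = 0, t_max = 10)
  set.seed(1)
  run <- sim_run(p)
  expect_equal(run$clone_total, 1)
  expect_equal(run$final$clones$live_cells, 100L)
  expect_equal(unname(run$event_counts[c("mutation_driver",
                                         "mutation_passenger")]), c(0, 0))
  expect_gt(run$event_counts["death_replacement"], 0)  # self-replacements tick
  expect_equal(run$trajectory$mean_fitness, rep(1, 11))
})

test_that("event bookkeeping ties clones to mutation events", {
  p <- tugwar_params(N = 100, mu = 0.1, p = 0.0909, s = 0.1, d = 0.01,
                     t_max = 50)
  set.seed(9)
  run <- sim_run(p)
  expect_equal(run$clone_total,
               1 + unname(run$event_counts["mutation_driver"] +
                            run$event_counts["mutation_passenger"]))
  expect_equal(sum(run$final$clones$live_cells), 100)
  # every non-initial clone differs from its parent by exactly one mutation
  cl <- run$final$clones
  kid <- which(!is.na(cl$parent_id))
  pid <- match(cl$parent_id[kid], cl$id)
  dd <- (cl$alpha[kid] - cl$alpha[pid]) + (cl$beta[kid] - cl$beta[pid])
  expect_true(all(dd == 1))
  expect_equal(cl$fitness,
               compute_fitness(cl$alpha, cl$beta, 0.1, 0.01))
})

test_that("driver fraction among mutations converges to p", {
  p <- tugwar_params(N = 100, mu = 1, p = 0.1, t_max = 30)
  set.seed(5)
  run <- sim_run(p)
  nd <- unname(run$event_counts["mutation_driver"])
  nm <- nd + unname(run$event_counts["mutation_passenger"])
  expect_gt(nm, 2000)
  # three binomial sigmas around p
  expect_lt(abs(nd / nm - 0.1), 3 * sqrt(0.1 * 0.9 / nm))
})

test_that("mutation counts over [0, t] are Poisson(N mu t)", {
  p <- tugwar_params(N = 20, mu = 0.5, p = 0.5, t_max = 5)
  set.seed(77)
  counts <- vapply(1:500, function(i) {
    run <- sim_run(p, record_grid = numeric(0))
    run$clone_total - 1L
  }, integer(1))
  lambda <- 20 * 0.5 * 5
  # chi-square goodness of fit with pooled tails (expected >= 5 per bin)
  lo <- qpois(0.005, lambda); hi <- qpois(0.995, lambda)
  obs <- c(sum(counts <= lo),
           vapply((lo + 1):(hi - 1), function(v) sum(counts == v), numeric(1)),
           sum(counts >= hi))
  pr <- c(ppois(lo, lambda),
          dpois((lo + 1):(hi - 1), lambda),
          ppois(hi - 1, lambda, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("inter-event rate matches the total-rate formula", {
  # N = 100 cells at fitness 1 with mu = 0.1: total rate 110
  p <- tugwar_params(N = 100, mu = 0.1, p = 0.5, t_max = 1000)
  set.seed(31)
  run <- sim_run(p, record_grid = numeric(0))
  n_ev <- sum(run$event_counts)
  # the observed mean rate drifts only because mutations change sigma_P
  # slowly at s = d = 0 (they do not: fitness stays 1)
  expect_equal(n_ev / 1000, 110, tolerance = 0.02)
})

test_that("Model A is a drift martingale and Model B drifts upward", {
  pA <- tugwar_params(N = 100, mu = 0, s = 0.01, d = 0.01, p = 0.5, t_max = 30)
  pB <- tugwar_params(N = 100, mu = 0, s = 0.01, d = 0.01, p = 0.5, t_max = 30,
                      model = "B")
  set.seed(2024)
  fitA <- replicate(200, {
    run <- sim_run(pA, init = "expdraw", record_grid = c(0, 30))
    run$trajectory$mean_fitness
  })
  expect_lt(abs(mean(fitA[2, ]) - mean(fitA[1, ])),
            3 * stats::sd(fitA[2, ] - fitA[1, ]) / sqrt(200))
  set.seed(2024)
  fitB <- replicate(200, {
    run <- sim_run(pB, init = "expdraw", record_grid = c(0, 30))
    run$trajectory$mean_fitness
  })
  expect_gt(mean(fitB[2, ]) - mean(fitB[1, ]),
            3 * stats::sd(fitB[2, ] - fitB[1, ]) / sqrt(200))
})

test_that("at mutational equilibrium sp = d(1-p) Model A shows no fitness trend", {
  p <- tugwar_params(N = 100, mu = 0.1, p = 0.0909, s = 0.1, d = 0.01,
                     t_max = 50)
  set.seed(404)
  fits <- replicate(100, {
    run <- sim_run(p, record_grid = c(0, 50))
    run$trajectory$mean_fitness[2]
  })
  expect_lt(abs(mean(fits) - 1), 3 * stats::sd(fits) / sqrt(100))
})

test_that("the event cap raises a condition carrying the partial result", {
  p <- tugwar_params(N = 50, mu = 0.5, p = 0.5, t_max = 100, max_events = 200)
  set.seed(8)
  err <- tryCatch(sim_run(p), tugwar_cap_error = function(e) e)
  expect_s3_class(err, "tugwar_cap_error")
  expect_s3_class(err$result, "tugwar_run")
  expect_true(err$result$capped)
  expect_lt(err$result$final$time, 100)
  expect_equal(sum(err$result$final$clones$live_cells), 50)
})

test_that("the pure-R stepper preserves the population invariants", {
  p <- tugwar_params(N = 15, mu = 0.5, p = 0.3, s = 0.2, d = 0.05, t_max = 10)
  pop <- init_homogeneous(p)
  set.seed(55)
  for (i in 1:200) pop <- sim_step(pop, p)
  expect_equal(sum(pop$clones$live_cells), 15)
  expect_gt(pop$time, 0)
  expect_equal(nrow(pop$clones),
               1 + sum(pop$clones$origin != "root"))
  expect_equal(pop$clones$fitness,
               compute_fitness(pop$clones$alpha, pop$clones$beta, 0.2, 0.05))
})

test_that("succession groups clones by driver haplotype", {
  # no drivers: one background group with fraction 1
  bg <- tugwar:::new_population(
    0, make_clones(1:2, c(NA, 1), live = c(3, 7),
                   origin = c("root", "passenger")), 10)
  s <- succession_by_driver(bg)
  expect_equal(nrow(s), 1)
  expect_equal(s$fraction, 1)

  # two driver clades of 30 and 70 cells
  clades <- tugwar:::new_population(
    0, make_clones(1:3, c(NA, 1, 1), live = c(0, 30, 70),
                   origin = c("root", "driver", "driver")), 100)
  s2 <- succession_by_driver(clades) |> dplyr::arrange(driver_group)
  expect_equal(s2$fraction, c(0.3, 0.7))

  # passenger subclones under one driver: cell-weighted mean fitness
  f1 <- 1.1 * 0.99; f2 <- 1.1 * 0.99^2
  sub <- tugwar:::new_population(
    0, make_clones(1:4, c(NA, 1, 2, 2), live = c(0, 0, 5, 5),
                   origin = c("root", "driver", "passenger", "passenger"),
                   fitness = c(1, 1.1, f1, f2)), 10)
  s3 <- succession_by_driver(sub)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$driver_group, 2)
  expect_equal(s3$mean_fitness, 1.1 * 0.99 * (1 + 0.99) / 2)
  expect_equal(s3$fraction, 1)

  # snapshot fractions always sum to 1
  p <- tugwar_params(N = 40, mu = 0.3, p = 0.3, s = 0.3, t_max = 20)
  set.seed(12)
  run <- sim_run(p, snapshot_times = c(5, 10, 20))
  tot <- succession_by_driver(run) |>
    dplyr::group_by(time) |>
    dplyr::summarise(f = sum(fraction))
  expect_equal(tot$f, rep(1, 3))
})
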