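test_that("global-peak estimation matches exhaustive enumeration on a tiny grid", {
  grid <- build_grid(n_levels = 6, seed = 12)
  model <- grn_model()
  states <- as.matrix(do.call(expand.grid, rep(list(1:6), 6)))
  Fall <- landscape_fitness(grid, states, model)
  true_best <- max(Fall)
  pk <- estimate_global_peak(grid, model, n_restarts = 20, seed = 1,
                             check_continuous = FALSE)
  expect_equal(pk$fitness, true_best)
  expect_equal(landscape_fitness(grid, pk$genotype, model), true_best)

  # cost-free limit: benefit-only optimum, still equal to enumeration
  m0 <- grn_model(constants = fitness_constants(alpha = 0))
  F0 <- landscape_fitness(grid, states, m0)
  pk0 <- estimate_global_peak(grid, m0, n_restarts = 20, seed = 1,
                              check_continuous = FALSE)
  expect_equal(pk0$fitness, max(F0))
})

test_that("grid and continuous peak estimators agree on the default landscape", {
  grid <- build_grid(seed = 1)
  pk <- estimate_global_peak(grid, seed = 1)
  expect_true(pk$agreement)
  expect_gte(pk$continuous$fitness, pk$fitness - 1e-12)
  expect_lte(abs(pk$continuous$fitness - pk$fitness),
             1e-3 * max(1, pk$continuous$fitness))
})

test_that("child seeds are deterministic, order-sensitive and reproducible", {
  expect_identical(child_seed(1, 50, 2, 17), child_seed(1, 50, 2, 17))
  expect_false(child_seed(1, 50, 2) == child_seed(1, 2, 50))
  expect_false(child_seed(1, 50) == child_seed(2, 50))
  expect_true(all(vapply(1:100, function(i) child_seed(i, 7, 3), 1L) >= 0))

  # design points are independently reproducible in any execution order
  toy <- two_peak_toy()
  ch <- walk_chain(toy)
  eAB <- lapply(list(c(2L, 2L), c(1L, 3L)), function(s)
    run_ensemble(toy, s, 20, peak_fitness = max(toy$fitness),
                 seed = child_seed(9, fitscape:::.toy_encode(s, toy$levels))))
  eBA <- lapply(list(c(1L, 3L), c(2L, 2L)), function(s)
    run_ensemble(toy, s, 20, peak_fitness = max(toy$fitness),
                 seed = child_seed(9, fitscape:::.toy_encode(s, toy$levels))))
  expect_identical(eAB[[1]]$fitness, eBA[[2]]$fitness)
  expect_identical(eAB[[2]]$fitness, eBA[[1]]$fitness)
})

test_that("toy ensembles match the chain and pad terminated replicates", {
  toy <- two_peak_toy()
  ch <- walk_chain(toy)
  start <- c(2L, 2L)
  code <- fitscape:::.toy_encode(start, toy$levels)
  ens <- run_ensemble(toy, start, 300, peak_fitness = max(toy$fitness),
                      seed = 77)
  p <- ch$p_global[code]
  expect_lte(abs(ens$fraction_reached - p), 3 * sqrt(p * (1 - p) / 300))
  expect_lte(abs(mean(ens$steps) - ch$expected_steps[code]),
             3 * sd(ens$steps) / sqrt(300))

  # padding: after termination a replicate's fitness is carried forward
  # (walk lengths vary on the single-peaked toy)
  ep <- run_ensemble(single_peak_toy(), c(1L, 1L), 50, seed = 11)
  expect_gt(max(ep$steps), min(ep$steps))
  for (r in which(ep$steps < max(ep$steps))) {
    tailvals <- ep$fitness[r, (ep$steps[r] + 1L):ncol(ep$fitness)]
    expect_true(all(tailvals == ep$terminal_fitness[r]))
  }
  # variance starts at zero (shared start) and ends positive (two basins)
  expect_equal(ens$var_fitness[1], 0)
  expect_gt(ens$var_fitness[length(ens$var_fitness)], 1e-4)
  expect_identical(ens$steps_to_peak[!ens$reached],
                   rep(NA_integer_, sum(!ens$reached)))
})

test_that("speed and variance series behave as defined", {
  toy <- two_peak_toy()
  # start at the peak: degenerate one-point series, zero speed
  epk <- run_ensemble(toy, c(3L, 3L), 10, peak_fitness = max(toy$fitness),
                      seed = 5)
  sp0 <- speed_of_evolution(epk)
  expect_identical(sp0$summary$peak_speed, 0)
  expect_null(sp0$series)

  ens <- run_ensemble(toy, c(2L, 2L), 100, peak_fitness = max(toy$fitness),
                      seed = 6)
  sp <- speed_of_evolution(ens)
  # the mean of monotone non-decreasing padded trajectories is monotone
  expect_true(all(sp$series$speed >= 0))
  expect_gt(sp$summary$peak_speed, 0)

  vd <- variance_dynamics(ens)
  expect_equal(vd$series$variance[1], 0)
  expect_equal(vd$summary$terminal_var,
               var(ens$terminal_fitness))
  expect_gte(vd$summary$peak_var, vd$summary$terminal_var)

  # identical replicates: variance identically zero
  w <- adaptive_walk(toy, c(2L, 2L), seed = 8)
  ens0 <- fitscape:::.ensemble_from_walks(list(w, w, w), c(2L, 2L),
                                          peak_fitness = max(toy$fitness),
                                          reach_tol = 1e-9, seed = 8,
                                          K_conn = NA_integer_,
                                          mean_degree = NA_real_)
  expect_true(all(ens0$var_fitness == 0))

  # terminal variance is zero iff all terminal fitnesses coincide
  expect_identical(all(ens$terminal_fitness == ens$terminal_fitness[1]),
                   vd$summary$terminal_var == 0)
})

test_that("reduced critical-K scan is well-formed and monotone on a small grid", {
  grid <- build_grid(n_levels = 150, seed = 31)
  design <- experiment_design(K_values = c(2, 8, 30), start_fitness = c(0.25, 0.6),
                              n_replicates = 15)
  scan <- critical_k_scan(grid, design, seed = 41)
  expect_identical(nrow(scan$table), 6L)
  expect_true(all(scan$table$fraction_reached >= 0 &
                    scan$table$fraction_reached <= 1))
  # pooled fractions non-decreasing in K (graph-ensemble averages)
  pooled <- tapply(scan$table$fraction_reached, scan$table$K, mean)
  expect_true(all(diff(pooled[order(as.numeric(names(pooled)))]) >= -0.1))
  # replicate fractions at the largest K dominate the smallest K
  expect_gte(pooled[length(pooled)], pooled[1])

  # identical seed reproduces the scan exactly
  scan2 <- critical_k_scan(grid, design, seed = 41)
  expect_identical(scan$table, scan2$table)
  expect_identical(scan$transition_K, scan2$transition_K)
})

test_that("sensitivity scan with unit multipliers reproduces the base scan", {
  grid <- build_grid(n_levels = 120, seed = 51)
  design <- experiment_design(K_values = c(3, 20), start_fitness = 0.4,
                              n_replicates = 10)
  base <- critical_k_scan(grid, design, seed = 61)
  sens <- fitness_function_sensitivity(grid, design,
                                       scenarios = list(unit = c(a = 1)),
                                       base = base, seed = 61)
  expect_identical(sens$table$transition_K[1], sens$table$transition_K[2])
  expect_identical(sens$scans$unit$table, base$table)
  expect_true(sens$invariant)
})
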