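test_that("closed-form steady state zeroes the dynamics, including boundary regimes", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_pset()
    S <- runif(1, 0, 2)
    ss <- steady_state(p, S)
    expect_true(all(unlist(ss) >= 0))
    res <- steady_state_residuals(p, S, ss)
    expect_lt(max(abs(res)), 1e-9 * max(1, abs(unlist(ss))))
  }

  # no production at all
  p0 <- param_set(bas = 0, k_act = 0.5, k_d = 1e-3, beta = 1, K_m = 10,
                  k_dT = 1e-3)
  expect_equal(unlist(steady_state(p0, 1)), c(R = 0, R_star = 0, T = 0))
  expect_equal(genotype_fitness(p0, 1)$F, 0)

  # no target expression: R, R* from the linear subsystem
  p1 <- param_set(bas = 0.2, k_act = 0.5, k_d = 1e-3, beta = 0, K_m = 10,
                  k_dT = 1e-3)
  ss1 <- steady_state(p1, 1)
  expect_equal(ss1$T, 0)
  expect_equal(ss1$R, 0.2 * (p1$k_r + 1e-3) / (1e-3 * (p1$k_r + 1e-3 + 0.5)))
  expect_gt(ss1$R_star, 0)

  # no signal: everything sits in the inactive pool
  p2 <- param_set(bas = 0.2, k_act = 0.5, k_d = 1e-3, beta = 1, K_m = 10,
                  k_dT = 1e-3)
  ss2 <- steady_state(p2, 0)
  expect_equal(ss2$R_star, 0)
  expect_equal(ss2$T, 0)
  expect_equal(ss2$R, 0.2 / 1e-3)

  # invalid parameters are rejected
  expect_error(param_set(0.1, -1, 1e-3, 1, 10, 1e-3), "invalid parameter")
  expect_error(param_set(0.1, 0.5, 0, 1, 10, 1e-3), "invalid parameter")
  expect_error(param_set(0.1, 0.5, 1e-3, 1, Inf, 1e-3), "invalid parameter")
  expect_error(steady_state(p2, -1), "signal")
})

test_that("steady state matches stiff numerical integration from the origin", {
  set.seed(202)
  for (i in 1:25) {
    p <- random_pset()
    ss <- unlist(steady_state(p, 1))
    out <- integrate_dynamics(p, 1, atol = pmax(1e-12 * ss, 1e-280))
    fin <- unlist(out[nrow(out), c("R", "R_star", "T")])
    expect_lt(max(abs(fin - ss) / pmax(abs(ss), 1e-280)), 1e-6)
  }

  # starting at the fixed point the trajectory stays there
  p <- param_set(bas = 0.1, k_act = 0.5, k_d = 1e-3, beta = 1, K_m = 50,
                 k_dT = 1e-3)
  ss <- steady_state(p, 1)
  out <- integrate_dynamics(p, 1, init = unlist(ss), t_end = 1e4)
  for (col in c("R", "R_star", "T"))
    expect_lt(max(abs(out[[col]] - ss[[col]])) / max(abs(ss[[col]]), 1e-12),
              1e-6)

  expect_error(integrate_dynamics(p, 1, init = c(-1, 0, 0)), "non-negative")
  expect_error(integrate_dynamics(p, 1, t_end = -5), "positive")
})

test_that("fitness components follow the cost-benefit arithmetic", {
  # half-saturation hand case
  ss <- structure(list(R = 0, R_star = 0, T = 10), class = "steady_state")
  fc <- fitness_constants(a = 1, b = 10, alpha = 2.5e-5)
  comp <- fitness_components(ss, fc)
  expect_equal(comp$B, 0.5)
  expect_equal(comp$C, 2.5e-4)
  expect_equal(comp$F, 0.49975)

  # empty cell
  ss0 <- structure(list(R = 0, R_star = 0, T = 0), class = "steady_state")
  expect_equal(unlist(fitness_components(ss0, fc)), c(B = 0, C = 0, F = 0))

  # identities and bounds over random states
  set.seed(303)
  for (i in 1:100) {
    ssr <- structure(list(R = runif(1, 0, 100), R_star = runif(1, 0, 100),
                          T = runif(1, 0, 1e4)), class = "steady_state")
    cr <- fitness_components(ssr, fc)
    expect_identical(cr$F, cr$B - cr$C)
    expect_true(cr$B >= 0 && cr$B < fc$a)
    expect_gte(cr$C, 0)
    expect_lt(cr$F, fc$a)
  }

  # cost-free limit: F -> a monotonically as T grows
  fc0 <- fitness_constants(alpha = 0)
  Ts <- 10^(0:6)
  Fs <- vapply(Ts, function(T)
    fitness_components(structure(list(R = 0, R_star = 0, T = T),
                                 class = "steady_state"), fc0)$F, 0)
  expect_true(all(diff(Fs) > 0))
  expect_true(all(Fs < fc0$a))
  expect_equal(Fs[length(Fs)], 1, tolerance = 1e-4)

  expect_error(fitness_constants(a = -1), "constants")
  expect_error(fitness_constants(alpha = -1), "constants")
})

test_that("fitness is invariant under time rescaling and monotone where expected", {
  set.seed(404)
  for (i in 1:20) {
    p <- random_pset()
    f0 <- genotype_fitness(p, 1)$F
    for (cc in c(10, 0.1)) {
      ps <- param_set(p$bas * cc, p$k_act * cc, p$k_d * cc, p$beta * cc,
                      p$K_m, p$k_dT * cc)
      expect_equal(genotype_fitness(ps, 1)$F, f0, tolerance = 1e-12)
    }
  }

  # T non-decreasing in beta, non-increasing in k_dT; B non-decreasing in T
  p <- random_pset()
  Tb <- vapply(10^seq(-3, 0, length.out = 9), function(b)
    steady_state(param_set(p$bas, p$k_act, p$k_d, b, p$K_m, p$k_dT), 1)$T, 0)
  expect_true(all(diff(Tb) >= 0))
  Td <- vapply(10^seq(-3, -1, length.out = 9), function(kdT)
    steady_state(param_set(p$bas, p$k_act, p$k_d, p$beta, p$K_m, kdT), 1)$T, 0)
  expect_true(all(diff(Td) <= 0))
  fc <- fitness_constants()
  Bs <- vapply(sort(c(Tb, Td)), function(T)
    fitness_components(structure(list(R = 0, R_star = 0, T = T),
                                 class = "steady_state"), fc)$B, 0)
  expect_true(all(diff(Bs) >= 0))
})

test_that("R and C++ fitness routes agree bitwise on random genotypes", {
  grid <- build_grid(n_levels = 200, seed = 11)
  model <- grn_model()
  set.seed(55)
  idx <- matrix(sample.int(200, 6 * 500, replace = TRUE), 500, 6)
  fR <- landscape_fitness(grid, idx, model)
  fC <- fitscape:::cpp_grn_fitness(idx - 1L, fitscape:::.grid_matrix(grid),
                                   model$S, 1, 10, 2.5e-5, TRUE, 1e-3, 0)
  expect_identical(fR, fC)
})
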