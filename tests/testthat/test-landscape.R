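test_that("grid construction: endpoints, ordering, determinism, distribution", {
  g <- build_grid(n_levels = 500, seed = 9)
  for (p in names(g$values)) {
    v <- g$values[[p]]
    r <- g$ranges[g$ranges$name == p, ]
    expect_length(v, 500)
    expect_true(all(diff(v) > 0))
    expect_identical(v[1], r$min)
    expect_identical(v[500], r$max)
  }
  expect_identical(build_grid(n_levels = 500, seed = 9), g)
  expect_false(identical(build_grid(n_levels = 500, seed = 10), g))

  # minimal grid: endpoints plus one interior draw
  lin <- data.frame(name = fitscape:::.PARAMS, min = 0, max = 1,
                    scale = "linear")
  g3 <- build_grid(lin, n_levels = 3, seed = 1)
  for (v in g3$values) {
    expect_identical(v[c(1, 3)], c(0, 1))
    expect_true(v[2] > 0 && v[2] < 1)
  }

  # interior values of a log-scale parameter are log-uniform
  gk <- build_grid(n_levels = 1000, seed = 21)
  v <- gk$values$K_m
  ks <- suppressWarnings(ks.test(log(v[2:999]), "punif", log(1), log(1e3)))
  expect_gt(ks$p.value, 0.01)

  bad <- default_param_ranges()
  bad$min[4] <- bad$max[4]
  expect_error(build_grid(bad), "beta")
  expect_error(build_grid(n_levels = 2), "n_levels")
})

test_that("neighbor networks are symmetric, self-loop-free and degree-correct", {
  for (mode in c("union", "strict")) {
    nw <- build_neighbors(200, 6, sigma = 4, mode = mode, seed = 31)
    deg <- lengths(nw$adj)
    # exhaustive symmetry / self-loop check
    for (i in seq_along(nw$adj)) {
      expect_false(i %in% nw$adj[[i]])
      for (j in nw$adj[[i]]) expect_true(i %in% nw$adj[[j]])
    }
    if (mode == "union") {
      expect_true(all(deg >= 6))          # own draws are kept
      expect_true(mean(deg) >= 6 && mean(deg) <= 12)
    } else {
      expect_true(all(deg <= 6))
      # top-up leaves a small deficit where under-degree nodes are too far
      # apart in the kernel to pair
      expect_gt(mean(deg), 0.97 * 6)
    }
    expect_identical(build_neighbors(200, 6, sigma = 4, mode = mode,
                                     seed = 31), nw)
  }

  # forced complete graphs
  n3 <- build_neighbors(3, 2, sigma = 0.5, seed = 1)
  expect_identical(n3$adj, list(2:3, c(1L, 3L), 1:2))
  nc <- build_neighbors(40, 39, sigma = 2, seed = 1)
  expect_true(all(lengths(nc$adj) == 39))

  expect_error(build_neighbors(10, 10, seed = 1), "K_conn")
  expect_error(build_neighbors(10, 3, sigma = 0, seed = 1), "sigma")
})

test_that("kernel draws follow the rounded truncated Gaussian", {
  set.seed(77)
  n <- 1000; sigma <- 20
  draws <- fitscape:::cpp_kernel_draws(n, 1L, sigma) + 1L
  # interior nodes: boundary truncation negligible at 5 sigma
  interior <- 101:900
  d <- draws[interior, 1] - interior
  expect_true(all(d != 0))
  # exact law of round(N(0, sigma)) conditioned on d != 0
  dd <- 1:200
  pd <- pnorm(dd + 0.5, 0, sigma) - pnorm(dd - 0.5, 0, sigma)
  breaks <- c(0, 5, 10, 15, 20, 25, 30, 40, 200)
  pbin <- vapply(seq_len(length(breaks) - 1), function(b)
    sum(pd[dd > breaks[b] & dd <= breaks[b + 1]]), 0)
  pbin <- pbin / sum(pbin)
  obs <- table(cut(abs(d), breaks))
  chi <- chisq.test(as.vector(obs), p = pbin)
  expect_gt(chi$p.value, 0.01)

  # locality and degree at study-scale connectivity
  nw <- build_neighbors(1000, 50, sigma = 20, mode = "union", seed = 5)
  dist <- unlist(lapply(seq_along(nw$adj), function(i) abs(nw$adj[[i]] - i)))
  expect_lte(median(dist), 2 * sigma)
  expect_gte(nw$mean_degree, 50)
  expect_lte(nw$mean_degree, 100)
})

test_that("one-mutant neighborhoods match exhaustive enumeration", {
  # complete 3-level landscape: 6 parameters x 2 alternatives = 12
  g3 <- build_grid(n_levels = 3, seed = 2)
  l3 <- build_landscape(g3, K_conn = 2, seed = 3)
  nb <- one_mutant_neighbors(l3, c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_identical(nrow(nb), 12L)

  # K-limited toy: set equality with a brute-force scan of the full space
  set.seed(13)
  adj <- lapply(1:3, function(i) build_neighbors(5, 2, sigma = 1.5)$adj)
  toy <- toy_landscape(array(runif(125), dim = c(5, 5, 5)), adj = adj)
  for (g in list(c(1L, 1L, 1L), c(3L, 2L, 5L), c(5L, 5L, 5L), c(2L, 4L, 3L))) {
    got <- sort_rows(one_mutant_neighbors(toy, g))
    want <- brute_neighbors(adj, g)
    dimnames(got) <- dimnames(want) <- NULL
    expect_identical(got, want)
    expect_identical(nrow(got), sum(vapply(1:3, function(p)
      length(adj[[p]][[g[p]]]), 1L)))
  }

  # neighbor relation is symmetric at the genotype level
  g0 <- c(3L, 2L, 5L)
  for (r in seq_len(nrow(one_mutant_neighbors(toy, g0)))) {
    h <- one_mutant_neighbors(toy, g0)[r, ]
    back <- one_mutant_neighbors(toy, h)
    expect_true(any(apply(back, 1, identical, g0)))
  }
})

test_that("landscapes freeze to text bundles and reload bit-exactly", {
  g <- build_grid(n_levels = 100, seed = 41)
  l <- build_landscape(g, K_conn = 8, seed = 42)
  dir <- withr::local_tempdir()
  write_landscape(l, dir)
  expect_true(all(file.exists(file.path(dir, c("values.csv", "edges.csv",
                                               "meta.json")))))
  l2 <- read_landscape(dir)
  expect_identical(l2$grid$values, l$grid$values)
  expect_identical(lapply(l2$networks, `[[`, "adj"),
                   lapply(l$networks, `[[`, "adj"))
  s <- find_start_genotype(g, 0.3, seed = 5)
  w1 <- adaptive_walk(l, s, seed = 99)
  w2 <- adaptive_walk(l2, s, seed = 99)
  expect_identical(w1$fitness, w2$fitness)
  expect_identical(w1$genotypes, w2$genotypes)
})
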