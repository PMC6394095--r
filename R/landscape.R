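#' Default ranges for the six evolvable parameters
#'
#' Physiologically plausible ranges spanning several orders of magnitude for
#' each biochemical parameter, sampled log-uniformly. Concentrations are in
#' arbitrary units (think nM), time in seconds: degradation/dilution rates
#' cover stable proteins diluted by growth up to actively degraded ones;
#' production rates and the activation threshold span typical promoter
#' strengths and transcription-factor operating points. The target's
#' expression budget binds: the maximal attainable steady-state target
#' level (`beta_max / k_dT_min` = 250) sits below the level at which the
#' marginal benefit would fall to the marginal cost, so the fitness peak is
#' pinned by the physiological constraints rather than by cost-benefit
#' saturation alone. The ranges are fully overridable; the graph-level
#' results (the critical-connectivity transition) do not hinge on them.
#'
#' @return A data.frame with columns `name`, `min`, `max`, `scale`
#'   (`"log"` or `"linear"`), one row per parameter in canonical order
#'   (`bas`, `k_act`, `k_d`, `beta`, `K_m`, `k_dT`).
#' @export
default_param_ranges <- function() {
  data.frame(
    name  = .PARAMS,
    min   = c(1e-4, 1e-4, 1e-4, 1e-3, 1e0, 1e-3),
    max   = c(1e0,  1e0,  1e-2, 2.5e-1, 1e3, 1e-1),
    scale = "log",
    stringsAsFactors = FALSE
  )
}

.check_ranges <- function(ranges) {
  need <- c("name", "min", "max", "scale")
  if (!all(need %in% names(ranges)))
    stop("ranges must have columns name, min, max, scale", call. = FALSE)
  missing <- setdiff(.PARAMS, ranges$name)
  if (length(missing))
    stop("missing range for parameter '", missing[1], "'", call. = FALSE)
  ranges <- ranges[match(.PARAMS, ranges$name), , drop = FALSE]
  for (i in seq_len(nrow(ranges))) {
    if (!is.finite(ranges$min[i]) || !is.finite(ranges$max[i]) ||
        ranges$min[i] >= ranges$max[i])
      stop("range for parameter '", ranges$name[i], "' must satisfy min < max",
           call. = FALSE)
    if (!ranges$scale[i] %in% c("log", "linear"))
      stop("range for parameter '", ranges$name[i],
           "' has unknown scale (use 'log' or 'linear')", call. = FALSE)
    if (ranges$scale[i] == "log" && ranges$min[i] <= 0)
      stop("log-scale range for parameter '", ranges$name[i],
           "' requires min > 0", call. = FALSE)
  }
  rownames(ranges) <- NULL
  ranges
}

#' Build the discretized parameter grid
#'
#' For each parameter, the grid holds `n_levels` distinct permissible
#' values: the range endpoints plus `n_levels - 2` values drawn uniformly
#' on the parameter's sampling scale (linear, or log for rate constants),
#' sorted ascending. These are the only values a parameter may ever take.
#'
#' @param ranges range table as from [default_param_ranges()].
#' @param n_levels number of discrete levels per parameter (default 1000).
#' @param seed RNG seed; the grid is deterministic given the seed.
#' @return An object of class `rt_grid`.
#' @export
#' @examples
#' g <- build_grid(n_levels = 100, seed = 1)
#' sapply(g$values, range)
build_grid <- function(ranges = default_param_ranges(), n_levels = 1000L,
                       seed = 1L) {
  ranges <- .check_ranges(ranges)
  if (n_levels < 3) stop("n_levels must be at least 3", call. = FALSE)
  set.seed(seed)
  values <- vector("list", nrow(ranges))
  names(values) <- ranges$name
  for (i in seq_len(nrow(ranges))) {
    lo <- ranges$min[i]; hi <- ranges$max[i]
    draw <- function(m) {
      if (ranges$scale[i] == "log") exp(runif(m, log(lo), log(hi)))
      else runif(m, lo, hi)
    }
    v <- draw(n_levels - 2L)
    # continuous draws collide with probability ~0, but re-draw defensively
    while (anyDuplicated(c(lo, v, hi))) {
      dup <- duplicated(c(lo, v, hi))[-c(1L, n_levels)]
      v[dup] <- draw(sum(dup))
    }
    values[[i]] <- sort(c(lo, v, hi))
  }
  structure(list(values = values, ranges = ranges,
                 n_levels = as.integer(n_levels), seed = as.integer(seed)),
            class = "rt_grid")
}

.grid_matrix <- function(grid) {
  do.call(cbind, grid$values)
}

# 1-based adjacency list -> 0-based CSR for the C++ walk core
.adj_to_csr <- function(adj) {
  deg <- lengths(adj)
  list(offsets = as.integer(c(0L, cumsum(deg))),
       neighbors = as.integer(unlist(adj, use.names = FALSE) - 1L))
}

.complete_adj <- function(n) {
  lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
}

#' Build a Gaussian-kernel mutational neighbor network over grid levels
#'
#' From each level `i`, `K_conn` distinct other levels are drawn with
#' probability proportional to a Gaussian kernel centred on `i` in index
#' (rank) space, standard deviation `sigma` (default 2% of the number of
#' levels), truncated to the grid and renormalized. Neighborhoods are then
#' symmetrized: in `"union"` mode an edge exists if either endpoint drew the
#' other (every node keeps its own `K_conn` draws, so degrees are at least
#' `K_conn` and average roughly 1.4-2x it); in `"strict"` mode proposed edges are accepted
#' in random order only while both endpoints have degree below `K_conn`
#' (degrees end `<= K_conn`, almost all exactly `K_conn`).
#'
#' @param n_levels number of levels.
#' @param K_conn nominal connectivity: distinct levels reachable from a
#'   level by a single mutation, `1 <= K_conn <= n_levels - 1`.
#' @param sigma kernel width in index units (default `0.02 * n_levels`).
#' @param mode `"strict"` (default) or `"union"` symmetrization. Strict
#'   matches the study's definition of connectivity (exactly `K_conn`
#'   values accessible from a level by one mutation); union keeps every
#'   node's own draws and so realizes ~1.4-2x the nominal connectivity.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return An object of class `rt_network`: adjacency list (`adj`,
#'   1-based, sorted), its CSR form (`csr`, 0-based), `K_conn`, `sigma`,
#'   `mode` and the realized `mean_degree`.
#' @export
build_neighbors <- function(n_levels, K_conn, sigma = 0.02 * n_levels,
                            mode = c("strict", "union"), seed = NULL) {
  mode <- match.arg(mode)
  n_levels <- as.integer(n_levels)
  K_conn <- as.integer(K_conn)
  if (K_conn < 1L || K_conn > n_levels - 1L)
    stop("K_conn must lie in [1, n_levels - 1]", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  idx <- seq_len(n_levels)
  if (K_conn == n_levels - 1L) {
    draws <- .complete_adj(n_levels)
  } else if (K_conn <= 4 * sigma) {
    # sequential kernel draws with rejection of repeats (fast path)
    m <- cpp_kernel_draws(n_levels, K_conn, sigma) + 1L
    draws <- lapply(idx, function(i) m[i, ])
  } else {
    # exact weighted sampling without replacement; needed when K demands
    # values far out in the kernel tail
    wd <- pmax(dnorm(0:(n_levels - 1L), mean = 0, sd = sigma), 1e-300)
    draws <- lapply(idx, function(i) {
      cand <- idx[-i]
      sample(cand, K_conn, prob = wd[abs(cand - i) + 1L])
    })
  }

  if (mode == "union") {
    from <- rep(idx, times = lengths(draws))
    to <- unlist(draws, use.names = FALSE)
    a <- pmin(from, to); b <- pmax(from, to)
    key <- a * (n_levels + 1) + b
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  } else if (K_conn == n_levels - 1L) {
    # complete graph is already K-regular; same assembly as union
    from <- rep(idx, times = lengths(draws))
    to <- unlist(draws, use.names = FALSE)
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(a * (n_levels + 1) + b)
    a <- a[keep]; b <- b[keep]
  } else {
    # degree-capped greedy acceptance plus kernel-weighted top-up toward an
    # exactly K_conn-regular graph (C++ core; R RNG)
    dm <- do.call(rbind, draws)
    ed <- cpp_strict_edges(dm - 1L, K_conn, sigma)
    a <- ed$i + 1L
    b <- ed$j + 1L
  }

  nodes <- c(a, b)
  nbrs <- as.integer(c(b, a))
  o <- order(nodes, nbrs)
  adj <- split(nbrs[o], factor(nodes[o], levels = idx))
  names(adj) <- NULL
  structure(list(adj = adj, csr = .adj_to_csr(adj),
                 K_conn = K_conn, sigma = sigma, mode = mode,
                 seed = seed, mean_degree = mean(lengths(adj))),
            class = "rt_network")
}

#' Assemble a full landscape: grid plus one neighbor network per parameter
#'
#' @param grid an [build_grid()] result.
#' @param K_conn nominal per-parameter connectivity.
#' @param sigma kernel width in index units (default 2% of levels).
#' @param mode symmetrization mode, see [build_neighbors()].
#' @param seed seed for the six network draws (networks are built in
#'   canonical parameter order from this seed).
#' @return An object of class `rt_landscape`.
#' @export
#' @examples
#' g <- build_grid(n_levels = 200, seed = 1)
#' l <- build_landscape(g, K_conn = 10, seed = 2)
#' summary(l)
build_landscape <- function(grid, K_conn, sigma = 0.02 * grid$n_levels,
                            mode = c("strict", "union"), seed = 1L) {
  stopifnot(inherits(grid, "rt_grid"))
  mode <- match.arg(mode)
  set.seed(seed)
  networks <- lapply(.PARAMS, function(p)
    build_neighbors(grid$n_levels, K_conn, sigma, mode, seed = NULL))
  names(networks) <- .PARAMS
  structure(list(grid = grid, networks = networks,
                 K_conn = as.integer(K_conn), sigma = sigma, mode = mode,
                 seed = as.integer(seed),
                 mean_degree = mean(vapply(networks, `[[`, 0, "mean_degree"))),
            class = "rt_landscape")
}

#' All one-mutant neighbors of a genotype
#'
#' A one-mutant neighbor differs in exactly one parameter, whose new level
#' is adjacent to the old one in that parameter's neighbor network; a
#' genotype therefore has `sum(degree)` (nominally `6 K`) neighbors.
#'
#' @param x an `rt_landscape` (or `toy_landscape`).
#' @param g genotype: integer vector of 1-based level indices.
#' @return Integer matrix, one neighbor per row, with attribute `"param"`
#'   giving the mutated coordinate of each row.
#' @export
one_mutant_neighbors <- function(x, g) {
  adj <- if (inherits(x, "rt_landscape")) lapply(x$networks, `[[`, "adj") else x$adj
  D <- length(adj)
  stopifnot(length(g) == D)
  rows <- vector("list", D)
  param <- integer(0)
  for (p in seq_len(D)) {
    nb <- adj[[p]][[g[p]]]
    if (length(nb)) {
      m <- matrix(rep(g, each = length(nb)), nrow = length(nb))
      m[, p] <- nb
      rows[[p]] <- m
      param <- c(param, rep(p, length(nb)))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(0), 0, D)
  attr(out, "param") <- param
  out
}

#' Parameter values of one or more genotypes
#'
#' @param grid an `rt_grid` (or an `rt_landscape`, whose grid is used).
#' @param g genotype vector or matrix of 1-based level indices (rows =
#'   genotypes).
#' @return Numeric matrix of raw parameter values, columns in canonical
#'   order.
#' @export
genotype_params <- function(grid, g) {
  if (inherits(grid, "rt_landscape")) grid <- grid$grid
  gm <- .grid_matrix(grid)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  out <- matrix(gm[cbind(as.vector(g), rep(seq_len(ncol(g)), each = nrow(g)))],
                nrow(g), ncol(g))
  colnames(out) <- .PARAMS
  out
}

#' Fitness of genotypes on a landscape
#'
#' @param x an `rt_landscape` or `rt_grid`.
#' @param g genotype vector or matrix of 1-based level indices.
#' @param model a [grn_model()].
#' @param components if `TRUE` return the full list of steady-state and
#'   fitness components; otherwise just the fitness vector.
#' @return Numeric fitness vector, or a list of component vectors.
#' @export
landscape_fitness <- function(x, g, model = grn_model(), components = FALSE) {
  P <- genotype_params(x, g)
  comp <- .fitness_vec(P, model)
  if (components) comp else comp$F
}

#' @export
print.rt_grid <- function(x, ...) {
  cat(sprintf("<rt_grid> %d parameters x %d levels (seed %d)\n",
              length(x$values), x$n_levels, x$seed))
  invisible(x)
}

#' @export
print.rt_network <- function(x, ...) {
  cat(sprintf("<rt_network> %d nodes, K_conn = %d, sigma = %g, mode = %s, mean degree %.2f\n",
              length(x$adj), x$K_conn, x$sigma, x$mode, x$mean_degree))
  invisible(x)
}

#' @export
print.rt_landscape <- function(x, ...) {
  cat(sprintf("<rt_landscape> %d x %d levels | K_conn = %d, sigma = %g, mode = %s, mean degree %.2f\n",
              length(x$grid$values), x$grid$n_levels, x$K_conn, x$sigma,
              x$mode, x$mean_degree))
  invisible(x)
}

#' @export
summary.rt_landscape <- function(object, ...) {
  deg <- unlist(lapply(object$networks, function(n) lengths(n$adj)))
  cat(sprintf("Landscape: %d parameters x %d levels (grid seed %d)\n",
              length(object$grid$values), object$grid$n_levels, object$grid$seed))
  cat(sprintf("Neighbor networks: K_conn = %d, sigma = %g, mode = %s (seed %d)\n",
              object$K_conn, object$sigma, object$mode, object$seed))
  cat(sprintf("Realized degree: min %d / mean %.2f / max %d\n",
              min(deg), mean(deg), max(deg)))
  invisible(object)
}
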