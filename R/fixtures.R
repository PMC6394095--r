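# Toy landscapes: explicit fitness tables on tiny grids, small enough to
# enumerate every genotype and every walk exactly. These are the oracle
# substrate for the walk and ensemble machinery.

#' Construct a toy landscape from an explicit fitness table
#'
#' @param fitness numeric array (or vector for one dimension); `dim(fitness)`
#'   gives the number of levels per parameter.
#' @param adj optional list of per-dimension adjacency lists (1-based). By
#'   default every dimension gets the complete graph.
#' @param networks optional list of `rt_network` objects (overrides `adj`).
#' @return An object of class `toy_landscape`.
#' @export
#' @examples
#' t <- toy_landscape(c(0.1, 0.3, 0.2))
#' local_optima(t)
toy_landscape <- function(fitness, adj = NULL, networks = NULL) {
  fitness <- as.array(fitness)
  levels <- dim(fitness)
  D <- length(levels)
  if (!is.null(networks)) adj <- lapply(networks, `[[`, "adj")
  if (is.null(adj)) adj <- lapply(levels, .complete_adj)
  stopifnot(length(adj) == D, all(lengths(adj) == levels))
  structure(list(fitness = fitness, levels = as.integer(levels), adj = adj,
                 csr = lapply(adj, .adj_to_csr)),
            class = "toy_landscape")
}

.toy_encode <- function(g, levels) {
  stride <- cumprod(c(1, levels[-length(levels)]))
  as.integer(1 + sum((g - 1) * stride))
}

.toy_states <- function(levels) {
  as.matrix(do.call(expand.grid, lapply(levels, seq_len)))
}

.toy_neighbor_codes <- function(x, g) {
  nb <- one_mutant_neighbors(x, g)
  if (nrow(nb) == 0L) return(integer(0))
  vapply(seq_len(nrow(nb)), function(r) .toy_encode(nb[r, ], x$levels), 1L)
}

#' Enumerate all local optima of a toy landscape
#'
#' A genotype is a local optimum when every one-mutant neighbor has strictly
#' lower fitness (with strictly beneficial moves, any state with no uphill
#' neighbor is absorbing).
#'
#' @param x a `toy_landscape`.
#' @return A list: `is_optimum` (logical over linearized states),
#'   `optima` (matrix of optimum genotypes), `fitness` (their fitnesses),
#'   `global` (linear index of the global optimum).
#' @export
local_optima <- function(x) {
  F <- as.vector(x$fitness)
  states <- .toy_states(x$levels)
  M <- nrow(states)
  is_opt <- logical(M)
  for (s in seq_len(M)) {
    codes <- .toy_neighbor_codes(x, states[s, ])
    is_opt[s] <- !any(F[codes] > F[s])
  }
  list(is_optimum = is_opt,
       optima = states[is_opt, , drop = FALSE],
       fitness = F[is_opt],
       global = which.max(F))
}

#' Exact absorbing-Markov-chain analysis of the adaptive walk
#'
#' The walk is a Markov chain on the genotypes: from a non-absorbing state
#' it moves uniformly among its strictly beneficial neighbors; local optima
#' are absorbing. On enumerable toys the chain gives exact absorption
#' (reach) probabilities and expected step counts, independently of the
#' walk implementation.
#'
#' @param x a `toy_landscape`.
#' @return A list: `absorbing` (logical), `reach_prob` (M x n_absorbing
#'   matrix of absorption probabilities), `absorbing_states` (their linear
#'   indices), `p_global` (probability of absorbing at the global optimum,
#'   per state), `expected_steps` (expected accepted mutations to
#'   absorption, per state), `global` (linear index).
#' @export
walk_chain <- function(x) {
  F <- as.vector(x$fitness)
  states <- .toy_states(x$levels)
  M <- nrow(states)
  nbrs <- vector("list", M)
  for (s in seq_len(M)) {
    codes <- .toy_neighbor_codes(x, states[s, ])
    nbrs[[s]] <- codes[F[codes] > F[s]]
  }
  absorbing <- lengths(nbrs) == 0L
  a_idx <- which(absorbing)
  t_idx <- which(!absorbing)
  nA <- length(a_idx)
  reach <- matrix(0, M, nA)
  reach[cbind(a_idx, seq_len(nA))] <- 1
  steps <- numeric(M)
  if (length(t_idx)) {
    nT <- length(t_idx)
    Q <- matrix(0, nT, nT)
    Rm <- matrix(0, nT, nA)
    t_pos <- match(seq_len(M), t_idx)
    a_pos <- match(seq_len(M), a_idx)
    for (r in seq_len(nT)) {
      to <- nbrs[[t_idx[r]]]
      pr <- 1 / length(to)
      for (s2 in to) {
        if (absorbing[s2]) Rm[r, a_pos[s2]] <- Rm[r, a_pos[s2]] + pr
        else Q[r, t_pos[s2]] <- Q[r, t_pos[s2]] + pr
      }
    }
    Ninv <- diag(nT) - Q
    reach[t_idx, ] <- solve(Ninv, Rm)
    steps[t_idx] <- solve(Ninv, rep(1, nT))
  }
  g <- which.max(F)
  stopifnot(absorbing[g])  # the global argmax has no uphill neighbor
  list(absorbing = absorbing, reach_prob = reach, absorbing_states = a_idx,
       p_global = reach[, match(g, a_idx)], expected_steps = steps,
       global = g)
}

#' Toy landscape from the regulator--target fitness on a tiny grid
#'
#' Restricts the full six-parameter model to a small factorial grid: the
#' parameters in `vary` take `levels` grid values each (from a tiny
#' [build_grid()]), the rest are frozen at `fixed_level`. The fitness table
#' is the closed-form genotype fitness evaluated pointwise.
#'
#' @param vary names of the varying parameters (at most 3 for enumerability).
#' @param levels levels per varying parameter (<= 5 recommended).
#' @param fixed_level level index (into the tiny grid) of frozen parameters.
#' @param ranges,seed passed to [build_grid()].
#' @param model a [grn_model()].
#' @param networks optional per-dimension networks (default complete).
#' @return A `toy_landscape` with attributes `grid`, `vary`, `fixed_level`.
#' @export
grn_toy_landscape <- function(vary = c("beta", "K_m", "k_dT"), levels = 4L,
                              fixed_level = NULL,
                              ranges = default_param_ranges(), seed = 1L,
                              model = grn_model(), networks = NULL) {
  stopifnot(all(vary %in% .PARAMS), length(vary) <= 3L)
  grid <- build_grid(ranges, n_levels = levels, seed = seed)
  fixed_level <- fixed_level %||% as.integer(ceiling(levels / 2))
  vi <- match(vary, .PARAMS)
  combos <- .toy_states(rep(as.integer(levels), length(vary)))
  idx <- matrix(fixed_level, nrow(combos), length(.PARAMS))
  idx[, vi] <- combos
  F <- landscape_fitness(grid, idx, model)
  out <- toy_landscape(array(F, dim = rep(levels, length(vary))),
                       networks = networks)
  attr(out, "grid") <- grid
  attr(out, "vary") <- vary
  attr(out, "fixed_level") <- fixed_level
  out
}

#' Build a toy fixture with its exhaustive ground truth
#'
#' Convenience wrapper producing a toy landscape together with everything a
#' test oracle needs: all local optima, the exact reach probabilities and
#' expected step counts from the walk's absorbing Markov chain.
#'
#' @param fitness explicit fitness table (array), or `NULL` to use the
#'   regulator--target model via [grn_toy_landscape()].
#' @param ... passed on to [toy_landscape()] or [grn_toy_landscape()].
#' @return A list of class `toy_fixture`: `landscape`, `optima`, `chain`.
#' @export
make_toy_fixture <- function(fitness = NULL, ...) {
  land <- if (is.null(fitness)) grn_toy_landscape(...)
          else toy_landscape(fitness, ...)
  if (prod(land$levels) > 4096)
    stop("fixture too large for exhaustive enumeration (", prod(land$levels),
         " states)", call. = FALSE)
  structure(list(landscape = land, optima = local_optima(land),
                 chain = walk_chain(land)),
            class = "toy_fixture")
}

#' @export
print.toy_landscape <- function(x, ...) {
  cat(sprintf("<toy_landscape> %s levels, %d states\n",
              paste(x$levels, collapse = " x "), prod(x$levels)))
  invisible(x)
}

#' @export
print.toy_fixture <- function(x, ...) {
  print(x$landscape)
  cat(sprintf("  %d local optima; global fitness %.6g\n",
              sum(x$optima$is_optimum), max(x$landscape$fitness)))
  invisible(x)
}
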