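# Shared builders for tests. Everything is generated in code; fixtures are
# small enough for exhaustive enumeration.

# random parameter set drawn log-uniformly from the default ranges
random_pset <- function() {
  r <- default_param_ranges()
  v <- exp(runif(nrow(r), log(r$min), log(r$max)))
  param_set(v[1], v[2], v[3], v[4], v[5], v[6])
}

# single-peaked 2-parameter toy: unique argmax at (3, 4)
single_peak_toy <- function() {
  f <- outer(1:5, 1:5, function(i, j) 1 - 0.1 * ((i - 3)^2 + (j - 4)^2))
  toy_landscape(f)
}

# two-peaked 2-parameter toy on chain adjacency (moves of +-1 level only):
# local optima at (1,1) (minor, F = 0.5) and (3,3) (global, F = 0.9)
two_peak_toy <- function() {
  f <- matrix(c(0.50, 0.30, 0.10,
                0.30, 0.20, 0.40,
                0.10, 0.40, 0.90), 3, 3, byrow = TRUE)
  chain <- list(2L, c(1L, 3L), 2L)
  toy_landscape(f, adj = list(chain, chain))
}

# hand-checkable 1-parameter toy: optima = {level 2}
hand_toy <- function() toy_landscape(c(0.1, 0.3, 0.2))

# exhaustive adjacency-respecting Hamming-1 neighbors, written independently
# of one_mutant_neighbors (loops over the full genotype space)
brute_neighbors <- function(adj, g) {
  D <- length(adj)
  levels <- lengths(adj)
  states <- as.matrix(do.call(expand.grid, lapply(levels, seq_len)))
  keep <- apply(states, 1, function(h) {
    d <- which(h != g)
    length(d) == 1 && h[d] %in% adj[[d]][[g[d]]]
  })
  m <- states[keep, , drop = FALSE]
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

sort_rows <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}
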