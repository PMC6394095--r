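#' Greedy adaptive walk to a local or global fitness optimum
#'
#' From the start genotype, all one-mutant neighbors (every level adjacent
#' in each parameter's neighbor network) are evaluated; one of the strictly
#' beneficial ones is chosen uniformly at random and the population moves
#' there. The walk stops when no neighbor has strictly higher fitness: a
#' local (possibly global) optimum. Fitness increases strictly at every
#' step, and takes finitely many values on the grid, so termination is
#' guaranteed; `max_steps` is a pure safety assertion. Equal-fitness
#' neighbors are neither moves nor blockers.
#'
#' @param x an `rt_landscape` or `toy_landscape`.
#' @param start genotype: integer vector of 1-based level indices.
#' @param ... passed to methods.
#' @return An object of class `rt_walk`: `genotypes` (matrix, one row per
#'   step, step 0 first), `fitness`, `mutated` (mutated parameter per step,
#'   `NA` for step 0), `n_steps` (accepted mutations), `terminal`
#'   (always `TRUE`), `seed`.
#' @export
#' @examples
#' g <- build_grid(n_levels = 150, seed = 1)
#' l <- build_landscape(g, K_conn = 20, seed = 2)
#' w <- adaptive_walk(l, start = rep(75L, 6), seed = 3)
#' w
adaptive_walk <- function(x, start, ...) UseMethod("adaptive_walk")

.check_start <- function(start, n_per_dim) {
  start <- as.integer(start)
  if (length(start) != length(n_per_dim) || any(start < 1L) ||
      any(start > n_per_dim))
    stop("start genotype has indices outside the landscape", call. = FALSE)
  start
}

.make_walk <- function(res, seed) {
  structure(list(genotypes = res$genotypes + 1L,
                 fitness = res$fitness,
                 mutated = res$mutated + 1L,
                 n_steps = length(res$fitness) - 1L,
                 terminal = TRUE,
                 seed = seed),
            class = "rt_walk")
}

#' @rdname adaptive_walk
#' @param model a [grn_model()].
#' @param seed RNG seed; `NULL` continues the current stream.
#' @param max_steps safety budget on accepted mutations.
#' @export
adaptive_walk.rt_landscape <- function(x, start, model = grn_model(),
                                       seed = NULL, max_steps = 1e6L, ...) {
  start <- .check_start(start, rep(x$grid$n_levels, length(x$networks)))
  if (!is.null(seed)) set.seed(seed)
  fc <- model$constants
  res <- cpp_walk_grn(start - 1L, lapply(x$networks, `[[`, "csr"),
                      .grid_matrix(x$grid),
                      model$S, fc$a, fc$b, fc$alpha,
                      is.null(model$kr_const), model$kr_ratio,
                      model$kr_const %||% 0,
                      as.integer(max_steps))
  .make_walk(res, seed)
}

#' @rdname adaptive_walk
#' @export
adaptive_walk.toy_landscape <- function(x, start, seed = NULL,
                                        max_steps = 1e6L, ...) {
  start <- .check_start(start, x$levels)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_walk_table(start - 1L, x$csr, as.vector(x$fitness),
                        as.integer(x$levels), as.integer(max_steps))
  .make_walk(res, seed)
}

#' Did a walk terminate at the global peak?
#'
#' Terminal fitness is compared to the (estimated) global-peak fitness at
#' the landscape's discretization scale. Near its flattest directions the
#' peak's fitness changes by well under 1e-3 per grid level, while genuine
#' local optima on the default landscape sit >= 1e-2 below the peak. The
#' default tolerance (5e-3, the discretization tolerance of the peak value
#' itself: regenerating the random grid shifts the attainable maximum by
#' a few 1e-3) counts a terminal state as "at the peak" when it is within
#' the discretization scale, cleanly separating it from real traps.
#'
#' @param walk an `rt_walk`.
#' @param peak_fitness global-peak fitness (a number or an `rt_peak`).
#' @param tol absolute comparison tolerance (default 5e-3, the
#'   discretization tolerance of the peak value, scaled by
#'   `max(1, |peak|)`).
#' @return Logical.
#' @export
reached_global <- function(walk, peak_fitness, tol = 5e-3) {
  if (inherits(peak_fitness, "rt_peak")) peak_fitness <- peak_fitness$fitness
  term <- walk$fitness[length(walk$fitness)]
  abs(term - peak_fitness) <= tol * max(1, abs(peak_fitness))
}

#' Find a start genotype with a prescribed fitness
#'
#' Rejection sampling over uniformly random genotypes (so the start is
#' representative of genotypes at that fitness), followed, if needed, by a
#' coordinate-wise refinement over all grid levels that minimizes
#' `|F - target|`. Start genotypes are chosen independently of any neighbor
#' network, so one start can be shared across connectivity values.
#'
#' @param grid an `rt_grid` (or `rt_landscape`).
#' @param target target fitness; must lie in the landscape's achievable
#'   range.
#' @param tol acceptance tolerance on `|F - target|` (default 1e-3).
#' @param model a [grn_model()].
#' @param seed RNG seed.
#' @param batch,max_batches rejection-sampling batch size and budget.
#' @param refine run the coordinate refinement if sampling alone does not
#'   reach `tol`.
#' @return Integer genotype with attribute `"fitness"` (its recomputed
#'   fitness). Errors if no genotype within `tol` is found, reporting the
#'   best candidate's fitness.
#' @export
find_start_genotype <- function(grid, target, tol = 1e-3,
                                model = grn_model(), seed = NULL,
                                batch = 20000L, max_batches = 25L,
                                refine = TRUE) {
  if (inherits(grid, "rt_landscape")) grid <- grid$grid
  stopifnot(inherits(grid, "rt_grid"))
  if (!is.null(seed)) set.seed(seed)
  gm <- .grid_matrix(grid)
  n <- grid$n_levels
  D <- ncol(gm)
  best <- NULL
  bestd <- Inf
  for (b in seq_len(max_batches)) {
    idx <- matrix(sample.int(n, D * batch, replace = TRUE), batch, D)
    P <- matrix(gm[cbind(as.vector(idx), rep(seq_len(D), each = batch))],
                batch, D)
    d <- abs(.fitness_vec(P, model)$F - target)
    j <- which.min(d)
    if (d[j] < bestd) { bestd <- d[j]; best <- idx[j, ] }
    if (bestd <= tol) break
  }
  if (refine && bestd > tol) {
    repeat {
      improved <- FALSE
      for (p in seq_len(D)) {
        vals <- gm[cbind(best, seq_len(D))]
        P <- matrix(rep(vals, each = n), n, D)
        P[, p] <- gm[, p]
        d <- abs(.fitness_vec(P, model)$F - target)
        j <- which.min(d)
        if (d[j] < bestd) { bestd <- d[j]; best[p] <- j; improved <- TRUE }
      }
      if (!improved || bestd <= tol) break
    }
  }
  f <- .fitness_vec(matrix(gm[cbind(best, seq_len(D))], 1L, D), model)$F
  if (bestd > tol)
    stop(sprintf("no genotype with fitness within %.3g of %.6g found (best candidate: F = %.6g)",
                 tol, target, f), call. = FALSE)
  structure(setNames(best, .PARAMS), fitness = f)
}

#' @export
print.rt_walk <- function(x, ...) {
  cat(sprintf("<rt_walk> %d accepted mutations, fitness %.6g -> %.6g (terminal)\n",
              x$n_steps, x$fitness[1], x$fitness[length(x$fitness)]))
  invisible(x)
}

#' @export
summary.rt_walk <- function(object, ...) {
  print(object)
  mut <- object$mutated[-1]
  if (length(mut)) {
    cat("Mutations per parameter:\n")
    D <- ncol(object$genotypes)
    labs <- if (D == length(.PARAMS)) .PARAMS else paste0("P", seq_len(D))
    print(table(factor(mut, levels = seq_len(D), labels = labs)))
  }
  invisible(object)
}

#' @export
plot.rt_walk <- function(x, ...) {
  plot(seq_along(x$fitness) - 1L, x$fitness, type = "s",
       xlab = "mutational events", ylab = "fitness", ...)
  invisible(x)
}
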