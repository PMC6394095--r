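#' Experiment design for ensemble simulations
#'
#' Defaults are the study conditions: connectivities
#' K in \{3, 5, 7, 10, 12, 15, 20, 50\}, five starting fitnesses from very
#' low (0.0826) to very high (0.8526), and 100 replicate walks per design
#' point.
#'
#' @param K_values connectivity values to scan.
#' @param start_fitness target starting fitnesses.
#' @param n_replicates replicate walks per (K, start) design point.
#' @param start_tol tolerance for the start-genotype search.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(K_values = c(3, 5, 7, 10, 12, 15, 20, 50),
                              start_fitness = c(0.0826, 0.2251, 0.45,
                                                0.6264, 0.8526),
                              n_replicates = 100L,
                              start_tol = 1e-3) {
  stopifnot(n_replicates >= 1, length(K_values) >= 1,
            length(start_fitness) >= 1)
  structure(list(K_values = as.integer(sort(K_values)),
                 start_fitness = start_fitness,
                 n_replicates = as.integer(n_replicates),
                 start_tol = start_tol),
            class = "experiment_design")
}

#' Estimate the global fitness peak of a grid
#'
#' Two independent estimators: (1) multi-start coordinate ascent on the
#' discrete grid with full per-parameter connectivity (each sweep sets each
#' parameter to its conditionally best level until no single-parameter move
#' improves); (2) continuous maximization of the closed-form fitness over
#' the box ranges (L-BFGS-B on log-scale parameters, multi-start). The
#' continuous optimum bounds the grid value from above; disagreement beyond
#' `agree_tol` (relative) raises a warning and is flagged in the result.
#'
#' @param grid an `rt_grid` (or `rt_landscape`).
#' @param model a [grn_model()].
#' @param n_restarts random restarts for the coordinate ascent.
#' @param seed RNG seed.
#' @param check_continuous run the continuous cross-check.
#' @param agree_tol relative agreement tolerance between the estimators.
#' @return An object of class `rt_peak`: `genotype`, `fitness`,
#'   `discretization_step` (largest single-rank fitness decrement at the
#'   peak), `continuous` (list with `par`, `fitness`), `agreement` flag.
#' @export
estimate_global_peak <- function(grid, model = grn_model(), n_restarts = 30L,
                                 seed = 1L, check_continuous = TRUE,
                                 agree_tol = 1e-3) {
  if (inherits(grid, "rt_landscape")) grid <- grid$grid
  stopifnot(inherits(grid, "rt_grid"))
  set.seed(seed)
  gm <- .grid_matrix(grid)
  n <- grid$n_levels
  D <- ncol(gm)
  bestF <- -Inf
  bestg <- NULL
  for (r in seq_len(n_restarts)) {
    g <- sample.int(n, D, replace = TRUE)
    vals <- gm[cbind(g, seq_len(D))]
    f <- .fitness_vec(matrix(vals, 1L, D), model)$F
    repeat {
      improved <- FALSE
      for (p in seq_len(D)) {
        P <- matrix(rep(vals, each = n), n, D)
        P[, p] <- gm[, p]
        FF <- .fitness_vec(P, model)$F
        j <- which.max(FF)
        if (FF[j] > f) {
          g[p] <- j; vals[p] <- gm[j, p]; f <- FF[j]; improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (f > bestF) { bestF <- f; bestg <- g }
  }

  # largest fitness decrement of a single-rank move at the peak: the
  # landscape's discretization unit (metadata; a guide for reach_tol
  # choices on rescaled fitness functions)
  vals0 <- gm[cbind(bestg, seq_len(D))]
  step <- 0
  for (p in seq_len(D)) {
    for (dl in c(-1L, 1L)) {
      j <- bestg[p] + dl
      if (j >= 1L && j <= n) {
        v <- vals0
        v[p] <- gm[j, p]
        step <- max(step, bestF - .fitness_vec(matrix(v, 1L, D), model)$F)
      }
    }
  }

  cont <- NULL
  agreement <- NA
  if (check_continuous) {
    ranges <- grid$ranges
    lo <- log(ranges$min)
    hi <- log(ranges$max)
    obj <- function(lp) -.fitness_vec(matrix(exp(lp), 1L, D), model)$F
    starts <- c(list(log(gm[cbind(bestg, seq_len(D))])),
                lapply(seq_len(9L), function(i) runif(D, lo, hi)))
    cbest <- NULL
    for (s in starts) {
      fit <- tryCatch(optim(s, obj, method = "L-BFGS-B", lower = lo,
                            upper = hi,
                            control = list(factr = 1e4, maxit = 500)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(cbest) || fit$value < cbest$value))
        cbest <- fit
    }
    cont <- list(par = setNames(exp(cbest$par), .PARAMS),
                 fitness = -cbest$value)
    agreement <- cont$fitness >= bestF - 1e-12 &&
      abs(cont$fitness - bestF) <= agree_tol * max(1, abs(cont$fitness))
    if (!isTRUE(agreement))
      warning(sprintf("grid (%.6g) and continuous (%.6g) peak estimates disagree beyond tolerance",
                      bestF, cont$fitness))
  }
  structure(list(genotype = setNames(bestg, .PARAMS), fitness = bestF,
                 discretization_step = step,
                 continuous = cont, agreement = agreement,
                 n_restarts = n_restarts, seed = seed),
            class = "rt_peak")
}

#' Run an ensemble of replicate adaptive walks from one start genotype
#'
#' Replicate `r` is seeded with `child_seed(seed, r)`, so any subset of
#' replicates is reproducible in any order. After a replicate terminates
#' its fitness is carried forward in the ensemble series (the population
#' sits at its peak), so mean and variance series stay defined until the
#' last replicate has terminated.
#'
#' @param landscape an `rt_landscape` or `toy_landscape`.
#' @param start genotype (1-based level indices).
#' @param n_replicates number of replicate walks.
#' @param model a [grn_model()] (ignored for toy landscapes).
#' @param peak_fitness global-peak fitness used to classify terminal states
#'   (`NULL` leaves `reached` as `NA`); an `rt_peak` object may be given.
#' @param seed master seed for the ensemble.
#' @param reach_tol absolute tolerance for [reached_global()] (default
#'   5e-3, the discretization tolerance of the peak value).
#' @param max_steps per-walk safety budget.
#' @param keep_walks retain the individual `rt_walk` objects.
#' @return An object of class `rt_ensemble`.
#' @export
run_ensemble <- function(landscape, start, n_replicates = 100L,
                         model = grn_model(), peak_fitness = NULL,
                         seed = 1L, reach_tol = NULL, max_steps = 1e6L,
                         keep_walks = FALSE) {
  if (inherits(peak_fitness, "rt_peak")) peak_fitness <- peak_fitness$fitness
  reach_tol <- reach_tol %||% 5e-3
  walks <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    walks[[r]] <- if (inherits(landscape, "toy_landscape"))
      adaptive_walk(landscape, start, seed = child_seed(seed, r),
                    max_steps = max_steps)
    else
      adaptive_walk(landscape, start, model = model,
                    seed = child_seed(seed, r), max_steps = max_steps)
  }
  .ensemble_from_walks(
    walks, start = start, peak_fitness = peak_fitness,
    reach_tol = reach_tol, seed = seed,
    K_conn = if (inherits(landscape, "rt_landscape")) landscape$K_conn else NA_integer_,
    mean_degree = if (inherits(landscape, "rt_landscape")) landscape$mean_degree else NA_real_,
    keep_walks = keep_walks)
}

# Assemble an rt_ensemble from a list of walks (shared machinery between
# run_ensemble and the resampled-network scan driver).
.ensemble_from_walks <- function(walks, start, peak_fitness, reach_tol,
                                 seed, K_conn, mean_degree,
                                 keep_walks = FALSE) {
  n_replicates <- length(walks)
  steps <- vapply(walks, `[[`, 0L, "n_steps")
  term <- vapply(walks, function(w) w$fitness[length(w$fitness)], 0)
  L <- max(steps) + 1L
  series <- do.call(rbind, lapply(walks, function(w) {
    f <- w$fitness
    c(f, rep(f[length(f)], L - length(f)))
  }))
  reached <- if (is.null(peak_fitness)) rep(NA, n_replicates)
             else abs(term - peak_fitness) <= reach_tol * max(1, abs(peak_fitness))
  structure(list(
    fitness = series,
    steps = steps,
    terminal_fitness = term,
    reached = reached,
    fraction_reached = if (is.null(peak_fitness)) NA_real_ else mean(reached),
    steps_to_peak = if (is.null(peak_fitness)) rep(NA_integer_, n_replicates)
                    else ifelse(reached, steps, NA_integer_),
    mean_fitness = colMeans(series),
    var_fitness = apply(series, 2L, var),
    start = start,
    start_fitness = series[1L, 1L],
    K_conn = K_conn,
    mean_degree = mean_degree,
    peak_fitness = peak_fitness,
    n_replicates = as.integer(n_replicates),
    seed = seed,
    walks = if (keep_walks) walks else NULL),
    class = "rt_ensemble")
}

#' Scan the critical-connectivity transition
#'
#' For each connectivity K in the design, a fresh neighbor network is built
#' on the shared grid and `n_replicates` adaptive walks are run from each
#' start genotype; the fraction of replicates whose terminal fitness equals
#' the estimated global-peak fitness is recorded. The transition K is the
#' smallest tested K whose fraction is at least `threshold` for every
#' start. Start genotypes are found once (independently of K) and shared
#' across all K values.
#'
#' Seeds: the peak uses `child_seed(seed, 101)`, start s uses
#' `child_seed(seed, 202, s)`, the landscape at connectivity K uses
#' `child_seed(seed, 303, K)`, and the ensemble at (K, s) uses
#' `child_seed(seed, K, s)` — every design point is reproducible in
#' isolation.
#'
#' @param grid an `rt_grid`.
#' @param design an [experiment_design()].
#' @param model a [grn_model()].
#' @param sigma kernel width (default 2% of levels).
#' @param mode network symmetrization mode.
#' @param seed master seed.
#' @param threshold fraction threshold defining the transition (default
#'   0.95).
#' @param reach_tol absolute tolerance classifying a terminal state as the
#'   global peak (default 5e-3, the discretization tolerance of the peak
#'   value itself: regenerating the random grid shifts the attainable
#'   maximum by a few 1e-3).
#' @param resample_networks build a fresh neighbor-network realization for
#'   every replicate (shared across starts) instead of freezing one network
#'   per K. The fraction then estimates the graph-ensemble reach
#'   probability; with a single quenched network it reflects the luck of
#'   that realization (whether a particular near-peak edge exists), which
#'   makes the fraction-vs-K curve non-monotone. Default `TRUE`.
#' @param resample_starts draw a fresh start genotype at the same target
#'   fitness for every replicate. Statistics attributed to a *starting
#'   fitness* (mean steps to peak, speed of evolution) then average over
#'   the genotypes realizing that fitness rather than reflecting one
#'   genotype's idiosyncratic neighborhood. Default `FALSE`: all
#'   replicates share one start genotype per fitness, which
#'   between-replicate variance dynamics require.
#' @param transition_rule `"binomial"` (default): smallest tested K from
#'   which onward the pooled counts are statistically compatible with reach
#'   probability `>= threshold`; `"point"`: smallest K with every start's
#'   sample fraction `>= threshold`.
#' @param starts optional pre-computed list of start genotypes (one per
#'   start fitness), e.g. to share starts across fitness-function variants.
#' @param peak optional pre-computed `rt_peak`.
#' @param keep_ensembles retain every `rt_ensemble` (needed for speed and
#'   variance analyses).
#' @param verbose print per-K progress.
#' @return An object of class `rt_kscan`: `table` (one row per design
#'   point: `K`, `start_fitness`, `fraction_reached`, `mean_steps`,
#'   `n_unreached`, `mean_degree`), `transition_K`, `peak`, `starts`,
#'   `design`, and optionally `ensembles`.
#' @export
critical_k_scan <- function(grid, design = experiment_design(),
                            model = grn_model(),
                            sigma = 0.02 * grid$n_levels,
                            mode = c("strict", "union"), seed = 1L,
                            threshold = 0.95, reach_tol = 5e-3,
                            resample_networks = TRUE,
                            resample_starts = FALSE,
                            transition_rule = c("binomial", "point"),
                            starts = NULL, peak = NULL,
                            keep_ensembles = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "rt_grid"))
  mode <- match.arg(mode)
  transition_rule <- match.arg(transition_rule)
  if (is.null(peak))
    peak <- estimate_global_peak(grid, model, seed = child_seed(seed, 101L))
  if (is.null(starts))
    starts <- lapply(seq_along(design$start_fitness), function(s)
      find_start_genotype(grid, design$start_fitness[s],
                          tol = design$start_tol, model = model,
                          seed = child_seed(seed, 202L, s)))
  rows <- list()
  ensembles <- list()
  for (K in design$K_values) {
    if (resample_networks || resample_starts) {
      # fresh network realization (and optionally a fresh start genotype at
      # the same target fitness) per replicate, shared by all starts:
      # statistics then estimate ensemble averages over the random
      # landscape/start draws instead of the luck of a single realization
      walks <- lapply(seq_along(starts), function(s)
        vector("list", design$n_replicates))
      degs <- numeric(design$n_replicates)
      land <- if (!resample_networks)
        build_landscape(grid, K, sigma, mode,
                        seed = child_seed(seed, 303L, K))
      for (r in seq_len(design$n_replicates)) {
        if (resample_networks)
          land <- build_landscape(grid, K, sigma, mode,
                                  seed = child_seed(seed, 303L, K, r))
        degs[r] <- land$mean_degree
        for (s in seq_along(starts)) {
          st <- if (resample_starts)
            find_start_genotype(grid, design$start_fitness[s],
                                tol = design$start_tol, model = model,
                                seed = child_seed(seed, 202L, s, r))
          else starts[[s]]
          walks[[s]][[r]] <- adaptive_walk(
            land, st, model = model,
            seed = child_seed(child_seed(seed, K, s), r))
        }
      }
      ens_list <- lapply(seq_along(starts), function(s)
        .ensemble_from_walks(walks[[s]], starts[[s]],
                             peak_fitness = peak$fitness,
                             reach_tol = reach_tol,
                             seed = child_seed(seed, K, s),
                             K_conn = as.integer(K),
                             mean_degree = mean(degs)))
      mean_deg <- mean(degs)
    } else {
      land <- build_landscape(grid, K, sigma, mode,
                              seed = child_seed(seed, 303L, K))
      ens_list <- lapply(seq_along(starts), function(s)
        run_ensemble(land, starts[[s]], design$n_replicates, model,
                     peak_fitness = peak$fitness,
                     seed = child_seed(seed, K, s),
                     reach_tol = reach_tol))
      mean_deg <- land$mean_degree
    }
    for (s in seq_along(starts)) {
      ens <- ens_list[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        K = K,
        start_fitness = design$start_fitness[s],
        fraction_reached = ens$fraction_reached,
        mean_steps = mean(ens$steps[ens$reached]),
        n_unreached = sum(!ens$reached),
        mean_degree = mean_deg)
      if (keep_ensembles)
        ensembles[[sprintf("K%d_s%d", K, s)]] <- ens
    }
    if (verbose)
      message(sprintf("K = %3d: fractions %s", K,
                      paste(sprintf("%.2f", vapply(
                        rows[(length(rows) - length(starts) + 1L):length(rows)],
                        `[[`, 0, "fraction_reached")), collapse = " ")))
  }
  tab <- do.call(rbind, rows)
  transition_K <- .transition_K(tab, design, threshold, transition_rule)
  structure(list(table = tab, transition_K = transition_K,
                 threshold = threshold, transition_rule = transition_rule,
                 peak = peak, starts = starts,
                 design = design, sigma = sigma, mode = mode, seed = seed,
                 reach_tol = reach_tol,
                 resample_networks = resample_networks,
                 resample_starts = resample_starts,
                 ensembles = if (keep_ensembles) ensembles else NULL),
            class = "rt_kscan")
}

# Transition K from a scan table. "binomial": smallest tested K from which
# onward the pooled replicate counts are statistically compatible with
# reach probability >= threshold (exact binomial, alpha = 0.05) -- a
# point-estimate rule flips on sampling noise when the true fraction sits
# near the threshold, the compatibility rule estimates the same quantity
# consistently. "point": smallest K with every start's sample fraction >=
# threshold (and all larger K too).
.transition_K <- function(tab, design, threshold,
                          rule = c("binomial", "point"), alpha = 0.05) {
  rule <- match.arg(rule)
  Ks <- design$K_values
  n <- design$n_replicates
  ok <- vapply(Ks, function(K) {
    fr <- tab$fraction_reached[tab$K == K]
    if (rule == "point") return(all(fr >= threshold))
    x <- sum(round(fr * n))
    N <- length(fr) * n
    stats::pbinom(x, N, threshold) >= alpha
  }, TRUE)
  ok <- rev(cumprod(rev(ok))) > 0  # require consistency for all larger K
  if (any(ok)) min(Ks[ok]) else NA_integer_
}

#' Mean steps to the global peak by design point
#'
#' Replicates that never reach the global peak contribute no steps (their
#' step count to the peak is infinite); they are counted separately.
#'
#' @param x an `rt_kscan`, an `rt_ensemble`, or a list of `rt_ensemble`s.
#' @return A data.frame with `K`, `start_fitness`, `mean_steps`
#'   (over reaching replicates; `NaN` when none reach), `n_reached`,
#'   `n_unreached`.
#' @export
steps_to_peak_summary <- function(x) {
  if (inherits(x, "rt_kscan")) {
    tab <- x$table
    return(data.frame(K = tab$K, start_fitness = tab$start_fitness,
                      mean_steps = tab$mean_steps,
                      n_reached = round(tab$fraction_reached *
                                          x$design$n_replicates),
                      n_unreached = tab$n_unreached))
  }
  if (inherits(x, "rt_ensemble")) x <- list(x)
  do.call(rbind, lapply(x, function(e) data.frame(
    K = e$K_conn, start_fitness = e$start_fitness,
    mean_steps = mean(e$steps[e$reached]),
    n_reached = sum(e$reached), n_unreached = sum(!e$reached))))
}

.ensemble_list <- function(x) {
  if (inherits(x, "rt_ensemble")) return(list(x))
  if (inherits(x, "rt_kscan")) {
    if (is.null(x$ensembles))
      stop("run critical_k_scan() with keep_ensembles = TRUE for series analyses",
           call. = FALSE)
    return(x$ensembles)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "rt_ensemble")))
  x
}

#' Speed of evolution: per-step gain of the ensemble-mean fitness
#'
#' Speed at step `t` is `meanF(t+1) - meanF(t)` (per mutational event, the
#' walk's natural clock). The summary reports each design point's peak
#' speed and, per K, the start fitness attaining the largest peak speed.
#'
#' @param x an `rt_ensemble`, list of them, or an `rt_kscan` run with
#'   `keep_ensembles = TRUE`.
#' @return An object of class `rt_speed`: `series` (long data.frame of
#'   speeds), `summary` (peak speed per design point), `best_start`
#'   (per K, the start fitness maximizing peak speed).
#' @export
speed_of_evolution <- function(x) {
  ens <- .ensemble_list(x)
  series <- do.call(rbind, lapply(ens, function(e) {
    sp <- diff(e$mean_fitness)
    if (!length(sp)) return(NULL)
    data.frame(K = e$K_conn, start_fitness = e$start_fitness,
               step = seq_along(sp) - 1L, speed = sp)
  }))
  summ <- do.call(rbind, lapply(ens, function(e) {
    sp <- diff(e$mean_fitness)
    data.frame(K = e$K_conn, start_fitness = e$start_fitness,
               peak_speed = if (length(sp)) max(sp) else 0,
               peak_step = if (length(sp)) which.max(sp) - 1L else NA_integer_)
  }))
  best <- do.call(rbind, lapply(split(summ, summ$K), function(d)
    data.frame(K = d$K[1],
               best_start_fitness = d$start_fitness[which.max(d$peak_speed)],
               peak_speed = max(d$peak_speed))))
  rownames(best) <- NULL
  structure(list(series = series, summary = summ, best_start = best),
            class = "rt_speed")
}

#' Between-replicate fitness variance dynamics
#'
#' Variance across replicate fitnesses at each mutational step (terminated
#' replicates keep contributing their terminal fitness). All replicates of
#' a design point share one start genotype, so the variance starts at 0; it
#' returns to 0 exactly when all replicates end on the same peak.
#'
#' @inheritParams speed_of_evolution
#' @return An object of class `rt_variance`: `series` (long data.frame),
#'   `summary` (`peak_var`, `peak_step`, `terminal_var` per design point).
#' @export
variance_dynamics <- function(x) {
  ens <- .ensemble_list(x)
  series <- do.call(rbind, lapply(ens, function(e)
    data.frame(K = e$K_conn, start_fitness = e$start_fitness,
               step = seq_along(e$var_fitness) - 1L,
               variance = e$var_fitness)))
  summ <- do.call(rbind, lapply(ens, function(e)
    data.frame(K = e$K_conn, start_fitness = e$start_fitness,
               peak_var = max(e$var_fitness),
               peak_step = which.max(e$var_fitness) - 1L,
               terminal_var = e$var_fitness[length(e$var_fitness)])))
  structure(list(series = series, summary = summ), class = "rt_variance")
}

#' Critical-K scans under scaled fitness-function constants
#'
#' Repeats [critical_k_scan()] with each constant-scaling scenario (by
#' default a x10, alpha x10, b x10, b /10) and reports whether the inferred
#' transition K is invariant. Start genotypes are found once under the base
#' constants and shared, so scenarios differ only in the fitness function;
#' the global peak is re-estimated under each scenario's constants.
#'
#' @param grid an `rt_grid`.
#' @param design an [experiment_design()].
#' @param scenarios named list of named multiplier sets over `a`, `b`,
#'   `alpha`.
#' @param model base [grn_model()].
#' @param base optional pre-computed base `rt_kscan` (saves one scan).
#' @param ... passed to [critical_k_scan()] (sigma, mode, seed, threshold).
#' @return An object of class `rt_sensitivity`: `table` (scenario,
#'   constants, transition K), `scans`, `invariant` flag.
#' @export
fitness_function_sensitivity <- function(grid, design = experiment_design(),
                                         scenarios = list(
                                           a_x10 = c(a = 10),
                                           alpha_x10 = c(alpha = 10),
                                           b_x10 = c(b = 10),
                                           b_div10 = c(b = 0.1)),
                                         model = grn_model(), base = NULL,
                                         ...) {
  if (is.null(base))
    base <- critical_k_scan(grid, design, model, ...)
  scans <- list(base = base)
  rows <- list(data.frame(scenario = "base", a = model$constants$a,
                          b = model$constants$b, alpha = model$constants$alpha,
                          transition_K = base$transition_K))
  for (nm in names(scenarios)) {
    mult <- scenarios[[nm]]
    fc <- model$constants
    for (f in names(mult)) fc[[f]] <- fc[[f]] * mult[[f]]
    m2 <- grn_model(S = model$S,
                    constants = fitness_constants(fc$a, fc$b, fc$alpha),
                    kr_ratio = model$kr_ratio, kr_const = model$kr_const)
    sc <- critical_k_scan(grid, design, m2, starts = base$starts, ...)
    scans[[nm]] <- sc
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = nm, a = fc$a, b = fc$b, alpha = fc$alpha,
      transition_K = sc$transition_K)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, scans = scans,
                 invariant = length(unique(tab$transition_K)) == 1L &&
                   !anyNA(tab$transition_K)),
            class = "rt_sensitivity")
}

#' @export
print.rt_peak <- function(x, ...) {
  cat(sprintf("<rt_peak> grid fitness %.6g", x$fitness))
  if (!is.null(x$continuous))
    cat(sprintf(" | continuous %.6g (agreement: %s)",
                x$continuous$fitness, x$agreement))
  cat("\n")
  invisible(x)
}

#' @export
print.rt_ensemble <- function(x, ...) {
  cat(sprintf("<rt_ensemble> %d replicates from F0 = %.4f", x$n_replicates,
              x$start_fitness))
  if (!is.na(x$K_conn)) cat(sprintf(" at K = %d", x$K_conn))
  if (!is.na(x$fraction_reached))
    cat(sprintf("; fraction at global peak %.2f", x$fraction_reached))
  cat(sprintf("; steps %d-%d\n", min(x$steps), max(x$steps)))
  invisible(x)
}

#' @export
print.rt_kscan <- function(x, ...) {
  cat(sprintf("<rt_kscan> %d K values x %d starts x %d replicates; transition K = %s\n",
              length(x$design$K_values), length(x$design$start_fitness),
              x$design$n_replicates, x$transition_K))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.rt_ensemble <- function(x, type = c("mean", "trajectories", "variance"),
                             ...) {
  type <- match.arg(type)
  steps <- seq_len(ncol(x$fitness)) - 1L
  switch(type,
    mean = plot(steps, x$mean_fitness, type = "l",
                xlab = "mutational events", ylab = "mean fitness", ...),
    trajectories = matplot(steps, t(x$fitness), type = "l", lty = 1,
                           col = grDevices::adjustcolor("steelblue", 0.3),
                           xlab = "mutational events", ylab = "fitness", ...),
    variance = plot(steps, x$var_fitness, type = "l",
                    xlab = "mutational events",
                    ylab = "between-replicate variance", ...))
  invisible(x)
}

#' @export
plot.rt_kscan <- function(x, ...) {
  tab <- x$table
  starts <- sort(unique(tab$start_fitness))
  cols <- grDevices::hcl.colors(max(2L, length(starts)), "Dark 3")
  plot(range(tab$K), c(0, 1), type = "n", log = "x",
       xlab = "connectivity K", ylab = "fraction reaching global peak", ...)
  for (i in seq_along(starts)) {
    d <- tab[tab$start_fitness == starts[i], ]
    lines(d$K, d$fraction_reached, type = "b", col = cols[i], pch = 16)
  }
  if (!is.na(x$transition_K)) abline(v = x$transition_K, lty = 2)
  legend("bottomright", legend = sprintf("F0 = %.4f", starts),
         col = cols[seq_along(starts)], lty = 1, pch = 16, bty = "n")
  invisible(x)
}
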