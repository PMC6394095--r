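# Configuration, serialization and manifests.

#' Assemble a run configuration
#'
#' A single nested list holding everything a run needs: grid settings,
#' neighbor-network settings, model (signal + fitness constants + k_r
#' coupling), the experiment design and the master seed. Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param grid list with `n_levels`, `seed` and optionally `ranges` (a list
#'   of `(name, min, max, scale)` entries; `NULL` means
#'   [default_param_ranges()]).
#' @param network list with `K`, `sigma` (`NULL` means 2% of levels),
#'   `mode`.
#' @param model list with `S`, `a`, `b`, `alpha`, `kr_ratio`, and
#'   optionally `kr_const`.
#' @param design list with `K_values`, `start_fitness`, `n_replicates`,
#'   `start_tol`.
#' @param seed master seed for walks and ensembles.
#' @param output output directory for CLI runs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid = list(n_levels = 1000L, seed = 1L, ranges = NULL),
                       network = list(K = 50L, sigma = NULL, mode = "strict"),
                       model = list(S = 1, a = 1, b = 10, alpha = 2.5e-5,
                                    kr_ratio = 1e-3, kr_const = NULL),
                       design = list(K_values = c(3, 5, 7, 10, 12, 15, 20, 50),
                                     start_fitness = c(0.0826, 0.2251, 0.45,
                                                       0.6264, 0.8526),
                                     n_replicates = 100L, start_tol = 1e-3),
                       seed = 1L, output = "fitscape-results") {
  cfg <- structure(list(grid = grid, network = network, model = model,
                        design = design, seed = seed, output = output),
                   class = "run_config")
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` (or plain list).
#' @return The validated configuration (invisibly classed `run_config`).
#' @export
validate_run_config <- function(cfg) {
  for (f in c("grid", "network", "model", "design", "seed"))
    if (is.null(cfg[[f]])) stop("config is missing the '", f, "' section",
                                call. = FALSE)
  if (is.null(cfg$grid$n_levels) || cfg$grid$n_levels < 3)
    stop("config: grid$n_levels must be >= 3", call. = FALSE)
  if (!is.null(cfg$grid$ranges)) .config_ranges(cfg$grid$ranges)
  if (is.null(cfg$network$K)) stop("config: network$K is required", call. = FALSE)
  if (cfg$network$K >= cfg$grid$n_levels)
    stop("config: network$K must be below grid$n_levels", call. = FALSE)
  md <- cfg$model
  fitness_constants(md$a %||% 1, md$b %||% 10, md$alpha %||% 2.5e-5)
  if (is.null(cfg$design$K_values) || is.null(cfg$design$start_fitness))
    stop("config: design needs K_values and start_fitness", call. = FALSE)
  class(cfg) <- "run_config"
  invisible(cfg)
}

# ranges in config form (list of entries) -> data.frame, with named errors
.config_ranges <- function(ranges) {
  if (is.data.frame(ranges)) return(.check_ranges(ranges))
  rows <- lapply(ranges, function(e) {
    if (is.null(e$name)) stop("config: range entry without a name", call. = FALSE)
    for (f in c("min", "max"))
      if (is.null(e[[f]]))
        stop("config: range entry for parameter '", e$name, "' missing '",
             f, "'", call. = FALSE)
    data.frame(name = e$name, min = e$min, max = e$max,
               scale = e$scale %||% "log", stringsAsFactors = FALSE)
  })
  .check_ranges(do.call(rbind, rows))
}

.config_grid <- function(cfg) {
  ranges <- if (is.null(cfg$grid$ranges)) default_param_ranges()
            else .config_ranges(cfg$grid$ranges)
  build_grid(ranges, n_levels = cfg$grid$n_levels,
             seed = cfg$grid$seed %||% 1L)
}

.config_model <- function(cfg) {
  md <- cfg$model
  grn_model(S = md$S %||% 1,
            constants = fitness_constants(md$a %||% 1, md$b %||% 10,
                                          md$alpha %||% 2.5e-5),
            kr_ratio = md$kr_ratio %||% 1e-3,
            kr_const = md$kr_const)
}

.config_design <- function(cfg) {
  d <- cfg$design
  experiment_design(K_values = d$K_values,
                    start_fitness = d$start_fitness,
                    n_replicates = d$n_replicates %||% 100L,
                    start_tol = d$start_tol %||% 1e-3)
}

#' Read / write a run configuration (YAML)
#'
#' @param path file path.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

# 32-bit FNV-1a over the YAML text; used to fingerprint resolved configs.
.config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg), precision = 15L)
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- (h - h %% 256) + low
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.fmt17 <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE),
         sprintf("%.17g", x))
}

#' Freeze a landscape to a plain-text bundle
#'
#' Writes `values.csv` (param, level, value at full precision),
#' `edges.csv` (param, i, j with i < j) and `meta.json` so a landscape can
#' be shared and reloaded bit-exactly with [read_landscape()].
#'
#' @param x an `rt_landscape`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(x, dir) {
  stopifnot(inherits(x, "rt_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- do.call(rbind, lapply(seq_along(x$grid$values), function(p)
    data.frame(param = names(x$grid$values)[p],
               level = seq_len(x$grid$n_levels),
               value = sprintf("%.17g", x$grid$values[[p]]))))
  write.csv(vals, file.path(dir, "values.csv"), row.names = FALSE,
            quote = FALSE)
  edges <- do.call(rbind, lapply(seq_along(x$networks), function(p) {
    adj <- x$networks[[p]]$adj
    from <- rep(seq_along(adj), times = lengths(adj))
    to <- unlist(adj, use.names = FALSE)
    keep <- from < to
    data.frame(param = names(x$networks)[p], i = from[keep], j = to[keep])
  }))
  write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE,
            quote = FALSE)
  meta <- list(n_levels = x$grid$n_levels, grid_seed = x$grid$seed,
               K_conn = x$K_conn, sigma = x$sigma, mode = x$mode,
               seed = x$seed, mean_degree = x$mean_degree,
               ranges = x$grid$ranges)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vals <- read.csv(file.path(dir, "values.csv"),
                   colClasses = c("character", "integer", "character"))
  edges <- read.csv(file.path(dir, "edges.csv"))
  n <- meta$n_levels
  values <- lapply(split(vals, factor(vals$param, levels = .PARAMS)),
                   function(d) as.numeric(d$value[order(d$level)]))
  grid <- structure(list(values = values,
                         ranges = .check_ranges(as.data.frame(meta$ranges)),
                         n_levels = as.integer(n),
                         seed = as.integer(meta$grid_seed)),
                    class = "rt_grid")
  networks <- lapply(.PARAMS, function(p) {
    d <- edges[edges$param == p, ]
    adj <- lapply(split(c(d$j, d$i), factor(c(d$i, d$j), levels = seq_len(n))),
                  function(v) sort(unique(as.integer(v))))
    names(adj) <- NULL
    structure(list(adj = adj, csr = .adj_to_csr(adj),
                   K_conn = as.integer(meta$K_conn), sigma = meta$sigma,
                   mode = meta$mode, seed = NULL,
                   mean_degree = mean(lengths(adj))),
              class = "rt_network")
  })
  names(networks) <- .PARAMS
  structure(list(grid = grid, networks = networks,
                 K_conn = as.integer(meta$K_conn), sigma = meta$sigma,
                 mode = meta$mode, seed = as.integer(meta$seed),
                 mean_degree = mean(vapply(networks, `[[`, 0, "mean_degree"))),
            class = "rt_landscape")
}

#' Write a walk trajectory as CSV (plus optional JSON sidecar)
#'
#' One row per step: the level indices, raw parameter values, steady-state
#' concentrations, benefit, cost, fitness, and the mutated parameter.
#'
#' @param walk an `rt_walk` from an `rt_landscape`.
#' @param landscape the landscape it was run on.
#' @param file output CSV path.
#' @param model the [grn_model()] used.
#' @param sidecar optional JSON path for metadata (seed, flags).
#' @param peak_fitness optional global-peak fitness for the
#'   `reached_global` flag.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(walk, landscape, file, model = grn_model(),
                             sidecar = NULL, peak_fitness = NULL) {
  G <- walk$genotypes
  comp <- landscape_fitness(landscape, G, model, components = TRUE)
  P <- genotype_params(landscape, G)
  df <- data.frame(step_index = seq_len(nrow(G)) - 1L)
  for (p in seq_len(ncol(G))) df[[paste0("idx_", .PARAMS[p])]] <- G[, p]
  for (p in seq_len(ncol(P))) df[[.PARAMS[p]]] <- .fmt17(P[, p])
  df$R <- .fmt17(comp$R); df$R_star <- .fmt17(comp$R_star)
  df$T <- .fmt17(comp$T); df$B <- .fmt17(comp$B); df$C <- .fmt17(comp$C)
  df$F <- .fmt17(comp$F)
  df$mutated_param <- c(NA, .PARAMS[walk$mutated[-1]])
  write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(sidecar)) {
    meta <- list(seed = walk$seed, n_steps = walk$n_steps, terminal = TRUE,
                 reached_global = if (is.null(peak_fitness)) NULL
                                  else reached_global(walk, peak_fitness),
                 terminal_fitness = walk$fitness[length(walk$fitness)])
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
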