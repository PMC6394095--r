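# fitscape

Simulation framework for evolutionary movement on the fitness landscape of
the simplest transcription network: a signal-activated regulator R and a
single target protein T. It asks a structural question about adaptation:
**how many alternative values of a biochemical parameter must be reachable
by a single mutation for a population to find the global fitness peak
instead of trapping at local optima?**

## The model in brief

The network's dynamics

    dR/dt  = bas − k_act·R·S + k_r·R* − k_d·R
    dR*/dt = k_act·R·S − k_r·R* − k_d·R*
    dT/dt  = β·R*² / (K_m² + R*²) − k_dT·T

have a closed-form steady state under a constant signal S, and fitness is
a cost-benefit function of that steady state:

    B = a·T/(T + b),   C = α·(T + R* + R),   F = B − C

with defaults a = 1, b = 10, α = 2.5e-5, and k_r = 1e-3·k_act.

Each of the six evolvable parameters (bas, k_act, k_d, β, K_m, k_dT) is
discretized to 1000 permissible values. A *neighbor network* of
connectivity K — built from a Gaussian kernel in rank space (σ = 20, i.e.
2% of the levels) and symmetrized to an (almost) K-regular graph — defines
which levels one mutation can reach, so a genotype has ≈ 6K one-mutant
neighbors. An *adaptive walk* repeatedly moves to a uniformly chosen
strictly beneficial neighbor until none exists (a local or global
optimum). Ensemble drivers measure, across K values and starting
fitnesses: the fraction of replicates reaching the global peak (a sharp
transition near K ≈ 10, 1% of levels), mean mutational steps to the peak,
the speed of evolution (fitness gain per mutational event), and
between-replicate variance dynamics. Exhaustively enumerable toy
landscapes with an absorbing-Markov-chain oracle back every stochastic
statistic with exact values.

## Worked example

```r
library(fitscape)

grid <- build_grid(seed = 1)                      # 6 x 1000 discrete levels
peak <- estimate_global_peak(grid, seed = 1)
peak
#> <rt_peak> grid fitness 0.954782 | continuous 0.954782 (agreement: TRUE)

land  <- build_landscape(grid, K_conn = 50, seed = 2)
start <- find_start_genotype(grid, target = 0.0826, seed = 3)
walk  <- adaptive_walk(land, start, seed = 4)
walk
#> <rt_walk> 87 accepted mutations, fitness 0.0826595 -> 0.954782 (terminal)
reached_global(walk, peak)
#> [1] TRUE
```

The walk climbed from fitness 0.083 to the global peak (0.955) in 87
mutations. The critical-connectivity scan reproduces the transition:

```r
scan <- critical_k_scan(grid, experiment_design(K_values = c(5, 10, 20),
                                                n_replicates = 20),
                        seed = 1)
scan$table[, 1:3]
#>   K start_fitness fraction_reached
#>   5        0.0826             0.00
#>   5        0.2251             0.15
#>   5        0.4500             0.30
#>   5        0.6264             0.05
#>   5        0.8526             0.55
#>  10        0.0826             1.00
#>  10        0.2251             0.90
#>  10        0.4500             0.95
#>  10        0.6264             0.95
#>  10        0.8526             1.00
#>  20        0.0826             1.00
#>  20        0.2251             1.00
#>  20        0.4500             1.00
#>  20        0.6264             1.00
#>  20        0.8526             1.00
scan$transition_K
#> [1] 10
```

At K = 5 almost every replicate traps at a local optimum; at K = 10
(~1% of levels) nearly all reach the global peak; by K = 20 all do.

A thin CLI wraps the same functions (`exec/fitscape` with subcommands
`simulate`, `scan`, `peak`, `fixture`; YAML config, CSV/JSON outputs).
See `vignettes/landscape-walks.Rmd` for the model, estimator choices and
their rationale.

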