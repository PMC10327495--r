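# Expensive simulated builds shared across acceptance tests, computed once
# per test run.  Problem sizes are the package's desk-scale study
# conditions (see the methods vignette).

.acc_cache <- new.env(parent = emptyenv())

acc_memo <- function(key, fn) {
  if (is.null(.acc_cache[[key]])) assign(key, fn(), envir = .acc_cache)
  .acc_cache[[key]]
}

# 10 genomes x 100 kb at ~1 % average pairwise divergence, default rates.
acc_build_default <- function() {
  acc_memo("build_default", function() {
    sp <- sim_params(n = 10L, len = 100000L, generations = 50L,
                     mu = mutation_rate_for_divergence(0.01, 10, 50))
    sim <- simulate_population(sp, seed = 42L)
    g <- build_pangraph(sim$genomes)
    list(sim = sim, graph = g)
  })
}

# One simulated population + build + breakpoint comparison against the
# true graph (the population-level refinement: a junction in any lineage
# cuts every path, in the truth exactly as in a built graph).
run_divergence_point <- function(divergence, seed, n = 10L, len = 50000L) {
  sp <- sim_params(n = n, len = len, generations = 50L,
                   mu = mutation_rate_for_divergence(divergence, n, 50))
  sim <- simulate_population(sp, seed = seed)
  g <- build_pangraph(sim$genomes)
  tg <- true_pangraph(sim$truth)
  glen <- stats::setNames(nchar(sim$genomes), names(sim$genomes))
  disp <- breakpoint_displacement(graph_breakpoints(g),
                                  graph_breakpoints(tg), glen)
  n_true <- sum(lengths(graph_breakpoints(tg)))
  list(disp = disp, n_true = n_true, graph = g, sim = sim)
}

acc_divergence_runs <- function() {
  acc_memo("divergence_runs", function() {
    seeds <- c(101L, 202L, 303L)
    list(low = lapply(seeds, function(s) run_divergence_point(0.01, s)),
         high = lapply(seeds, function(s) run_divergence_point(0.15, s)))
  })
}

# 20-strain build for the marginalization-consistency check; full-length
# genomes so boundary-scale disagreement is measured against a realistic
# genome size
acc_build_20 <- function() {
  acc_memo("build_20", function() {
    sp <- sim_params(n = 20L, len = 100000L, generations = 50L,
                     mu = mutation_rate_for_divergence(0.01, 20, 50))
    sim <- simulate_population(sp, seed = 77L)
    g <- build_pangraph(sim$genomes)
    list(sim = sim, graph = g)
  })
}
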