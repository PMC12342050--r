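# Independent numerical oracles and shared (memoised) simulations.

# quadrature oracle for E[log beta] under Beta(a, b)
quad_elogbeta <- function(a, b) {
  integrate(function(x) log(x) * dbeta(x, a, b), 0, 1,
            rel.tol = 1e-10)$value
}

# time-weighted moment of order p from per-cycle records (single-step
# lineages only: one exponential segment per cycle)
cycles_time_moment <- function(cycles, p, mu = 1, drop = 100) {
  cyc <- if (drop > 0) cycles[-seq_len(drop), ] else cycles
  total <- sum(cyc$interdivision_time)
  sum((cyc$division_size^p - cyc$birth_size^p) / (p * mu)) / total
}

# simulations reused across test files, built once per run
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# long deterministic-halving adder lineage (mu = k = 1)
adder_det_sim <- function() cached("adder_det", function() {
  simulate_lineage(sim_config(single_step_params(1, 1, 1),
                              partition_law(0.5, 0),
                              n_cycles = 1e5, seed = 8675309))
})

# five-stage equal-rate lineage with mild partitioning noise
m5_sim <- function() cached("m5", function() {
  simulate_lineage(sim_config(equal_rate_params(1, 1, 5),
                              partition_law(0.5, 0.02),
                              n_cycles = 1e5, seed = 5551212))
})
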