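# Steady-state simulations are deterministic but not free; cache them so
# several test files can share the same converged cycles.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, m, cfg = sim_config()) {
  if (!exists(key, envir = .sim_cache))
    assign(key, suppressWarnings(simulate_steady_state(m, cfg)),
           envir = .sim_cache)
  get(key, envir = .sim_cache)
}

cached_sweep <- function(key, spec, cfg = sim_config()) {
  if (!exists(key, envir = .sim_cache))
    assign(key, run_sweep(spec, cfg), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# endpoint-only sweeps used by several acceptance/property checks
endpoint_sweep <- function(scenario, varied, from, to, overrides = list()) {
  key <- paste("ep", scenario, varied, from, to,
               paste(names(overrides), unlist(overrides), collapse = "_"),
               sep = "_")
  cached_sweep(key, sweep_spec(scenario, varied, from, to, n = 2L,
                               overrides = overrides))
}

random_state <- function(m, scale = 1) {
  s <- default_initial_state(m)
  s * stats::runif(12, 0.5, 1.5) * scale
}
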