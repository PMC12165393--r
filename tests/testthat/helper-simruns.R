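# Shared expensive computations for the acceptance suite: the 5-seed
# oscillatory and oscillation-free simulation batches are used by several
# criteria, so they are computed lazily once per test run.

.acc_cache <- new.env(parent = emptyenv())

acc_cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) assign(key, force(expr), envir = .acc_cache)
  get(key, envir = .acc_cache)
}

# one simulated module realization at the reference configuration
# (N = 75, hexagonal spacing 0.85 m, sigma = 0.12, 30-min synthetic
# trajectory), scored with the self-mode reference
acc_module_run <- function(seed, bank) {
  pop <- gridPopulation(N = 75, spacing = 0.85, sigma = 0.12, seed = seed)
  traj <- synthTrajectory(1800, seed = seed + 2)
  spikes <- simulateGridModule(pop, traj, bank, seed = seed + 3)
  bs <- runTDA(spikes, tdaConfig(), seed = seed + 4)
  sc <- toroidality(bs, referenceMode = "self")
  list(score = sc, gap = h1h2Gap(bs))
}

acc_batch <- function(cond) {
  acc_cached(cond, {
    bank <- if (cond == "osc") buildOscillatorBank("methods_default") else
      buildOscillatorBank("none")
    lapply(1:5, function(s) acc_module_run(100 + s, bank))
  })
}
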