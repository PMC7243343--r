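# Shared fixtures for the test suite. Simulations that only probe invariants
# (not published equilibrium values) run on a shortened integration or a
# smaller array to keep the suite fast; equilibrium-sensitive checks use the
# full defaults.

zero_inputs <- function(n = 20L) {
  msi_inputs(numeric(n), numeric(n), numeric(n), numeric(n))
}

aligned_condition <- function(condition, intensity, n = 20L, loc = 8,
                              sigma = 1) {
  build_condition_inputs(
    condition_spec(condition,
                   audio = stimulus_spec(loc, sigma, intensity),
                   visual = stimulus_spec(loc, sigma, intensity)),
    n)
}

# Readout responses (M, V, A) at the stimulus-aligned neuron for one
# intensity, computed in a single batch.
readout_mva <- function(params, intensity, offset = 0, loc = 8L, sigma = 1) {
  n <- params$n_neurons
  mk <- function(cnd) {
    build_condition_inputs(
      condition_spec(cnd,
                     audio = stimulus_spec(loc, sigma, intensity),
                     visual = stimulus_spec(loc + offset, sigma, intensity)),
      n)
  }
  out <- simulate_batch(list(mk("bimodal_full"), mk("bimodal_no_cortex"),
                             mk("unimodal_visual"), mk("unimodal_audio")),
                        params)
  m <- out$membrane[loc + 1L, ]
  list(M_on = m[1], M_off = m[2], V = m[3], A = m[4])
}
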