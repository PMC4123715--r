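# Shared fixture builders.  Everything is generated in code; no stored data.

R_GAS <- 8.314
FARADAY <- 96485

# independent brute-force four-state open probability: plain arithmetic on
# the unnormalized weights, no log-space machinery (keep |exponents| < ~200
# so the naive path cannot overflow)
brute_force_po <- function(J, L, D, v, temp) {
  tk <- temp + 273.15
  j <- exp(-(J$dH - tk * J$dS - J$z * FARADAY * v / 1000) / (R_GAS * tk))
  l <- exp(-(L$dH - tk * L$dS - L$z * FARADAY * v / 1000) / (R_GAS * tk))
  (l + j * l * D) / (1 + j + l + j * l * D)
}

# a model that is open with probability ~ 1 everywhere (for ohmic fixtures)
always_open_model <- function() thermo_transition(dH = -1e5, dS = 0, z = 0)

# random moderate transition parameters for property sweeps
random_transition <- function() {
  thermo_transition(dH = runif(1, -2e5, 2e5), dS = runif(1, -600, 600),
                    z = runif(1, -6, 6))
}

random_allosteric <- function() {
  allosteric_params(J = random_transition(), L = random_transition(),
                    D = 10^runif(1, -1, 6))
}

# replicate G-V pipeline run: returns mean fitted parameters
run_gv_recovery <- function(v_half, q, test_voltages, n_reps, seed,
                            noise_sd = 0.5) {
  res <- gv_recovery_experiment(v_half, q, test_voltages, n_reps = n_reps,
                                seed = seed, noise_sd = noise_sd)
  stopifnot(all(res$converged))
  list(v_half = mean(res$v_half_mV), q = mean(res$q_e0))
}
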