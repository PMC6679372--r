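## Small shared fixtures for the toy-ensemble tests.

quick_harmonic <- function(..., n_samples = 400, seed = 11) {
  toy_system_spec("harmonic_morph", n_samples = n_samples, seed = seed, ...)
}

quick_charging <- function(..., k = 300, n_samples = 400, seed = 5) {
  toy_system_spec("charging", k_A = k, k_B = k,
                  n_samples = n_samples, seed = seed, ...)
}

## Independent brute-force re-evaluation of the ligand-bath Coulomb energy
## over stored snapshots (plain pairwise sum, no package internals).
brute_coulomb <- function(traj, q_site) {
  X <- traj$configurations
  f <- 138.935458
  q_bath <- -0.1
  vapply(seq_len(nrow(X)), function(s) sum(f * q_site * q_bath / abs(X[s, ])),
         numeric(1))
}

## A free_energy with minimal ceremony
fe <- function(value, sigma = 0, method = "TI", direction = c("A", "B")) {
  free_energy(value, sigma, method, direction)
}
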