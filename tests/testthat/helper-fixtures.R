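# shared fixtures built in code

# final published population model (also exercised via final_model())
published_model <- function(...) {
  population_model(
    theta = pk_parameters(cl = 14.7, v1 = 26.0, q = 2.25, v2 = 9.93),
    ...)
}

# typical 70-kg parameters
typical_params <- function() pk_parameters(14.7, 26.0, 2.25, 9.93)

# reference dose: 12 g/m2 for a 1.85 m2 (70 kg) individual
ref_dose <- function() 22200

# tiny deterministic dataset for I/O and LSS plumbing tests
toy_dataset <- function(n = 6, seed = 123, residual_error = FALSE) {
  simulate_group(final_model(), 12, 2, n = n, seed = seed,
                 residual_error = residual_error)
}
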