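# small shared scenario constructors for the test suite

quiet_scenario <- function(...) {
  # noise-free enclosure scenario with no wall loss, for exact oracles
  enclosure_scenario(noise_cv = 0, residual_loss_frac = 0,
                     n_replicates = 1, samples_per_phase = 5, ...)
}

small_assay <- function(...) {
  assay_scenario(duration_min = 1, dt_min = 0.25, ...)
}
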