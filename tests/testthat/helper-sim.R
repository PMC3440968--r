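# Small, fast simulation configs reused across tests.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_probes = 40L, n_confirmed = 32L,
             n_predicted = 8L, ...)
}

# Noise-free configuration: deterministic signals, no dye bias, no
# background variability, so every downstream quantity is exact.
clean_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_probes = 40L, n_confirmed = 32L,
                   n_predicted = 8L, noise_sd_log2 = 0,
                   background_sd = 0, dye_bias_amplitude = 0,
                   frac_treatment_effect = 0, frac_gender_effect = 0,
                   ct_noise_sd = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# One tiny hand-built chip: 2 probes x 2 channels x 3 spots.
tiny_chip <- function(bg_mean = 20, bg_sd = 5) {
  spots <- expand.grid(probe_id = c("mir-a", "mir-b"),
                       spot_index = 1:3,
                       channel = c("Cy3", "Cy5"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  spots <- spots[order(spots$probe_id, spots$channel, spots$spot_index), ]
  spots$raw_signal <- 100 + seq_len(nrow(spots))
  chip_data("tiny", bg_mean, bg_sd, spots)
}
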