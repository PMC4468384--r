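# shared fixtures: small, fast configurations used across test files

# deterministic micro-network: no membrane noise, no tonic sensory baseline
quiet_config <- function(n = 100, ...) {
  network_config(n_per_type = n,
                 dynamics = list(membrane_noise_sd_mv = 0),
                 odor = list(osn_baseline_mv = 0),
                 ...)
}

# default-calibration config at reduced size for speed
small_config <- function(n = 50, ...) network_config(n_per_type = n, ...)

# granule-cell parameters straight from the shipped profile
gr_params <- function() network_config()$populations$gr

# run a detection measurement: n_base spontaneous runs + reference + evoked
quick_detect <- function(net, odor, ne_um, seed, population = "pyr",
                         n_base = 7, duration = 1200, settle = 200) {
  ne <- ne_state(ne_um, ne_um)
  spont <- lapply(seq_len(n_base + 1), function(i) {
    run_simulation(net, NULL, ne, duration_ms = duration,
                   settle_ms = settle, seed = derive_seed(seed, 101, i))
  })
  ev <- run_simulation(net, odor, ne, duration_ms = duration,
                       settle_ms = settle, seed = derive_seed(seed, 999))
  detection_index(lapply(spont[seq_len(n_base)], `[[`,
                         c("rates", population)),
                  ev$rates[[population]],
                  spont[[n_base + 1]]$rates[[population]])
}
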