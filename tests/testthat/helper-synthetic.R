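# Shared fixtures, built in code. Sessions are kept small: LFP-only work
# runs at 1 kHz (no decimation needed), spike tests at >= 6 kHz.

# LFP-only session -> conditioned, z-scored, epoched
make_lfp_epochs <- function(n_calls = 40, seed = 1,
                            burst_table = default_burst_table()[0, ],
                            coherence_table = default_coherence_table()[0, ],
                            n_faf = 1, n_cn = 1, evoked_amp = 0,
                            isolation_fraction = 1) {
  cfg <- session_config(
    n_faf_channels = n_faf, n_cn_channels = n_cn, fs_neural_hz = 1000,
    n_calls_per_class = n_calls, isolation_fraction = isolation_fraction,
    burst_table = burst_table, coherence_table = coherence_table,
    evoked_amp = evoked_amp, make_audio = FALSE, make_spikes = FALSE,
    rng_seed = seed)
  s <- generate_session(cfg)
  rec <- zscore_recording(bandpass_lfp(s$recording), "auto")
  keep <- s$events$isolated & !s$events$is_distractor
  list(epochs = extract_epochs(rec, s$events[keep, , drop = FALSE]),
       session = s)
}

# session with phase-locked spiking (1 FAF + 1 CN channel at 1 kHz)
make_spiking_session <- function(kappa, seed = 1, n_calls = 40,
                                 preferred_phase = pi / 2, base_rate = 40) {
  cfg <- session_config(
    n_faf_channels = 1, n_cn_channels = 1, fs_neural_hz = 1000,
    n_calls_per_class = n_calls, isolation_fraction = 1,
    burst_table = default_burst_table()[0, ],
    coherence_table = default_coherence_table()[0, ],
    spike_coupling = spike_coupling("theta", kappa = kappa,
                                    preferred_phase = preferred_phase,
                                    base_rate_hz = base_rate),
    evoked_amp = 0, spike_amp_mad = 0, make_audio = FALSE,
    make_spikes = TRUE, rng_seed = seed)
  s <- generate_session(cfg)
  rec <- zscore_recording(bandpass_lfp(s$recording), "auto")
  list(epochs = extract_epochs(rec, s$events[s$events$isolated, , drop = FALSE]),
       spikes = s$spikes, session = s)
}

# bare feature_set for decoder unit tests
make_feature_set <- function(x, y) {
  structure(list(x = as.matrix(x), y = factor(y), band = "test",
                 window = c(-0.5, 0), time = seq_len(ncol(as.matrix(x))),
                 log_power = TRUE),
            class = "feature_set")
}

# single-channel recording wrapper
wrap_recording <- function(x, fs, structure = "CN", depth = 200) {
  neural_recording(matrix(x, nrow = 1), fs,
                   data.frame(structure = structure, depth_um = depth,
                              stringsAsFactors = FALSE))
}
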