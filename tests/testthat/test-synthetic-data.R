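# Synthetic-data generator: call templates, session structure, determinism,
# spectral shape of the background, and phase-locked spiking.

test_that("call templates hit their spectral targets through the de-noised FFT", {
  fs <- 250000
  ca <- generate_call_audio(echolocation_spec(), rng_seed = 4)
  i0 <- round(ca$event$onset_s * fs) + 1
  len <- round(0.001 * fs)
  pk <- peak_frequency(ca$waveform[i0:(i0 + len - 1)],
                       ca$waveform[(i0 - len):(i0 - 1)], fs)
  expect_lt(abs(pk - 72), 2)

  cc <- generate_call_audio(communication_spec("LF"), rng_seed = 4)
  i0 <- round(cc$event$onset_s * fs) + 1
  len <- round(0.005 * fs)
  pk2 <- peak_frequency(cc$waveform[i0:(i0 + len - 1)],
                        cc$waveform[(i0 - len):(i0 - 1)], fs)
  expect_lt(abs(pk2 - 14), 1)

  # LHF variant carries real >50 kHz energy; LF does not
  lhf <- generate_call_audio(communication_spec("LHF"), rng_seed = 4)
  i0 <- round(lhf$event$onset_s * fs) + 1
  sp <- vocolock:::denoised_spectrum(lhf$waveform[i0:(i0 + len - 1)],
                                     lhf$waveform[(i0 - len):(i0 - 1)], fs)
  expect_equal(subclassify_communication(sp), "LHF")
})

test_that("degenerate call specs are rejected", {
  expect_error(call_class_spec("echolocation", duration_ms = 0,
                               peak_freq_khz = 72), "positive")
  expect_error(generate_call_audio(echolocation_spec(), fs = 100000),
               "Nyquist")
  expect_error(call_class_spec("echolocation", duration_ms = 1,
                               peak_freq_khz = 40), "> 50")
  expect_error(call_class_spec("communication", "LF", duration_ms = 5,
                               peak_freq_khz = 14, hf_component_gain = 1),
               "hf_component_gain")
})

test_that("identical seeds regenerate the session bit-identically", {
  cfg <- session_config(n_faf_channels = 2, n_cn_channels = 1,
                        fs_neural_hz = 1000, n_calls_per_class = 5,
                        make_audio = FALSE, make_spikes = TRUE,
                        spike_amp_mad = 0, rng_seed = 33)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$traces, s2$recording$traces)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$events, s2$events)
  expect_identical(serialize(s1$ground_truth, NULL),
                   serialize(s2$ground_truth, NULL))
})

test_that("background spectrum follows the configured 1/f slope", {
  for (alpha in c(1, 1.5)) {
    cfg <- session_config(n_faf_channels = 1, n_cn_channels = 1,
                          fs_neural_hz = 1000, n_calls_per_class = 30,
                          burst_table = default_burst_table()[0, ],
                          coherence_table = default_coherence_table()[0, ],
                          evoked_amp = 0, alpha = alpha, make_audio = FALSE,
                          make_spikes = FALSE, rng_seed = 8)
    s <- generate_session(cfg)
    x <- s$recording$traces[1, ]
    pg <- stats::spec.pgram(stats::ts(x, frequency = 1000), spans = 51,
                            plot = FALSE, taper = 0)
    sel <- pg$freq >= 2 & pg$freq <= 80
    fit <- stats::lm(log10(pg$spec[sel]) ~ log10(pg$freq[sel]))
    expect_lt(abs(unname(fit$coefficients[2]) + alpha), 0.2)
  }
})

test_that("isolated events have no neighbors within 500 ms", {
  cfg <- session_config(n_faf_channels = 1, n_cn_channels = 1,
                        fs_neural_hz = 1000, n_calls_per_class = 20,
                        isolation_fraction = 0.5, make_audio = FALSE,
                        make_spikes = FALSE, rng_seed = 2)
  ev <- generate_session(cfg)$events
  expect_true(any(ev$contaminated_post))
  for (i in which(ev$isolated)) {
    others <- ev[-i, ]
    expect_false(any(others$onset_s < ev$offset_s[i] + 0.5 &
                       others$offset_s > ev$onset_s[i] - 0.5))
  }
  # contaminated_post calls have a vocalization in their post window
  for (i in which(ev$contaminated_post)) {
    others <- ev[-i, ]
    expect_true(any(others$onset_s >= ev$offset_s[i] &
                      others$onset_s < ev$offset_s[i] + 0.5))
  }
})

test_that("phase-locked spike generator converges to the von Mises law", {
  fs <- 1000
  phase <- Arg(exp(1i * 2 * pi * 6 * (0:(600 * fs - 1)) / fs)) # 6-Hz cycle
  # kappa = 0: uniform limit
  st0 <- generate_phase_locked_spikes(phase, 0, pi / 2, 10, fs, rng_seed = 5)
  ph0 <- phase[pmin(length(phase), round(st0 * fs) + 1)]
  expect_gt(length(ph0), 1000)
  expect_lt(vector_strength(ph0), 3 / sqrt(length(ph0)))
  # kappa = 5: concentration at the preferred phase, VS ~ I1(5)/I0(5)
  st5 <- generate_phase_locked_spikes(phase, 5, pi / 2, 10, fs, rng_seed = 5)
  ph5 <- phase[pmin(length(phase), round(st5 * fs) + 1)]
  expect_gt(length(ph5), 2000)
  expect_lt(abs(circular_mean(ph5) - pi / 2), 0.1)
  expect_lt(abs(vector_strength(ph5) - besselI(5, 1) / besselI(5, 0)), 0.05)
  # empty phase series -> empty train
  expect_identical(generate_phase_locked_spikes(numeric(0), 5, 0, 10, fs),
                   numeric(0))
})

test_that("von Mises sampler matches its closed-form moments", {
  th <- withr::with_seed(7, rvonmises(20000, 1, 2))
  expect_lt(abs(vector_strength(th) - besselI(2, 1) / besselI(2, 0)), 0.02)
  expect_lt(abs(circular_mean(th) - 1), 0.05)
  u <- withr::with_seed(7, rvonmises(5000, 0, 0))
  expect_lt(vector_strength(u), 3 / sqrt(5000))
})
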