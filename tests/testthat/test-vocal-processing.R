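# Call detection, spectral characterization, classification rules and
# isolation selection.

test_that("detect_calls finds isolated pulses at their true onsets", {
  fs <- 250000
  x <- withr::with_seed(1, rnorm(fs * 2.5, sd = 1e-3))
  tone <- sin(2 * pi * 30000 * (0:(round(0.002 * fs) - 1)) / fs)
  on1 <- 0.5; on2 <- 1.5
  for (on in c(on1, on2)) {
    i0 <- round(on * fs) + 1
    x[i0:(i0 + length(tone) - 1)] <- x[i0:(i0 + length(tone) - 1)] + 0.5 * tone
  }
  ev <- detect_calls(x, fs)
  expect_equal(nrow(ev), 2)
  expect_lt(max(abs(ev$onset_s - c(on1, on2))), 5e-4)

  # silent audio: no events, no error
  expect_equal(nrow(detect_calls(withr::with_seed(2, rnorm(fs, sd = 1e-3)),
                                 fs)), 0)
})

test_that("sub-threshold dips shorter than min_gap are bridged", {
  fs <- 250000
  x <- withr::with_seed(3, rnorm(fs, sd = 1e-3))
  n <- round(0.004 * fs)
  tone <- 0.5 * sin(2 * pi * 20000 * (0:(n - 1)) / fs)
  gap <- round(0.0001 * fs) # 0.1-ms silent dip mid-call
  tone[(n / 2):(n / 2 + gap)] <- 0
  i0 <- round(0.5 * fs)
  x[i0:(i0 + n - 1)] <- x[i0:(i0 + n - 1)] + tone
  expect_equal(nrow(detect_calls(x, fs, min_gap_ms = 1)), 1)
})

test_that("call spectrogram resolves tones, sweeps and DC", {
  fs <- 250000
  t <- (0:(round(0.003 * fs) - 1)) / fs
  m <- call_spectrogram(sin(2 * pi * 72000 * t), fs)
  expect_equal(m$params$nfft, 2048)
  ridge <- m$freq[apply(m$values, 1, which.max)]
  expect_lt(max(abs(ridge - 72000)), fs / 2048 * 1.5)

  # downward sweep 90 -> 60 kHz: monotonically decreasing ridge
  finst <- seq(90000, 60000, length.out = length(t))
  sw <- sin(2 * pi * cumsum(finst) / fs)
  ms <- call_spectrogram(sw, fs)
  ridge <- ms$freq[apply(ms$values, 1, which.max)]
  mid <- ridge[seq(5, length(ridge) - 5)] # edges are padded frames
  expect_lt(stats::cor(mid, seq_along(mid)), -0.95)
  expect_gt(mid[1], tail(mid, 1))

  # DC input: all power in bin 0
  md <- call_spectrogram(rep(2, length(t)), fs)
  expect_true(all(apply(md$values, 1, which.max) == 1))

  # shorter than one frame: single-frame map
  expect_equal(length(call_spectrogram(sin(2 * pi * 50000 * t[1:50]), fs)$time), 1)
})

test_that("peak_frequency implements de-noising, ties and scale invariance", {
  fs <- 250000
  n <- round(0.005 * fs)
  t <- (0:(n - 1)) / fs
  noise <- withr::with_seed(4, rnorm(n, sd = 0.05))
  call <- sin(2 * pi * 14000 * t) + withr::with_seed(5, rnorm(n, sd = 0.05))
  pk <- peak_frequency(call, noise, fs)
  expect_lt(abs(pk - 14), fs / n / 1000 * 1.5)
  # amplitude scaling of both snippets leaves the peak unchanged
  expect_equal(peak_frequency(call * 7.3, noise * 7.3, fs), pk)

  # call identical to noise: exact cancellation, flagged undefined
  expect_warning(res <- peak_frequency(noise, noise, fs), "undefined")
  expect_true(is.na(res))

  # two equal peaks at 20 and 60 kHz: tie broken toward the lower frequency
  nt <- 25000 # 0.1 s: both tones on exact FFT bins
  tt <- (0:(nt - 1)) / fs
  two <- sin(2 * pi * 20000 * tt) + sin(2 * pi * 60000 * tt)
  expect_equal(peak_frequency(two, numeric(nt), fs), 20)
})

test_that("class and subclass rules honor their boundary contracts", {
  expect_equal(classify_call(72), "echolocation")
  expect_equal(classify_call(14), "communication")
  expect_equal(classify_call(50.0), "communication") # boundary
  sp <- function(h, l) list(freq_khz = c(20, 60), power = c(l, h))
  expect_equal(subclassify_communication(sp(6, 10)), "LHF")
  expect_equal(subclassify_communication(sp(4, 10)), "LF")
  expect_equal(subclassify_communication(sp(5, 10)), "LHF") # H = L/2 inclusive
  expect_equal(subclassify_communication(list(freq_khz = c(10, 20),
                                              power = c(1, 2))), "LF")
})

test_that("select_isolated applies the 500-ms rule, start margins and is idempotent", {
  ev <- data.frame(onset_s = c(1.0, 1.3, 3.0),
                   offset_s = c(1.0, 1.3, 3.0) + 0.01)
  out <- select_isolated(ev, recording_bounds = c(0, 5))
  expect_equal(out$isolated, c(FALSE, FALSE, TRUE))

  out2 <- select_isolated(data.frame(onset_s = c(3.0, 3.2),
                                     offset_s = c(3.01, 3.21)),
                          recording_bounds = c(0, 10))
  expect_true(out2$contaminated_post[1])
  expect_false(out2$isolated[1])

  out3 <- select_isolated(data.frame(onset_s = 0.2, offset_s = 0.21),
                          recording_bounds = c(0, 10))
  expect_false(out3$isolated)

  # idempotent and order-independent
  shuffled <- ev[c(3, 1, 2), ]
  expect_equal(select_isolated(select_isolated(ev, recording_bounds = c(0, 5)),
                               recording_bounds = c(0, 5))$isolated,
               out$isolated)
  expect_equal(select_isolated(shuffled, recording_bounds = c(0, 5))$isolated,
               out$isolated)
})

test_that("generator calls are recovered and classified perfectly end to end", {
  cfg <- session_config(n_faf_channels = 1, n_cn_channels = 1,
                        fs_neural_hz = 1000, n_calls_per_class = 6,
                        isolation_fraction = 1, make_audio = TRUE,
                        make_spikes = FALSE, rng_seed = 12)
  s <- generate_session(cfg)
  ev <- annotate_calls(s$audio$x, s$audio$fs)
  ev <- ev[!is.na(ev$class), ]
  expect_equal(nrow(ev), nrow(s$events))
  ord <- order(ev$onset_s)
  # template peaks are >= 10 kHz away from the 50-kHz boundary: 100% recovery
  expect_equal(ev$class[ord], s$events$class)
  expect_lt(max(abs(ev$onset_s[ord] - s$events$onset_s)), 1e-3)
})

test_that("WAV round trip preserves the waveform to 16-bit precision", {
  x <- withr::with_seed(6, runif(5000, -0.9, 0.9))
  path <- tempfile(fileext = ".wav")
  write_wav(x, path, 250000)
  back <- read_wav(path)
  expect_equal(back$fs, 250000)
  expect_lt(max(abs(back$x - x)), 1 / 32767 + 1e-9)
  unlink(path)
})
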