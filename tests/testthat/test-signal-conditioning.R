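# LFP conditioning: filtering, line-noise removal, decimation, z-scoring,
# epoching, spike detection, PSTH and tuning curves.

test_that("LFP band-pass preserves the passband and rejects 200 Hz and DC", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  in6 <- sin(2 * pi * 6 * t)
  out6 <- bandpass_lfp(wrap_recording(in6, fs))$traces[1, ]
  mid <- seq(5 * fs, 15 * fs)
  expect_lt(abs(stats::sd(out6[mid]) / stats::sd(in6[mid]) - 1), 0.05)

  in200 <- sin(2 * pi * 200 * t)
  out200 <- bandpass_lfp(wrap_recording(in200, fs))$traces[1, ]
  expect_lt(stats::sd(out200[mid]) / stats::sd(in200[mid]), 0.1)

  outdc <- bandpass_lfp(wrap_recording(rep(3, length(t)), fs))$traces[1, ]
  expect_lt(mean(abs(outdc)), 0.01 * 3)

  expect_error(bandpass_lfp(wrap_recording(c(1, NA, 1), fs)), "non-finite")
})

test_that("line-noise removal attenuates 50 Hz but leaves clean signals intact", {
  fs <- 1000
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  wn <- withr::with_seed(11, rnorm(n))
  pw50 <- function(x) {
    X <- Mod(stats::fft(x))^2
    fr <- (0:(n - 1)) * fs / n
    mean(X[abs(fr - 50) < 0.5])
  }
  contam <- wn + 5 * sin(2 * pi * 50 * t)
  out <- remove_line_noise(wrap_recording(contam, fs))$traces[1, ]
  expect_gt(10 * log10(pw50(contam) / pw50(out)), 10)

  clean <- remove_line_noise(wrap_recording(wn, fs))$traces[1, ]
  expect_lt(abs(stats::sd(clean) - stats::sd(wn)) / stats::sd(wn), 0.01)

  tone <- 3 * sin(2 * pi * 50 * t)
  resid <- remove_line_noise(wrap_recording(tone, fs))$traces[1, ]
  expect_lt(stats::sd(resid) / stats::sd(tone), 0.1)

  expect_error(remove_line_noise(wrap_recording(wn, fs), win_s = 0.01),
               "cycles")
})

test_that("decimation preserves in-band content and suppresses aliases", {
  fs <- 20000
  t <- (0:(20000 - 1)) / fs
  rec30 <- wrap_recording(sin(2 * pi * 30 * t), fs)
  dn <- downsample_recording(rec30, 1000)
  expect_equal(ncol(dn$traces), 1000)
  expect_equal(dn$fs, 1000)
  mid <- 200:800
  expect_lt(abs(stats::sd(dn$traces[1, mid]) / stats::sd(sin(2 * pi * 30 * t)) - 1),
            0.02)
  # dominant frequency unchanged
  X <- Mod(stats::fft(dn$traces[1, ]))[1:500]
  expect_equal(which.max(X) - 1, 30 * 1)

  rec700 <- wrap_recording(sin(2 * pi * 700 * t), fs)
  d700 <- downsample_recording(rec700, 1000)
  expect_lt(stats::sd(d700$traces[1, mid]) / stats::sd(sin(2 * pi * 700 * t)),
            0.1)

  expect_error(downsample_recording(wrap_recording(t, fs), 1500), "divide")
})

test_that("z-scoring modes follow the per-structure conventions", {
  set.seed(21)
  tr <- rbind(rnorm(5000, 3, 1), rnorm(5000, -1, 2))
  rec <- neural_recording(tr, 1000,
                          data.frame(structure = c("FAF", "FAF"),
                                     depth_um = c(50, 100)))
  zp <- zscore_recording(rec, "per_channel")
  expect_lt(max(abs(rowMeans(zp$traces))), 1e-9)
  expect_lt(max(abs(apply(zp$traces, 1, sd) - 1)), 1e-9)

  za <- zscore_recording(rec, "across_channels")
  r <- sd(za$traces[2, ]) / sd(za$traces[1, ])
  expect_lt(abs(r - 2), 0.1) # amplitude relationship preserved

  recc <- neural_recording(rbind(rnorm(100), rep(1, 100)), 1000,
                           data.frame(structure = c("CN", "CN"),
                                      depth_um = c(200, 400)))
  expect_error(zscore_recording(recc, "per_channel"), "zero-variance")
})

test_that("epoch extraction indexes the onset sample exactly and skips margins", {
  fs <- 1000
  x <- seq_len(10 * fs) # trace value = sample index
  rec <- wrap_recording(x, fs)
  ep <- extract_epochs(rec, data.frame(onset_s = 2, class = "echolocation",
                                       subclass = "none"))
  expect_equal(dim(ep$data)[3], 1001)
  expect_equal(ep$data[1, 1, 501], x[2 * fs + 1]) # t = 0 sample
  expect_equal(ep$time[501], 0)

  ep0 <- extract_epochs(rec, data.frame(onset_s = numeric(0)))
  expect_equal(dim(ep0$data)[1], 0)

  expect_warning(eps <- extract_epochs(rec, data.frame(onset_s = 0.1)),
                 "skipped")
  expect_equal(dim(eps$data)[1], 0)
})

test_that("spike detection recovers injected spikes with few false positives", {
  fs <- 20000
  x <- withr::with_seed(31, rnorm(10 * fs))
  bf <- signal::butter(2, c(300, 3000) / (fs / 2), "pass")
  sigma <- stats::mad(signal::filtfilt(bf, x))
  w_half <- round(0.0004 * fs)
  shape <- -exp(-(((-w_half:w_half) / fs)^2) / (2 * 0.00008^2))
  tr_idx <- withr::with_seed(32, sort(sample(seq(fs, 9 * fs), 50)))
  tr_idx <- tr_idx[c(TRUE, diff(tr_idx) > 0.005 * fs)]
  for (j in tr_idx) {
    x[(j - w_half):(j + w_half)] <- x[(j - w_half):(j + w_half)] +
      12 * sigma * shape
  }
  st <- detect_spikes(wrap_recording(x, fs))[[1]]
  hits <- vapply((tr_idx - 1) / fs,
                 function(t0) any(abs(st$times - t0) < 2e-4), logical(1))
  expect_gte(sum(hits), length(tr_idx) - 1)

  # detection count invariant to positive rescaling
  st2 <- detect_spikes(wrap_recording(3.7 * x, fs))[[1]]
  expect_equal(length(st2$times), length(st$times))

  # pure Gaussian noise: < 1 Hz false positives over 10 s
  stn <- detect_spikes(wrap_recording(withr::with_seed(33, rnorm(10 * fs)),
                                      fs))[[1]]
  expect_lt(length(stn$times) / 10, 1)
})

test_that("refractory lockout merges spikes closer than 1 ms", {
  fs <- 20000
  x <- withr::with_seed(34, rnorm(2 * fs))
  bf <- signal::butter(2, c(300, 3000) / (fs / 2), "pass")
  sigma <- stats::mad(signal::filtfilt(bf, x))
  w_half <- round(0.0002 * fs)
  shape <- -exp(-(((-w_half:w_half) / fs)^2) / (2 * 0.00006^2))
  for (j in c(fs, fs + round(0.0003 * fs))) { # two spikes 0.3 ms apart
    x[(j - w_half):(j + w_half)] <- x[(j - w_half):(j + w_half)] +
      15 * sigma * shape
  }
  st <- detect_spikes(wrap_recording(x, fs))[[1]]
  near <- st$times[abs(st$times - (fs - 1) / fs) < 0.002]
  expect_equal(length(near), 1)
})

test_that("PSTH counts spikes per trial in half-open 3-ms bins", {
  onsets <- seq(10, 100, by = 10)
  p <- psth(onsets, onsets) # one spike exactly at t = 0 per trial
  zero_bin <- which(p$t_left <= 0 & p$t_left + 0.003 > 0)
  expect_equal(p$spikes_per_trial[zero_bin], 1.0)
  expect_equal(sum(p$spikes_per_trial), 1.0)

  # homogeneous Poisson spikes: bins ~ rate * binwidth
  r <- 100
  spikes <- withr::with_seed(41, sort(runif(r * 200, 0, 200)))
  p2 <- psth(spikes, seq(10, 190, by = 2))
  expect_lt(abs(mean(p2$spikes_per_trial) - r * 0.003), 0.02)

  expect_equal(sum(psth(numeric(0), onsets)$spikes_per_trial), 0)
  expect_error(psth(1:3, numeric(0)), "trial")
})

test_that("best frequency is the argmax of post-onset Hilbert energy", {
  fs <- 1000
  freqs <- seq(10, 30, by = 5)
  mk_ep <- function(amp) {
    tt <- seq(-0.5, 0.5, by = 1 / fs)
    resp <- amp * exp(-((tt - 0.05)^2) / (2 * 0.02^2)) * sin(2 * pi * 20 * tt)
    dat <- array(rep(resp, each = 2), dim = c(2, 1, length(tt)))
    epoch_set(dat, fs, c(-0.5, 0.5),
              data.frame(class = "tone", subclass = "none", onset_s = c(1, 2)),
              data.frame(structure = "CN", depth_um = 200))
  }
  # channel responds only to 15 kHz
  eps <- lapply(freqs, function(f) mk_ep(if (f == 15) 1 else 0.05))
  bf <- best_frequency(eps, freqs)
  expect_equal(bf$best_khz, 15)
  # doubling response amplitude leaves the best frequency unchanged
  eps2 <- lapply(freqs, function(f) mk_ep(2 * (if (f == 15) 1 else 0.05)))
  expect_equal(best_frequency(eps2, freqs)$best_khz, 15)
  # flat responses: tie goes to the lowest grid frequency
  flat <- lapply(freqs, function(f) mk_ep(1))
  expect_equal(best_frequency(flat, freqs)$best_khz, 10)
  expect_warning(best_frequency(flat[1], freqs[1]), "single")
})

test_that("conditioning commutes with epoching away from edges", {
  fs <- 20000
  y <- withr::with_seed(51, rnorm(20 * fs))
  full <- downsample_recording(bandpass_lfp(wrap_recording(y, fs)), 1000)
  ep_full <- extract_epochs(full, data.frame(onset_s = 10))$data[1, 1, ]
  seg <- wrap_recording(y[(7 * fs + 1):(13 * fs)], fs)
  segp <- downsample_recording(bandpass_lfp(seg), 1000)
  ep_seg <- extract_epochs(segp, data.frame(onset_s = 3))$data[1, 1, ]
  expect_lt(sqrt(mean((ep_full - ep_seg)^2)), 1e-6)
})

test_that("z-scored FAF epochs pool to zero mean and unit spread", {
  made <- make_lfp_epochs(n_calls = 20, seed = 3, n_faf = 2)
  faf <- made$epochs$data[, made$epochs$channel_meta$structure == "FAF", ]
  expect_lt(abs(mean(faf)), 0.1)
  expect_lt(abs(stats::sd(as.numeric(faf)) - 1), 0.15)
})
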