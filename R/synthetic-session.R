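# Synthetic recording sessions with the statistical structure the analyses
# assume: 1/f LFP background, call-locked band-limited bursts with per-trial
# phase jitter, inter-areal coherent components with a fixed lag, a
# deterministic post-call evoked deflection in deep FAF channels, and
# spiking phase-locked to a chosen LFP band. Everything is driven by one
# seed and summarized in a ground-truth record.

#' One injected oscillatory burst, locked to call onsets of one class
#'
#' The burst is a Gaussian-windowed sinusoid at the band's center frequency
#' placed in the stated window relative to call onset, added to all channels
#' of `region` whose depth lies in `depth_range`. Its phase is drawn
#' uniformly per trial (and per channel), so extensive trial averaging
#' removes the oscillation but randomization-trial spectra retain the power
#' contrast.
#'
#' @param class `"echolocation"` or `"communication"`.
#' @param region `"FAF"` or `"CN"`.
#' @param depth_range numeric `c(min, max)` depth in um.
#' @param band band name (see [lfp_bands()]) or `c(low, high)` Hz.
#' @param window_ms `c(start, end)` relative to call onset, within +-500 ms.
#' @param gain burst amplitude in z-comparable units, `>= 0`.
#' @return one-row data.frame.
#' @export
burst_entry <- function(class, region, depth_range = c(0, 800), band,
                        window_ms, gain) {
  band <- resolve_band(band)
  stopifnot(class %in% c("echolocation", "communication"),
            region %in% c("FAF", "CN"),
            length(window_ms) == 2, window_ms[1] < window_ms[2],
            all(abs(window_ms) <= 500), gain >= 0)
  data.frame(class = class, region = region,
             depth_min_um = depth_range[1], depth_max_um = depth_range[2],
             f_lo = band[1], f_hi = band[2],
             t_start_ms = window_ms[1], t_end_ms = window_ms[2],
             gain = gain, stringsAsFactors = FALSE)
}

#' One inter-areal coherent component, locked to call onsets of one class
#'
#' A band-limited Gaussian-windowed sinusoid with a phase drawn per trial
#' but shared between regions: added to every FAF channel, and to every CN
#' channel delayed by `lag_ms`. Drives inter-areal coherence in the stated
#' band and window.
#'
#' @inheritParams burst_entry
#' @param lag_ms CN delay relative to FAF (ms).
#' @param strength component amplitude, `>= 0`.
#' @export
coherence_entry <- function(class, band = "theta", window_ms, lag_ms = 5,
                            strength = 1) {
  band <- resolve_band(band)
  stopifnot(class %in% c("echolocation", "communication"),
            length(window_ms) == 2, window_ms[1] < window_ms[2],
            all(abs(window_ms) <= 500), strength >= 0)
  data.frame(class = class, f_lo = band[1], f_hi = band[2],
             t_start_ms = window_ms[1], t_end_ms = window_ms[2],
             lag_ms = lag_ms, strength = strength, stringsAsFactors = FALSE)
}

#' Spike-LFP coupling parameters of the generator
#'
#' Spikes are an inhomogeneous Poisson process (realized by thinning) whose
#' intensity is `base_rate_hz * exp(kappa * cos(phase - preferred_phase)) /
#' I0(kappa)`, where `phase` is the Hilbert phase of the channel's own LFP
#' filtered to `band`; the stationary spike-phase distribution is then
#' exactly von Mises(`preferred_phase`, `kappa`). The rate is additionally
#' multiplied by `1 + evoked_gain` for 250 ms after each call onset.
#'
#' @param band band name or `c(low, high)` Hz.
#' @param kappa von Mises concentration, `>= 0` (0 = no locking).
#' @param preferred_phase preferred phase (rad; cosine convention).
#' @param base_rate_hz mean firing rate (Hz).
#' @param evoked_gain post-call rate multiplier minus one, `>= 0`.
#' @export
spike_coupling <- function(band = "theta", kappa = 2, preferred_phase = pi / 2,
                           base_rate_hz = 20, evoked_gain = 1) {
  band <- resolve_band(band)
  stopifnot(kappa >= 0, base_rate_hz > 0, evoked_gain >= 0)
  list(f_lo = band[1], f_hi = band[2], kappa = kappa,
       preferred_phase = preferred_phase, base_rate_hz = base_rate_hz,
       evoked_gain = evoked_gain)
}

#' Default injection structure of the generator
#'
#' Pre-call high-gamma and high-beta power in deep FAF channels during
#' echolocation, pre-call CN theta power during communication; theta
#' coherence pre-onset for communication vs. late post-onset for
#' echolocation (CN lagging FAF by 5 ms).
#'
#' @return data.frame of [burst_entry()] / [coherence_entry()] rows.
#' @export
default_burst_table <- function() {
  rbind(
    burst_entry("echolocation", "FAF", c(350, 800), "high_gamma",
                c(-300, -50), gain = 2),
    burst_entry("echolocation", "FAF", c(350, 800), "high_beta",
                c(-300, -50), gain = 1.5),
    burst_entry("communication", "CN", c(0, 800), "theta",
                c(-400, -100), gain = 1.5)
  )
}

#' @rdname default_burst_table
#' @export
default_coherence_table <- function() {
  rbind(
    coherence_entry("communication", "theta", c(-400, -100), lag_ms = 5,
                    strength = 1.5),
    coherence_entry("echolocation", "theta", c(280, 480), lag_ms = 5,
                    strength = 1.5)
  )
}

#' Configuration of a synthetic recording session
#'
#' @param n_faf_channels laminar FAF channels (depths 50-um spaced from
#'   50 um).
#' @param n_cn_channels CN channels (200-um spaced).
#' @param fs_neural_hz neural sampling rate (Hz; 20 kHz matches the
#'   acquisition; lower rates are accepted for LFP-only work).
#' @param fs_audio_hz audio sampling rate (Hz).
#' @param n_calls_per_class calls per class.
#' @param isolation_fraction fraction of calls with >= 500 ms of silence on
#'   both sides; the remainder get a trailing distractor pulse within
#'   500 ms (clean pre, contaminated post).
#' @param burst_table data.frame of [burst_entry()] rows (may be empty).
#' @param coherence_table data.frame of [coherence_entry()] rows.
#' @param spike_coupling a [spike_coupling()] list.
#' @param alpha spectral exponent of the 1/f background (power ~ 1/f^alpha).
#' @param evoked_amp amplitude of the deterministic post-call deflection in
#'   deep FAF channels (z-comparable units).
#' @param evoked_depth_min_um minimum depth receiving the evoked deflection.
#' @param spike_amp_mad amplitude of injected spike waveforms in multiples
#'   of the MAD of the 300-3,000 Hz background.
#' @param make_audio synthesize the audio track (off for LFP-only work).
#' @param make_spikes simulate spike trains (requires
#'   `fs_neural_hz >= 4 * f_hi` of the coupling band).
#' @param rng_seed master integer seed; recorded in the ground truth.
#' @return validated list of class `session_config`.
#' @export
session_config <- function(n_faf_channels = 16, n_cn_channels = 4,
                           fs_neural_hz = 20000, fs_audio_hz = 250000,
                           n_calls_per_class = 30, isolation_fraction = 0.8,
                           burst_table = default_burst_table(),
                           coherence_table = default_coherence_table(),
                           spike_coupling = vocolock::spike_coupling(),
                           alpha = 1, evoked_amp = 1,
                           evoked_depth_min_um = 500, spike_amp_mad = 8,
                           make_audio = TRUE, make_spikes = TRUE,
                           rng_seed = 1) {
  stopifnot(n_faf_channels >= 1, n_cn_channels >= 1,
            fs_neural_hz >= 200, n_calls_per_class >= 1,
            isolation_fraction >= 0, isolation_fraction <= 1,
            alpha >= 0, evoked_amp >= 0, spike_amp_mad >= 0)
  if (nrow(burst_table) > 0) {
    stopifnot(all(burst_table$gain >= 0),
              all(burst_table$f_lo >= 1), all(burst_table$f_hi <= 90),
              all(abs(c(burst_table$t_start_ms, burst_table$t_end_ms)) <= 500))
  }
  stopifnot(spike_coupling$kappa >= 0)
  structure(list(
    n_faf_channels = n_faf_channels, n_cn_channels = n_cn_channels,
    fs_neural_hz = fs_neural_hz, fs_audio_hz = fs_audio_hz,
    n_calls_per_class = n_calls_per_class,
    isolation_fraction = isolation_fraction,
    burst_table = burst_table, coherence_table = coherence_table,
    spike_coupling = spike_coupling, alpha = alpha,
    evoked_amp = evoked_amp, evoked_depth_min_um = evoked_depth_min_um,
    spike_amp_mad = spike_amp_mad, make_audio = make_audio,
    make_spikes = make_spikes, rng_seed = as.integer(rng_seed)),
    class = "session_config")
}

# 1/f^alpha noise by FFT spectral shaping of white noise, unit variance.
# Frequencies below 1 Hz keep the 1-Hz magnitude (flat floor) so the
# variance does not diverge for alpha >= 1.
one_over_f_noise <- function(n, fs, alpha = 1) {
  z <- stats::rnorm(n)
  if (alpha == 0) return(z)
  Z <- stats::fft(z)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency magnitudes
  shape <- pmax(f, 1)^(-alpha / 2)
  shape[1] <- 0                        # remove DC
  x <- Re(stats::fft(Z * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

# gaussian burst envelope on time axis tt (s) for window [t1, t2] (s):
# sd = width/4 so the window covers ~95% of the mass
burst_envelope <- function(tt, t1, t2) {
  tc <- (t1 + t2) / 2
  sdv <- (t2 - t1) / 4
  exp(-((tt - tc)^2) / (2 * sdv^2))
}

# schedule call events; returns the event table (no audio yet)
schedule_events <- function(config) {
  n_per <- config$n_calls_per_class
  cls <- rep(c("echolocation", "communication"), n_per)
  # communication subclasses: alternate LF / LHF
  sub <- ifelse(cls == "communication",
                rep(c("LF", "LHF"), length.out = length(cls)), "none")
  dur_ms <- ifelse(cls == "echolocation", 1, 5)
  n_tot <- length(cls)
  n_contam <- round((1 - config$isolation_fraction) * n_tot)
  contam <- rep(FALSE, n_tot)
  if (n_contam > 0) contam[sample.int(n_tot, n_contam)] <- TRUE
  rows <- list()
  cursor <- 1.0
  for (i in seq_len(n_tot)) {
    # jittered spacing; inter-onset always > 1 s so +-0.5 s epochs of
    # neighboring calls never share samples
    onset <- cursor + stats::runif(1, 0.05, 0.25)
    offset <- onset + dur_ms[i] / 1000
    rows[[length(rows) + 1]] <- data.frame(
      onset_s = onset, offset_s = offset, duration_ms = dur_ms[i],
      class = cls[i], subclass = sub[i],
      isolated = !contam[i], contaminated_post = contam[i],
      is_distractor = FALSE, stringsAsFactors = FALSE)
    if (contam[i]) {
      # trailing distractor pulse 250 ms after offset: clean pre for call i,
      # contaminated post
      d_on <- offset + 0.25
      rows[[length(rows) + 1]] <- data.frame(
        onset_s = d_on, offset_s = d_on + 0.001, duration_ms = 1,
        class = "echolocation", subclass = "none",
        isolated = FALSE, contaminated_post = FALSE,
        is_distractor = TRUE, stringsAsFactors = FALSE)
      cursor <- d_on + 0.001 + 0.96
    } else {
      cursor <- offset + 0.96
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic session
#'
#' Produces call audio, a multichannel neural recording, spike trains, an
#' event table, and a ground-truth record. Identical configurations
#' (including the seed) give bit-identical outputs.
#'
#' @param config a [session_config()].
#' @return list with elements `audio` (list `x`, `fs`, or NULL), `recording`
#'   (a [neural_recording()]), `spikes` (list of spike-time vectors, one per
#'   channel; NULL if `make_spikes = FALSE`), `events` (data.frame), and
#'   `ground_truth` (list; sufficient to regenerate the session).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$rng_seed, generate_session_impl(config))
}

generate_session_impl <- function(config) {
  events <- schedule_events(config)
  fs <- config$fs_neural_hz
  dur_raw <- max(events$offset_s) + 1.0
  n_samp <- stats::nextn(ceiling(dur_raw * fs), c(2, 3, 5)) # FFT-friendly
  duration_s <- n_samp / fs
  tt <- (seq_len(n_samp) - 1) / fs

  meta <- data.frame(
    structure = c(rep("FAF", config$n_faf_channels),
                  rep("CN", config$n_cn_channels)),
    depth_um = c(50 * seq_len(config$n_faf_channels),
                 200 * seq_len(config$n_cn_channels)),
    stringsAsFactors = FALSE)
  n_ch <- nrow(meta)
  traces <- matrix(0, n_ch, n_samp)

  for (ch in seq_len(n_ch)) {
    traces[ch, ] <- one_over_f_noise(n_samp, fs, config$alpha)
  }

  add_windowed_tone <- function(ch, onset, t1, t2, f_c, amp, phase) {
    # support limited to +-3 sd around the window center
    tc <- onset + (t1 + t2) / 2
    half <- 3 * (t2 - t1) / 4 + (t2 - t1) / 2
    i0 <- max(1L, time_to_index(tc - half, 0, fs))
    i1 <- min(n_samp, time_to_index(tc + half, 0, fs))
    if (i0 >= i1) return(invisible())
    seg_t <- tt[i0:i1] - onset
    traces[ch, i0:i1] <<- traces[ch, i0:i1] +
      amp * burst_envelope(seg_t, t1, t2) * cos(2 * pi * f_c * seg_t + phase)
    invisible()
  }

  # class-, region- and depth-specific bursts (random phase per trial/channel)
  bt <- config$burst_table
  if (!is.null(bt) && nrow(bt) > 0) {
    for (b in seq_len(nrow(bt))) {
      chans <- which(meta$structure == bt$region[b] &
                       meta$depth_um >= bt$depth_min_um[b] &
                       meta$depth_um <= bt$depth_max_um[b])
      evs <- which(events$class == bt$class[b] & !events$is_distractor)
      f_c <- (bt$f_lo[b] + bt$f_hi[b]) / 2
      for (e in evs) {
        for (ch in chans) {
          add_windowed_tone(ch, events$onset_s[e],
                            bt$t_start_ms[b] / 1000, bt$t_end_ms[b] / 1000,
                            f_c, bt$gain[b], stats::runif(1, 0, 2 * pi))
        }
      }
    }
  }

  # inter-areal coherent components: phase shared across regions, CN lagged
  ct <- config$coherence_table
  faf_ch <- which(meta$structure == "FAF")
  cn_ch <- which(meta$structure == "CN")
  if (!is.null(ct) && nrow(ct) > 0) {
    for (b in seq_len(nrow(ct))) {
      evs <- which(events$class == ct$class[b] & !events$is_distractor)
      f_c <- (ct$f_lo[b] + ct$f_hi[b]) / 2
      lag_s <- ct$lag_ms[b] / 1000
      for (e in evs) {
        ph <- stats::runif(1, 0, 2 * pi)
        for (ch in faf_ch) {
          add_windowed_tone(ch, events$onset_s[e],
                            ct$t_start_ms[b] / 1000, ct$t_end_ms[b] / 1000,
                            f_c, ct$strength[b], ph)
        }
        for (ch in cn_ch) {
          add_windowed_tone(ch, events$onset_s[e] + lag_s,
                            ct$t_start_ms[b] / 1000, ct$t_end_ms[b] / 1000,
                            f_c, ct$strength[b], ph)
        }
      }
    }
  }

  # deterministic post-call evoked deflection in deep FAF channels
  if (config$evoked_amp > 0) {
    deep <- which(meta$structure == "FAF" &
                    meta$depth_um >= config$evoked_depth_min_um)
    for (e in which(!events$is_distractor)) {
      for (ch in deep) {
        tc <- events$onset_s[e] + 0.08
        i0 <- max(1L, time_to_index(tc - 0.12, 0, fs))
        i1 <- min(n_samp, time_to_index(tc + 0.12, 0, fs))
        seg_t <- tt[i0:i1]
        traces[ch, i0:i1] <- traces[ch, i0:i1] -
          config$evoked_amp * exp(-((seg_t - tc)^2) / (2 * 0.03^2))
      }
    }
  }

  # phase-locked spiking from each channel's own band phase
  spikes <- NULL
  if (config$make_spikes) {
    sc <- config$spike_coupling
    if (fs < 4 * sc$f_hi) {
      stop("fs_neural_hz too low for the spike-coupling band")
    }
    post_ind <- rep(FALSE, n_samp)
    for (e in which(!events$is_distractor)) {
      j0 <- time_to_index(events$onset_s[e], 0, fs)
      j1 <- min(n_samp, time_to_index(events$onset_s[e] + 0.25, 0, fs))
      post_ind[j0:j1] <- TRUE
    }
    bf <- signal::butter(2, c(sc$f_lo, sc$f_hi) / (fs / 2), type = "pass")
    spikes <- vector("list", n_ch)
    spike_wave_amp <- NULL
    for (ch in seq_len(n_ch)) {
      filt <- signal::filtfilt(bf, traces[ch, ])
      phase <- Arg(analytic_signal(filt))
      rate_mult <- 1 + sc$evoked_gain * post_ind
      st <- thinned_phase_spikes(phase, sc$kappa, sc$preferred_phase,
                                 sc$base_rate_hz, fs, rate_mult)
      spikes[[ch]] <- st
      if (config$spike_amp_mad > 0 && length(st) > 0) {
        if (is.null(spike_wave_amp)) {
          hp <- signal::butter(2, c(300, 3000) / (fs / 2), type = "pass")
          bg <- signal::filtfilt(hp, traces[ch, seq_len(min(n_samp, fs))])
          spike_wave_amp <- config$spike_amp_mad * stats::mad(bg)
        }
        # short negative-going waveform at each spike time
        w_half <- round(0.0004 * fs)
        w_t <- (-w_half:w_half) / fs
        wshape <- -exp(-(w_t^2) / (2 * 0.00008^2))
        for (s in st) {
          j <- time_to_index(s, 0, fs)
          j0 <- j - w_half; j1 <- j + w_half
          if (j0 >= 1 && j1 <= n_samp) {
            traces[ch, j0:j1] <- traces[ch, j0:j1] + spike_wave_amp * wshape
          }
        }
      }
    }
  }

  # audio track
  audio <- NULL
  if (config$make_audio) {
    fsa <- config$fs_audio_hz
    n_aud <- ceiling(duration_s * fsa)
    x <- stats::rnorm(n_aud, sd = 1e-3)
    for (e in seq_len(nrow(events))) {
      spec <- if (events$class[e] == "echolocation") {
        echolocation_spec()
      } else {
        communication_spec(events$subclass[e])
      }
      cw <- synth_call_samples(spec, fsa)
      i0 <- time_to_index(events$onset_s[e], 0, fsa)
      idx <- i0:(i0 + length(cw) - 1L)
      x[idx] <- x[idx] + cw
    }
    audio <- list(x = x / max(abs(x)), fs = fsa)
  }

  ground_truth <- list(
    events = events,
    burst_table = config$burst_table,
    coherence_table = config$coherence_table,
    spike_coupling = config$spike_coupling,
    alpha = config$alpha, evoked_amp = config$evoked_amp,
    evoked_depth_min_um = config$evoked_depth_min_um,
    duration_s = duration_s,
    rng_seed = config$rng_seed)

  list(audio = audio,
       recording = neural_recording(traces, fs, meta),
       spikes = spikes,
       events = events,
       ground_truth = ground_truth)
}

# inhomogeneous Poisson spikes by thinning; intensity
# base * exp(kappa cos(phase - mu)) / I0(kappa) * rate_mult
thinned_phase_spikes <- function(phase, kappa, mu, base_rate, fs,
                                 rate_mult = NULL) {
  n <- length(phase)
  if (n == 0L) return(numeric(0))
  max_mult <- if (is.null(rate_mult)) 1 else max(rate_mult)
  i0k <- besselI(kappa, 0, expon.scaled = TRUE)
  # exp(kappa cos(.))/I0 <= exp(kappa)/I0; with scaled Bessel:
  # exp(kappa*(cos-1))/i0k <= 1/i0k
  lam_max <- base_rate / i0k * max_mult
  dur <- n / fs
  n_cand <- stats::rpois(1, lam_max * dur)
  if (n_cand == 0L) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, dur))
  idx <- pmin(n, pmax(1L, as.integer(round(cand * fs)) + 1L))
  lam <- base_rate * exp(kappa * (cos(phase[idx] - mu) - 1)) / i0k
  if (!is.null(rate_mult)) lam <- lam * rate_mult[idx]
  keep <- stats::runif(n_cand) < lam / lam_max
  cand[keep]
}

#' Generate spikes phase-locked to a given LFP phase series
#'
#' Thinning of a Poisson process with intensity
#' `base_rate_hz * exp(kappa * cos(phase - preferred_phase)) / I0(kappa)`;
#' as the sample grows, the spike-phase histogram converges to
#' von Mises(`preferred_phase`, `kappa`). An empty phase series yields an
#' empty train.
#'
#' @param lfp_band_phase instantaneous phase series (rad) sampled at `fs`.
#' @param kappa concentration, `>= 0`.
#' @param preferred_phase preferred phase (rad).
#' @param base_rate_hz mean rate (Hz); must be below `fs / 2`.
#' @param fs sampling rate of the phase series (Hz).
#' @param rng_seed integer seed.
#' @return numeric vector of spike times (s, same timeline as the series).
#' @export
generate_phase_locked_spikes <- function(lfp_band_phase, kappa,
                                         preferred_phase, base_rate_hz,
                                         fs = 1000, rng_seed = 1) {
  stopifnot(kappa >= 0, base_rate_hz > 0)
  if (base_rate_hz >= fs / 2) stop("base_rate_hz must be below fs / 2")
  if (length(lfp_band_phase) == 0L) return(numeric(0))
  with_seed(rng_seed,
            thinned_phase_spikes(lfp_band_phase, kappa, preferred_phase,
                                 base_rate_hz, fs))
}
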