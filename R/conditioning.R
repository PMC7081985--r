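# Raw wideband traces -> analysis-ready LFP epochs, spike trains, PSTHs and
# pure-tone tuning summaries. All filtering is zero-phase (forward-backward
# Butterworth): downstream phase analyses cannot tolerate causal phase lag.

apply_filtfilt <- function(recording, filt) {
  out <- recording
  for (ch in seq_len(nrow(recording$traces))) {
    out$traces[ch, ] <- signal::filtfilt(filt, recording$traces[ch, ])
  }
  out
}

#' Band-pass filter a recording to the LFP range (1-90 Hz)
#'
#' Order-2 Butterworth band-pass applied forward-backward (zero phase).
#'
#' @param recording a [neural_recording()].
#' @param low_hz,high_hz band edges (Hz).
#' @return filtered [neural_recording()].
#' @export
bandpass_lfp <- function(recording, low_hz = 1, high_hz = 90) {
  stopifnot(inherits(recording, "neural_recording"),
            recording$fs >= 2 * high_hz)
  stop_if_not_finite(recording$traces, "recording traces")
  bf <- signal::butter(2, c(low_hz, high_hz) / (recording$fs / 2), type = "pass")
  apply_filtfilt(recording, bf)
}

#' Remove power-line noise with a sliding-window sinusoid fit
#'
#' In each window a least-squares sinusoid at `line_hz` (plus optional
#' harmonics) is fitted and subtracted; windows are combined by
#' Hann-weighted overlap-add (50% overlap by default).
#'
#' @param recording a [neural_recording()].
#' @param line_hz line frequency (Hz), below Nyquist.
#' @param win_s window length (s); must cover at least 2 line cycles.
#' @param step_s window step (s).
#' @param n_harmonics number of harmonics fitted (1 = fundamental only;
#'   default 2 includes the first harmonic).
#' @return cleaned [neural_recording()].
#' @export
remove_line_noise <- function(recording, line_hz = 50, win_s = 1,
                              step_s = 0.5, n_harmonics = 2) {
  stopifnot(inherits(recording, "neural_recording"),
            line_hz < recording$fs / 2)
  if (win_s < 2 / line_hz) stop("win_s must cover at least 2 line cycles")
  fs <- recording$fs
  n <- ncol(recording$traces)
  win_n <- round(win_s * fs)
  step_n <- max(1L, round(step_s * fs))
  if (win_n >= n) { win_n <- n; step_n <- n }
  starts <- seq(1L, max(1L, n - win_n + 1L), by = step_n)
  if (tail(starts, 1) + win_n - 1L < n) starts <- c(starts, n - win_n + 1L)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_n) - 1) / (win_n - 1))
  tt <- (seq_len(win_n) - 1) / fs
  harm <- seq_len(n_harmonics) * line_hz
  harm <- harm[harm < fs / 2]
  X <- do.call(cbind, lapply(harm, function(f) {
    cbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))
  }))
  qrX <- qr(X)
  out <- recording
  for (ch in seq_len(nrow(recording$traces))) {
    x <- recording$traces[ch, ]
    est <- numeric(n)
    wgt <- numeric(n)
    for (s in starts) {
      idx <- s:(s + win_n - 1L)
      fit <- X %*% qr.coef(qrX, x[idx])
      est[idx] <- est[idx] + hann * fit
      wgt[idx] <- wgt[idx] + hann
    }
    ok <- wgt > 1e-6
    est[ok] <- est[ok] / wgt[ok]
    out$traces[ch, ] <- x - est
  }
  out
}

#' Downsample a recording with anti-alias filtering
#'
#' Zero-phase order-4 Butterworth low-pass at `0.4 * target_fs`, then
#' decimation by the (integer) factor `fs / target_fs`.
#'
#' @param recording a [neural_recording()].
#' @param target_fs target sampling rate (Hz); must divide `fs`.
#' @return decimated [neural_recording()] with `fs = target_fs`.
#' @export
downsample_recording <- function(recording, target_fs = 1000) {
  stopifnot(inherits(recording, "neural_recording"))
  factor <- recording$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target_fs must divide the recording sampling rate")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(recording)
  lp <- signal::butter(4, (0.4 * target_fs) / (recording$fs / 2), type = "low")
  rec <- apply_filtfilt(recording, lp)
  rec$traces <- rec$traces[, seq(1L, ncol(rec$traces), by = factor), drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Z-score a recording
#'
#' `per_channel`: each channel is centered and scaled by its own mean/sd
#' over the whole recording. `across_channels`: one pooled mean/sd over all
#' channels is applied to each (preserves amplitude relationships between
#' channels). `auto` applies the convention used for the two structures:
#' across-channels for FAF, per-channel for CN.
#'
#' @param recording a [neural_recording()].
#' @param mode `"auto"`, `"per_channel"` or `"across_channels"`.
#' @return z-scored [neural_recording()].
#' @export
zscore_recording <- function(recording,
                             mode = c("auto", "per_channel", "across_channels")) {
  mode <- match.arg(mode)
  stopifnot(inherits(recording, "neural_recording"))
  tr <- recording$traces
  sds <- apply(tr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance channel(s): ", paste(which(sds == 0), collapse = ", "))
  }
  zc_per <- function(rows) {
    for (ch in rows) tr[ch, ] <<- (tr[ch, ] - mean(tr[ch, ])) / sds[ch]
  }
  zc_pooled <- function(rows) {
    m <- mean(tr[rows, ]); s <- stats::sd(as.numeric(tr[rows, ]))
    for (ch in rows) tr[ch, ] <<- (tr[ch, ] - m) / s
  }
  if (mode == "per_channel") {
    zc_per(seq_len(nrow(tr)))
  } else if (mode == "across_channels") {
    zc_pooled(seq_len(nrow(tr)))
  } else {
    faf <- which(recording$channel_meta$structure == "FAF")
    cn <- which(recording$channel_meta$structure == "CN")
    if (length(faf)) zc_pooled(faf)
    if (length(cn)) zc_per(cn)
  }
  recording$traces <- tr
  recording
}

#' Extract event-aligned epochs
#'
#' Cuts a window around each event onset; the `t = 0` sample is the sample
#' nearest the onset. Events whose window does not fit inside the recording
#' are skipped with a warning.
#'
#' @param recording a [neural_recording()] (typically conditioned, 1 kHz).
#' @param events data.frame with `onset_s` (and optionally `class`,
#'   `subclass`).
#' @param window `c(pre, post)` relative to onset (s).
#' @return an [epoch_set()]; trials ordered as the surviving events.
#' @export
extract_epochs <- function(recording, events, window = c(-0.5, 0.5)) {
  stopifnot(inherits(recording, "neural_recording"))
  fs <- recording$fs
  n <- ncol(recording$traces)
  n_pre <- round(-window[1] * fs)
  n_post <- round(window[2] * fs)
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    c0 <- time_to_index(events$onset_s[i], 0, fs)
    keep[i] <- (c0 - n_pre >= 1L) && (c0 + n_post <= n)
  }
  if (any(!keep)) {
    warning(sum(!keep), " event(s) out of bounds, skipped")
  }
  ev <- events[keep, , drop = FALSE]
  dat <- array(0, dim = c(nrow(ev), nrow(recording$traces), n_pre + n_post + 1L))
  for (i in seq_len(nrow(ev))) {
    c0 <- time_to_index(ev$onset_s[i], 0, fs)
    dat[i, , ] <- recording$traces[, (c0 - n_pre):(c0 + n_post), drop = FALSE]
  }
  labels <- data.frame(
    class = ev$class %||% rep(NA_character_, nrow(ev)),
    subclass = ev$subclass %||% rep("none", nrow(ev)),
    onset_s = ev$onset_s,
    stringsAsFactors = FALSE)
  if ("isolated" %in% names(ev)) labels$isolated <- ev$isolated
  if ("contaminated_post" %in% names(ev)) {
    labels$contaminated_post <- ev$contaminated_post
  }
  epoch_set(dat, fs, window, labels, recording$channel_meta)
}

#' Threshold spike detection (multi-unit)
#'
#' Each raw channel is band-passed 300-3,000 Hz (order-2 Butterworth, zero
#' phase); negative-going crossings of `-threshold_mad * MAD` (MAD with the
#' Gaussian-consistency factor 1/0.6745) are detected, the spike time is
#' the trough of each sub-threshold run, and a 1-ms refractory lockout is
#' enforced. Detection counts are invariant to positive rescaling of the
#' trace.
#'
#' @param recording raw [neural_recording()] with `fs >= 6000`.
#' @param threshold_mad threshold in MAD multiples (default 5).
#' @param lockout_ms refractory lockout (ms).
#' @return list with one element per channel: `times` (s), `channel`,
#'   `threshold` (absolute units), `threshold_mad`.
#' @export
detect_spikes <- function(recording, threshold_mad = 5, lockout_ms = 1) {
  stopifnot(inherits(recording, "neural_recording"), recording$fs >= 6000)
  fs <- recording$fs
  bf <- signal::butter(2, c(300, 3000) / (fs / 2), type = "pass")
  out <- vector("list", nrow(recording$traces))
  for (ch in seq_len(nrow(recording$traces))) {
    x <- signal::filtfilt(bf, recording$traces[ch, ])
    thr <- threshold_mad * stats::mad(x) # mad() includes the 1.4826 factor
    below <- x < -thr
    times <- numeric(0)
    if (any(below)) {
      r <- rle(below)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- cbind(starts[r$values], ends[r$values])
      troughs <- apply(runs, 1, function(se) {
        se[1] - 1L + which.min(x[se[1]:se[2]])
      })
      tt <- (troughs - 1) / fs
      # refractory lockout
      keep <- numeric(0)
      last <- -Inf
      for (t1 in tt) {
        if (t1 - last >= lockout_ms / 1000) {
          keep <- c(keep, t1)
          last <- t1
        }
      }
      times <- keep
    }
    out[[ch]] <- list(times = times, channel = ch, threshold = thr,
                      threshold_mad = threshold_mad)
  }
  out
}

#' Peri-stimulus time histogram
#'
#' Spikes per trial per bin: total spike count in each half-open bin
#' `[left, right)` across trials, divided by the number of trials.
#'
#' @param spike_times numeric vector of spike times (s, recording timeline).
#' @param onsets event onset times (s); at least one.
#' @param bin_ms bin size (ms).
#' @param window `c(pre, post)` around onset (s).
#' @return data.frame with `t_left`, `t_mid`, `spikes_per_trial`.
#' @export
psth <- function(spike_times, onsets, bin_ms = 3, window = c(-0.5, 0.5)) {
  if (length(onsets) == 0L) stop("psth requires at least one trial")
  edges <- seq(window[1], window[2], by = bin_ms / 1000)
  counts <- numeric(length(edges) - 1L)
  for (on in onsets) {
    rel <- spike_times - on
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      counts <- counts + tabulate(findInterval(rel, edges), length(counts))
    }
  }
  data.frame(t_left = edges[-length(edges)],
             t_mid = edges[-length(edges)] + bin_ms / 2000,
             spikes_per_trial = counts / length(onsets))
}

#' Best frequency from pure-tone LFP responses
#'
#' For each channel and stimulus frequency the trial-averaged LFP is
#' Hilbert-transformed; the instantaneous energy (modulus of the analytic
#' signal) summed over the post-onset window is the response. The stimulus
#' frequency with the highest energy is the best frequency (ties toward the
#' lower frequency). The response is invariant to common amplitude scaling
#' in the sense that scaling all responses leaves the argmax unchanged.
#'
#' @param tone_epochs list of [epoch_set()] objects, one per stimulus
#'   frequency, sharing channels and time axes.
#' @param stim_freq_khz stimulus frequencies (kHz), same length.
#' @param post_window window over which energy is summed (s rel. onset).
#' @return list with `best_khz` (per channel) and `tuning` (channels x
#'   frequencies energy matrix).
#' @export
best_frequency <- function(tone_epochs, stim_freq_khz,
                           post_window = c(0, 0.15)) {
  stopifnot(length(tone_epochs) == length(stim_freq_khz),
            length(tone_epochs) >= 1)
  if (length(stim_freq_khz) == 1L) {
    warning("single-frequency grid: best frequency is trivially that frequency")
  }
  ord <- order(stim_freq_khz)
  tone_epochs <- tone_epochs[ord]
  stim_freq_khz <- stim_freq_khz[ord]
  ep1 <- tone_epochs[[1]]
  n_ch <- dim(ep1$data)[2]
  sel <- ep1$time >= post_window[1] & ep1$time <= post_window[2]
  tuning <- matrix(0, n_ch, length(stim_freq_khz))
  for (j in seq_along(tone_epochs)) {
    ep <- tone_epochs[[j]]
    for (ch in seq_len(n_ch)) {
      mat <- ep$data[, ch, , drop = FALSE]
      dim(mat) <- dim(mat)[c(1, 3)]
      avg <- colMeans(mat)
      tuning[ch, j] <- sum(Mod(analytic_signal(avg))[sel])
    }
  }
  best <- stim_freq_khz[apply(tuning, 1, which.max)] # first max = lower freq
  list(best_khz = best, tuning = tuning, stim_freq_khz = stim_freq_khz)
}
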