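# Detection, characterization and classification of vocalizations from
# high-rate audio. Class rule: de-noised spectral peak above 50 kHz ->
# echolocation, otherwise communication; communication calls split into LF
# and LHF by the half-power rule on the >50 kHz part of the spectrum.

#' Detect supra-threshold acoustic events
#'
#' Envelope detector: the rectified waveform is smoothed with a moving
#' average (`smooth_ms`), thresholded at
#' `median(envelope) + threshold_mad * mad(envelope)`, and supra-threshold
#' runs separated by gaps shorter than `min_gap_ms` are merged.
#'
#' @param audio numeric waveform.
#' @param fs sampling rate (Hz).
#' @param threshold_mad threshold in MAD multiples above the median
#'   envelope.
#' @param min_gap_ms sub-threshold gaps shorter than this are bridged.
#' @param min_dur_ms events shorter than this are discarded as noise blips
#'   (well below the ~1-ms echolocation template).
#' @param smooth_ms moving-average length (ms).
#' @return data.frame with `onset_s`, `offset_s`, sorted by onset (possibly
#'   zero rows).
#' @export
detect_calls <- function(audio, fs, threshold_mad = 5, min_gap_ms = 1,
                         min_dur_ms = 0.2, smooth_ms = 0.1) {
  stop_if_not_finite(audio, "audio")
  n <- length(audio)
  w <- max(1L, round(smooth_ms / 1000 * fs))
  env <- stats::filter(abs(audio), rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- stats::median(env) + threshold_mad * stats::mad(env)
  above <- env > thr
  if (!any(above)) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge across short gaps
  gap_n <- min_gap_ms / 1000 * fs
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - merged$end[nrow(merged)] - 1 < gap_n) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  out <- data.frame(onset_s = (merged$start - 1) / fs,
                    offset_s = merged$end / fs)
  out[out$offset_s - out$onset_s >= min_dur_ms / 1000, , drop = FALSE]
}

#' Spectrogram of a call waveform
#'
#' Hamming-windowed short-time FFT with a 0.8-ms frame, 0.05-ms frame
#' shift, zero-padded to 2,048 points (frequency resolution `fs / 2048`).
#' A waveform shorter than one frame yields a single zero-padded frame.
#'
#' @param waveform numeric call waveform.
#' @param fs sampling rate (Hz), nominally 250 kHz.
#' @param frame_ms frame width (ms).
#' @param shift_ms frame shift (ms).
#' @param nfft FFT length.
#' @return a [tf_map] of kind `"power"` (freq in Hz up to `fs/2`).
#' @export
call_spectrogram <- function(waveform, fs, frame_ms = 0.8, shift_ms = 0.05,
                             nfft = 2048) {
  stop_if_not_finite(waveform, "waveform")
  frame_n <- round(frame_ms / 1000 * fs)
  n <- length(waveform)
  if (n < frame_n) {
    waveform <- c(waveform, numeric(frame_n - n))
    n <- frame_n
  }
  if (frame_n > nfft) stop("frame longer than nfft")
  starts <- unique(pmax(1L, as.integer(round(
    seq(1, n - frame_n + 1, by = shift_ms / 1000 * fs)))))
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_n) - 1) / (frame_n - 1))
  buf <- matrix(0, nfft, length(starts))
  for (i in seq_along(starts)) {
    buf[1:frame_n, i] <- waveform[starts[i]:(starts[i] + frame_n - 1L)] * ham
  }
  F <- stats::mvfft(buf)[1:(nfft / 2 + 1), , drop = FALSE]
  pw <- t(Re(F * Conj(F)))
  freq <- (0:(nfft / 2)) * fs / nfft
  tc <- (starts - 1 + (frame_n - 1) / 2) / fs
  structure(list(time = tc, freq = freq, values = pw, kind = "power",
                 params = list(frame_ms = frame_ms, shift_ms = shift_ms,
                               nfft = nfft, fs = fs)),
            class = "tf_map")
}

# one-sided de-noised magnitude spectrum: max(|FFT(call)| - |FFT(noise)|, 0)
denoised_spectrum <- function(call_waveform, noise_waveform, fs) {
  if (length(call_waveform) != length(noise_waveform)) {
    stop("call and noise snippets must have equal length")
  }
  n <- length(call_waveform)
  half <- seq_len(floor(n / 2) + 1L)
  mag <- pmax(Mod(stats::fft(call_waveform))[half] -
                Mod(stats::fft(noise_waveform))[half], 0)
  list(freq_khz = (half - 1) * fs / n / 1000, power = mag^2, de_noised = TRUE)
}

#' Peak frequency from the de-noised FFT
#'
#' The noise-floor magnitude spectrum (equal-length snippet, by default
#' taken immediately before the call) is subtracted from the call magnitude
#' spectrum, negative values floored at zero, and the frequency of the
#' maximum returned. Ties (within relative 1e-9) break toward the lower
#' frequency. If the difference is identically zero the peak is undefined
#' and `NA` is returned with a warning.
#'
#' @param call_waveform call snippet.
#' @param noise_waveform noise snippet of the same length.
#' @param fs sampling rate (Hz).
#' @return peak frequency in kHz (scalar, `NA` if undefined).
#' @export
peak_frequency <- function(call_waveform, noise_waveform, fs) {
  sp <- denoised_spectrum(call_waveform, noise_waveform, fs)
  m <- max(sp$power)
  if (m <= 0) {
    warning("de-noised spectrum identically zero: peak frequency undefined")
    return(NA_real_)
  }
  idx <- which(sp$power >= m * (1 - 1e-9))[1] # lowest-frequency tie wins
  sp$freq_khz[idx]
}

#' Classify a call from its spectral peak
#'
#' Peak above 50 kHz: echolocation; at or below 50 kHz: communication
#' (boundary assigned to communication).
#'
#' @param peak_freq_khz numeric vector of peak frequencies (kHz).
#' @param boundary_khz class boundary (default 50).
#' @return character vector of class labels.
#' @export
classify_call <- function(peak_freq_khz, boundary_khz = 50) {
  stopifnot(is.numeric(peak_freq_khz))
  ifelse(peak_freq_khz > boundary_khz, "echolocation", "communication")
}

#' Split communication calls into LF and LHF
#'
#' LHF if the power maximum above 50 kHz is at least half the power maximum
#' below 50 kHz (`H >= L / 2`, boundary inclusive); otherwise LF. An empty
#' high band gives LF.
#'
#' @param spectrum list with `freq_khz` and `power` (e.g. from the
#'   de-noised FFT).
#' @param boundary_khz split frequency (default 50).
#' @return `"LF"` or `"LHF"`.
#' @export
subclassify_communication <- function(spectrum, boundary_khz = 50) {
  stopifnot(!is.null(spectrum$freq_khz), !is.null(spectrum$power))
  hi <- spectrum$power[spectrum$freq_khz > boundary_khz]
  lo <- spectrum$power[spectrum$freq_khz <= boundary_khz]
  if (length(hi) == 0L || length(lo) == 0L) return("LF")
  if (max(hi) >= max(lo) / 2) "LHF" else "LF"
}

#' Flag temporally isolated calls
#'
#' A call is isolated when no other event onset or offset falls within
#' `pre_s` before its onset or `post_s` after its offset, and the margins
#' fit inside the recording. Calls with a clean pre-window but another
#' vocalization within `post_s` after offset are flagged
#' `contaminated_post` (the decoder-generalization control set). The
#' operation is idempotent and independent of input order.
#'
#' @param events data.frame with `onset_s`, `offset_s` (extra columns kept).
#' @param pre_s clean time required before onset (s).
#' @param post_s clean time required after offset (s).
#' @param recording_bounds `c(start, end)` of the recording (s).
#' @return `events` with logical columns `isolated` and
#'   `contaminated_post`, sorted by onset.
#' @export
select_isolated <- function(events, pre_s = 0.5, post_s = 0.5,
                            recording_bounds = c(0, Inf)) {
  stopifnot(all(events$offset_s > events$onset_s))
  events <- events[order(events$onset_s), , drop = FALSE]
  n <- nrow(events)
  clean_pre <- clean_post <- logical(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    pre_lo <- events$onset_s[i] - pre_s
    post_hi <- events$offset_s[i] + post_s
    overlaps <- function(lo, hi) {
      any(events$onset_s[others] < hi & events$offset_s[others] > lo)
    }
    clean_pre[i] <- pre_lo >= recording_bounds[1] &&
      !overlaps(pre_lo, events$onset_s[i])
    clean_post[i] <- post_hi <= recording_bounds[2] &&
      !overlaps(events$offset_s[i], post_hi)
  }
  events$isolated <- clean_pre & clean_post
  events$contaminated_post <- clean_pre & !clean_post
  rownames(events) <- NULL
  events
}

#' Detect, characterize and classify all calls in a recording
#'
#' Runs [detect_calls()], estimates each call's de-noised peak frequency
#' against an equal-length noise snippet taken immediately before the call,
#' applies the class and LF/LHF rules, and flags isolation.
#'
#' @inheritParams detect_calls
#' @param pre_s,post_s isolation margins (s).
#' @return event table (data.frame) with onset_s, offset_s, duration_ms,
#'   peak_freq_khz, class, subclass, isolated, contaminated_post.
#' @export
annotate_calls <- function(audio, fs, threshold_mad = 5, min_gap_ms = 1,
                           min_dur_ms = 0.2, pre_s = 0.5, post_s = 0.5) {
  ev <- detect_calls(audio, fs, threshold_mad, min_gap_ms, min_dur_ms)
  n <- nrow(ev)
  ev$duration_ms <- (ev$offset_s - ev$onset_s) * 1000
  ev$peak_freq_khz <- NA_real_
  ev$class <- NA_character_
  ev$subclass <- "none"
  for (i in seq_len(n)) {
    i0 <- time_to_index(ev$onset_s[i], 0, fs)
    i1 <- time_to_index(ev$offset_s[i], 0, fs) - 1L
    len <- i1 - i0 + 1L
    if (i0 - len < 1L) next # no room for a matched noise snippet
    call_w <- audio[i0:i1]
    noise_w <- audio[(i0 - len):(i0 - 1L)]
    sp <- denoised_spectrum(call_w, noise_w, fs)
    if (max(sp$power) <= 0) next
    pk <- sp$freq_khz[which(sp$power >= max(sp$power) * (1 - 1e-9))[1]]
    ev$peak_freq_khz[i] <- pk
    ev$class[i] <- classify_call(pk)
    if (ev$class[i] == "communication") {
      ev$subclass[i] <- subclassify_communication(sp)
    }
  }
  select_isolated(ev, pre_s, post_s,
                  recording_bounds = c(0, length(audio) / fs))
}
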