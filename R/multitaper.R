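# Multitaper spectral estimation with discrete prolate spheroidal (Slepian)
# tapers. Defaults follow the locked-LFP analysis settings: 250-ms windows,
# time-bandwidth product TW = 2, K = 3 tapers, on 1-kHz LFP data. The
# sub-sample 0.5-ms step of the original Chronux call is rounded up to one
# sample; coarser steps are a plain parameter.

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computed as eigenvectors of the symmetric tridiagonal matrix whose
#' spectrum orders sequences by energy concentration in `[-W, W]`
#' (Slepian's tridiagonal formulation). Tapers are unit-energy columns,
#' ordered by decreasing concentration.
#'
#' @param n taper length in samples.
#' @param tw time-bandwidth product (half-bandwidth `W = tw / n` in
#'   cycles/sample).
#' @param k number of tapers; must satisfy `k <= 2 * tw - 1`.
#' @return `n x k` matrix, one taper per column, `sum(col^2) = 1`.
#' @export
dpss_tapers <- function(n, tw = 2, k = 3) {
  stopifnot(n >= 2, tw > 0)
  if (k > 2 * tw - 1) stop("number of tapers k must be <= 2*TW - 1")
  w <- tw / n
  t0 <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign: symmetric tapers positive mean, antisymmetric
  # tapers positive initial slope
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    s <- if (abs(sum(v)) > 1e-8) sign(sum(v)) else sign(v[2] - v[1])
    tapers[, j] <- v * s
  }
  tapers
}

# window start indices for a sliding analysis window
mt_window_starts <- function(n_time, win_n, step_n) {
  if (n_time < win_n) stop("signal shorter than the analysis window")
  seq(1L, n_time - win_n + 1L, by = step_n)
}

# Batched multitaper spectrogram of many equal-length signals.
# X: n_signals x n_time. Returns list(power = n_signals x n_pos x n_freq,
# t_center = center offsets in seconds from the first sample, freq).
mt_specgram_core <- function(X, fs, win_s = 0.25, step_s = 0.01, tw = 2,
                             k = 3, nfft = NULL, freq_range = c(1, 90)) {
  stopifnot(is.matrix(X), fs > 0)
  if (k > 2 * tw - 1) stop("number of tapers k must be <= 2*TW - 1")
  win_n <- round(win_s * fs)
  step_n <- max(1L, as.integer(round(step_s * fs)))
  starts <- mt_window_starts(ncol(X), win_n, step_n)
  nfft <- nfft %||% (2^ceiling(log2(max(win_n, fs)))) # df <= 1 Hz at 1 kHz
  freq_all <- (0:(nfft / 2)) * fs / nfft
  fidx <- which(freq_all >= freq_range[1] & freq_all <= freq_range[2])
  if (length(fidx) == 0L) stop("freq_range contains no FFT bins")
  tapers <- dpss_tapers(win_n, tw, k)
  n_sig <- nrow(X)
  power <- array(0, dim = c(n_sig, length(starts), length(fidx)))
  buf <- matrix(0, nfft, n_sig)
  for (p in seq_along(starts)) {
    seg <- t(X[, starts[p]:(starts[p] + win_n - 1L), drop = FALSE])
    acc <- matrix(0, length(fidx), n_sig)
    for (j in seq_len(k)) {
      buf[] <- 0
      buf[1:win_n, ] <- seg * tapers[, j]
      F <- stats::mvfft(buf)[fidx, , drop = FALSE]
      acc <- acc + Re(F * Conj(F))
    }
    power[, p, ] <- t(acc) * (2 / (k * fs)) # one-sided PSD, taper-averaged
  }
  list(
    power = power,
    t_center = (starts - 1 + (win_n - 1) / 2) / fs,
    freq = freq_all[fidx]
  )
}

#' Time-frequency map container
#'
#' @param time time grid (s), strictly increasing.
#' @param freq frequency grid (Hz), strictly increasing.
#' @param values `length(time) x length(freq)` matrix.
#' @param kind one of `"log_power"`, `"power"`, `"delta"`, `"coherence"`.
#' @param params list of estimation parameters recorded with the map.
#' @return object of class `tf_map`.
#' @export
tf_map <- function(time, freq, values, kind, params = list()) {
  stopifnot(all(diff(time) > 0), all(diff(freq) > 0),
            nrow(values) == length(time), ncol(values) == length(freq))
  structure(list(time = time, freq = freq, values = values,
                 kind = kind, params = params),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map '%s'> %d time bins [%.3f, %.3f] s x %d freq bins [%.1f, %.1f] Hz\n",
              x$kind, length(x$time), min(x$time), max(x$time),
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Multitaper spectrogram of a single signal
#'
#' Sliding-window power spectral density averaged over `k` Slepian tapers.
#' The value at time `t` uses the window centered on `t`; edge positions
#' where a full window does not fit are dropped. The frequency grid is a
#' zero-padded FFT grid restricted to `freq_range` (resolution <= 1 Hz at
#' the 1-kHz LFP rate).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param win_s window length (s); default 0.25.
#' @param step_s window step (s); rounded to >= 1 sample.
#' @param tw time-bandwidth product (default 2).
#' @param k number of tapers (default 3; requires `k <= 2*tw - 1`).
#' @param nfft FFT length (default: next power of two >= max(window, fs)).
#' @param freq_range frequencies to keep, Hz (default 1-90).
#' @param t0 time of the first sample of `x` (s), so map times can be
#'   expressed relative to an alignment event.
#' @return a [tf_map] of kind `"power"`.
#' @export
multitaper_spectrogram <- function(x, fs = 1000, win_s = 0.25, step_s = 0.0005,
                                   tw = 2, k = 3, nfft = NULL,
                                   freq_range = c(1, 90), t0 = 0) {
  stopifnot(is.numeric(x))
  core <- mt_specgram_core(matrix(x, nrow = 1), fs, win_s, step_s, tw, k,
                           nfft, freq_range)
  vals <- core$power[1, , , drop = FALSE]
  dim(vals) <- dim(vals)[2:3]
  tf_map(core$t_center + t0, core$freq, vals,
         kind = "power",
         params = list(win_s = win_s, step_s = step_s, tw = tw, k = k,
                       fs = fs, nfft = nfft %||% 2^ceiling(log2(max(round(win_s * fs), fs)))))
}
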