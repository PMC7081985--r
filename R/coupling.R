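# Inter-areal LFP-LFP coherence between FAF depths and striatal channels.
# Coherence is the magnitude of the coherency: the trial- and taper-averaged
# cross-spectral density normalized by the auto-spectra; no randomization
# averaging is used here (per-trial epochs enter directly).

#' Multitaper coherogram between two sets of aligned epochs
#'
#' `C(t, f) = |sum S_ab| / sqrt(sum S_aa * sum S_bb)` with cross- and
#' auto-spectra summed over trials and Slepian tapers in each sliding
#' window; values lie in \[0, 1\]. Requires at least 2 trials (coherence is
#' trivially 1 for a single trial).
#'
#' @param epochs_a,epochs_b trials x time matrices of simultaneously
#'   recorded, aligned epochs (equal dimensions, trial i of `a`
#'   simultaneous with trial i of `b`).
#' @param fs sampling rate (Hz).
#' @param win_s,step_s,tw,k multitaper parameters (as the spectral
#'   analysis: 0.25 s window, TW 2, K 3).
#' @param t0 time of the first sample (s rel. onset), e.g. -0.5.
#' @param freq_range frequencies kept (Hz).
#' @return a [tf_map] of kind `"coherence"` with attribute `n_trials`.
#' @export
coherogram <- function(epochs_a, epochs_b, fs = 1000, win_s = 0.25,
                       step_s = 0.01, tw = 2, k = 3, t0 = -0.5,
                       freq_range = c(1, 90)) {
  stopifnot(is.matrix(epochs_a), is.matrix(epochs_b),
            all(dim(epochs_a) == dim(epochs_b)))
  if (nrow(epochs_a) < 2) stop("coherence requires at least 2 trials")
  if (k > 2 * tw - 1) stop("number of tapers k must be <= 2*TW - 1")
  win_n <- round(win_s * fs)
  step_n <- max(1L, as.integer(round(step_s * fs)))
  starts <- mt_window_starts(ncol(epochs_a), win_n, step_n)
  nfft <- 2^ceiling(log2(max(win_n, fs)))
  freq_all <- (0:(nfft / 2)) * fs / nfft
  fidx <- which(freq_all >= freq_range[1] & freq_all <= freq_range[2])
  tapers <- dpss_tapers(win_n, tw, k)
  n_tr <- nrow(epochs_a)
  C <- matrix(0, length(starts), length(fidx))
  buf_a <- buf_b <- matrix(0, nfft, n_tr)
  for (p in seq_along(starts)) {
    ia <- starts[p]:(starts[p] + win_n - 1L)
    seg_a <- t(epochs_a[, ia, drop = FALSE])
    seg_b <- t(epochs_b[, ia, drop = FALSE])
    sab <- matrix(0 + 0i, length(fidx), 1)
    saa <- sbb <- matrix(0, length(fidx), 1)
    for (j in seq_len(k)) {
      buf_a[] <- 0; buf_a[1:win_n, ] <- seg_a * tapers[, j]
      buf_b[] <- 0; buf_b[1:win_n, ] <- seg_b * tapers[, j]
      Fa <- stats::mvfft(buf_a)[fidx, , drop = FALSE]
      Fb <- stats::mvfft(buf_b)[fidx, , drop = FALSE]
      sab <- sab + rowSums(Fa * Conj(Fb))
      saa <- saa + rowSums(Re(Fa * Conj(Fa)))
      sbb <- sbb + rowSums(Re(Fb * Conj(Fb)))
    }
    C[p, ] <- Mod(sab) / sqrt(saa * sbb)
  }
  map <- tf_map((starts - 1 + (win_n - 1) / 2) / fs + t0, freq_all[fidx],
                C, kind = "coherence",
                params = list(win_s = win_s, step_s = step_s, tw = tw, k = k,
                              fs = fs))
  attr(map, "n_trials") <- n_tr
  map
}

#' Average coherograms over CN channels
#'
#' Element-wise mean of the coherograms obtained between one FAF depth and
#' each striatal channel.
#'
#' @param maps non-empty list of [tf_map] objects (kind `"coherence"`)
#'   sharing grids.
#' @return a [tf_map] of kind `"coherence"`.
#' @export
average_over_cn <- function(maps) {
  if (length(maps) == 0L) stop("no coherograms to average")
  ref <- maps[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (m in maps) {
    if (!isTRUE(all.equal(m$freq, ref$freq)) ||
        !isTRUE(all.equal(m$time, ref$time))) {
      stop("coherograms must share grids")
    }
    acc <- acc + m$values
  }
  tf_map(ref$time, ref$freq, acc / length(maps), kind = "coherence",
         params = ref$params)
}

#' Percentile significance mask for coherence maps
#'
#' The threshold is the `pct` percentile of ALL coherence values pooled
#' over every map of one condition; bins strictly exceeding it are
#' significant (about `100 - pct` percent of bins by construction).
#'
#' @param maps list of [tf_map] objects (kind `"coherence"`) of one
#'   condition, or a single map.
#' @param pct percentile (default 95).
#' @return list with `threshold` and `masks` (list of logical matrices
#'   matching the maps). Constant maps give an empty mask with a warning.
#' @export
significance_mask <- function(maps, pct = 95) {
  if (inherits(maps, "tf_map")) maps <- list(maps)
  vals <- unlist(lapply(maps, function(m) as.numeric(m$values)))
  if (length(vals) == 0L) stop("no coherence values pooled")
  thr <- stats::quantile(vals, pct / 100, names = FALSE)
  masks <- lapply(maps, function(m) m$values > thr)
  if (!any(unlist(masks))) {
    warning("no bin exceeds the percentile threshold (constant maps?)")
  }
  list(threshold = thr, masks = masks, pct = pct)
}

#' Band-averaged coherence across depths
#'
#' Mean coherence over the band's frequency bins, per FAF depth and time
#' bin; rows ordered by depth.
#'
#' @param maps list of depth-wise [tf_map] objects (kind `"coherence"`)
#'   sharing grids.
#' @param band band name or `c(low, high)` Hz (theta and alpha in the
#'   depth profiles).
#' @param depths_um per-map depth (um).
#' @return list with `profile` (depth x time), `time`, `depths_um`.
#' @export
band_coherence_profile <- function(maps, band, depths_um = seq_along(maps)) {
  band_depth_profile(maps, band, depths_um)
}
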