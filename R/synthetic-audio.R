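# Synthetic vocalization audio: two spectro-temporal templates (short
# downward-FM echolocation pulse peaking ~72 kHz; longer low-frequency
# communication call peaking ~14 kHz) plus an LHF communication variant
# carrying an additional component above 50 kHz.

# fractional half-span of the downward FM sweep around the peak frequency
FM_SWEEP_FRAC <- 0.11
# fixed carrier of the LHF high-frequency component (kHz)
LHF_COMPONENT_KHZ <- 60

#' Specification of one synthetic call class
#'
#' @param class_label `"echolocation"` or `"communication"`.
#' @param subclass `"LF"`, `"LHF"` or `"none"`.
#' @param duration_ms call duration (ms), `> 0`.
#' @param peak_freq_khz spectral peak (kHz). Echolocation requires `> 50`,
#'   communication `< 50`.
#' @param fm_sweep `"down"` (linear downward sweep of +-11% around the
#'   peak) or `"none"`.
#' @param hf_component_gain amplitude of the additional >50 kHz component
#'   relative to the main component; `> 0` only for LHF.
#' @return validated list of class `call_class_spec`.
#' @export
call_class_spec <- function(class_label = c("echolocation", "communication"),
                            subclass = c("none", "LF", "LHF"),
                            duration_ms, peak_freq_khz,
                            fm_sweep = c("none", "down"),
                            hf_component_gain = 0) {
  class_label <- match.arg(class_label)
  subclass <- match.arg(subclass)
  fm_sweep <- match.arg(fm_sweep)
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    stop("duration_ms must be a positive number")
  }
  stopifnot(peak_freq_khz > 0, hf_component_gain >= 0)
  if (class_label == "echolocation") {
    if (peak_freq_khz <= 50) stop("echolocation spec requires peak_freq_khz > 50")
    if (subclass != "none") stop("echolocation has no LF/LHF subclass")
  } else {
    if (peak_freq_khz >= 50) stop("communication spec requires peak_freq_khz < 50")
    if (subclass == "LF" && hf_component_gain != 0) {
      stop("LF spec requires hf_component_gain = 0")
    }
    if (subclass == "LHF" && hf_component_gain <= 0) {
      stop("LHF spec requires hf_component_gain > 0")
    }
  }
  structure(list(class_label = class_label, subclass = subclass,
                 duration_ms = duration_ms, peak_freq_khz = peak_freq_khz,
                 fm_sweep = fm_sweep, hf_component_gain = hf_component_gain),
            class = "call_class_spec")
}

#' Default call templates
#'
#' Echolocation: 1 ms, downward FM, peak 72 kHz. Communication: 5 ms,
#' peak 14 kHz; the LHF variant adds a 60-kHz component (relative
#' amplitude 0.9, comfortably above the LHF half-power rule).
#'
#' @param subclass for `communication_spec`, `"LF"` or `"LHF"`.
#' @return a [call_class_spec].
#' @export
echolocation_spec <- function() {
  call_class_spec("echolocation", "none", duration_ms = 1,
                  peak_freq_khz = 72, fm_sweep = "down")
}

#' @rdname echolocation_spec
#' @export
communication_spec <- function(subclass = c("LF", "LHF")) {
  subclass <- match.arg(subclass)
  call_class_spec("communication", subclass, duration_ms = 5,
                  peak_freq_khz = 14, fm_sweep = "none",
                  hf_component_gain = if (subclass == "LHF") 0.9 else 0)
}

# Hann-enveloped call waveform (no padding/noise), peak amplitude amp
synth_call_samples <- function(spec, fs, amp = 0.9) {
  n <- max(2L, round(spec$duration_ms / 1000 * fs))
  tt <- (seq_len(n) - 1) / fs
  f0 <- spec$peak_freq_khz * 1000
  if (spec$fm_sweep == "down") {
    finst <- seq(f0 * (1 + FM_SWEEP_FRAC), f0 * (1 - FM_SWEEP_FRAC),
                 length.out = n)
  } else {
    finst <- rep(f0, n)
  }
  phase <- 2 * pi * cumsum(finst) / fs
  w <- cos(phase)
  if (spec$hf_component_gain > 0) {
    w <- w + spec$hf_component_gain * cos(2 * pi * LHF_COMPONENT_KHZ * 1000 * tt)
  }
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # Hann taper
  w <- w * env
  w / max(abs(w)) * amp
}

#' Synthesize one isolated call embedded in low-level noise
#'
#' The call is a cosine-tapered tone or downward FM sweep, padded on both
#' sides with `pad_s` of background noise and normalized to \[-1, 1\].
#'
#' @param spec a [call_class_spec].
#' @param rng_seed integer seed (noise is the only stochastic component).
#' @param fs audio sampling rate (Hz); must be at least 2.5x the highest
#'   instantaneous call frequency.
#' @param noise_level standard deviation of the background noise relative
#'   to the call peak amplitude (0.9).
#' @param pad_s silence/noise padding on each side (s).
#' @return list with `waveform`, `fs`, and `event` (one-row data.frame:
#'   onset_s, offset_s, duration_ms, peak_freq_khz, class, subclass).
#' @export
generate_call_audio <- function(spec, rng_seed = 1, fs = 250000,
                                noise_level = 1e-3, pad_s = 0.005) {
  stopifnot(inherits(spec, "call_class_spec"))
  f_max <- spec$peak_freq_khz * 1000 *
    (if (spec$fm_sweep == "down") 1 + FM_SWEEP_FRAC else 1)
  f_max <- max(f_max, if (spec$hf_component_gain > 0) LHF_COMPONENT_KHZ * 1000 else 0)
  if (fs < 2.5 * f_max) {
    stop(sprintf("peak frequency %.1f kHz too close to Nyquist: need fs >= %.0f Hz",
                 f_max / 1000, 2.5 * f_max))
  }
  call <- synth_call_samples(spec, fs)
  n_pad <- round(pad_s * fs)
  wav <- with_seed(rng_seed,
                   stats::rnorm(2L * n_pad + length(call), sd = noise_level))
  idx <- n_pad + seq_along(call)
  wav[idx] <- wav[idx] + call
  wav <- wav / max(abs(wav))
  event <- data.frame(
    onset_s = n_pad / fs,
    offset_s = (n_pad + length(call)) / fs,
    duration_ms = spec$duration_ms,
    peak_freq_khz = spec$peak_freq_khz,
    class = spec$class_label,
    subclass = spec$subclass,
    stringsAsFactors = FALSE
  )
  list(waveform = wav, fs = fs, event = event)
}
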