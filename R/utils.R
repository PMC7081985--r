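#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns `x + i * H(x)` where `H` is the Hilbert transform, computed by
#' zeroing negative frequencies of the FFT. Instantaneous amplitude is
#' `Mod(analytic_signal(x))`, instantaneous phase `Arg(analytic_signal(x))`
#' (cosine convention: a cosine has phase 0 at its peaks).
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unwrap a phase series: remove 2*pi jumps so the series is continuous
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

# nearest sample index of time t on an axis starting at t0 with rate fs
time_to_index <- function(t, t0, fs) as.integer(round((t - t0) * fs)) + 1L

stop_if_not_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite samples in %s", what))
}
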