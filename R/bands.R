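#' Standard LFP frequency bands
#'
#' The six non-overlapping bands used throughout the analyses:
#' theta 4-8 Hz, alpha 8-12 Hz, low beta 12-20 Hz, high beta 20-30 Hz,
#' low gamma 30-50 Hz, high gamma 50-80 Hz.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
lfp_bands <- function() {
  data.frame(
    name    = c("theta", "alpha", "low_beta", "high_beta", "low_gamma", "high_gamma"),
    low_hz  = c(4, 8, 12, 20, 30, 50),
    high_hz = c(8, 12, 20, 30, 50, 80),
    stringsAsFactors = FALSE
  )
}

# resolve a band given as a name or c(low, high) into c(low, high), validated
resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1L) {
    tab <- lfp_bands()
    i <- match(band, tab$name)
    if (is.na(i)) stop(sprintf("unknown band '%s'", band))
    band <- c(tab$low_hz[i], tab$high_hz[i])
  }
  stopifnot(is.numeric(band), length(band) == 2L)
  if (!(band[1] >= 1 && band[1] < band[2] && band[2] <= 90)) {
    stop("band must satisfy 1 <= low < high <= 90 Hz")
  }
  band
}

# indices of frequency-grid points inside [low, high]; error if none
band_bins <- function(freq, band) {
  band <- resolve_band(band)
  idx <- which(freq >= band[1] & freq <= band[2])
  if (length(idx) == 0L) stop("band contains no frequency bins of the grid")
  idx
}
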