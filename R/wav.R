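# Minimal mono PCM-16 WAV I/O. High-rate (250 kHz) acoustic recordings use
# plain PCM; only the canonical 44-byte header layout is written/accepted.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param x numeric vector in \[-1, 1\] (clipped otherwise).
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @export
write_wav <- function(x, path, fs) {
  stopifnot(is.numeric(x), fs > 0)
  x <- pmin(1, pmax(-1, x))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return list with `x` (numeric in \[-1, 1\]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4) stop("malformed WAV: missing data chunk")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM WAV supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- {
        invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
        invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
        readBin(con, "integer", 1, size = 2, endian = "little")
      }
      if (bits != 16L) stop("only 16-bit PCM WAV supported")
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2L, size = 2, endian = "little")
      return(list(x = pcm / 32767, fs = fs))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
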