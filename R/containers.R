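# Core data containers shared across the pipeline.

#' Multichannel extracellular recording
#'
#' @param traces numeric matrix, channels x samples.
#' @param fs sampling rate (Hz).
#' @param channel_meta data.frame with one row per channel and columns
#'   `structure` (`"FAF"` or `"CN"`) and `depth_um`; depths must be unique
#'   within a structure.
#' @return object of class `neural_recording`.
#' @export
neural_recording <- function(traces, fs, channel_meta) {
  stopifnot(is.matrix(traces), fs > 0,
            nrow(channel_meta) == nrow(traces),
            all(channel_meta$structure %in% c("FAF", "CN")))
  for (s in unique(channel_meta$structure)) {
    d <- channel_meta$depth_um[channel_meta$structure == s]
    if (anyDuplicated(d)) stop("duplicate depths within structure ", s)
  }
  structure(list(traces = traces, fs = fs, channel_meta = channel_meta),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d channels (%d FAF, %d CN) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$traces), sum(x$channel_meta$structure == "FAF"),
              sum(x$channel_meta$structure == "CN"), ncol(x$traces),
              x$fs, ncol(x$traces) / x$fs))
  invisible(x)
}

#' Event-aligned LFP epochs
#'
#' Trials x channels x time array of z-scored LFP aligned to call onset,
#' default window \[-0.5, +0.5\] s at 1 kHz (1001 samples, sample 501 = onset).
#'
#' @param data trials x channels x time array.
#' @param fs sampling rate (Hz).
#' @param window two-element window relative to onset (s).
#' @param labels data.frame with one row per trial (columns `class`,
#'   `subclass`, `onset_s`, ...).
#' @param channel_meta as in [neural_recording()].
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, window = c(-0.5, 0.5), labels, channel_meta) {
  stopifnot(length(dim(data)) == 3)
  n_time <- round((window[2] - window[1]) * fs) + 1L
  if (dim(data)[3] != n_time) stop("time axis length must equal window * fs + 1")
  if (nrow(labels) != dim(data)[1]) stop("labels must have one row per trial")
  structure(list(data = data, fs = fs, window = window,
                 time = seq(window[1], window[2], by = 1 / fs),
                 labels = labels, channel_meta = channel_meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, window [%g, %g] s @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2], x$fs))
  if (nrow(x$labels)) print(table(x$labels$class))
  invisible(x)
}

# number of trials of one condition in an epoch_set
n_condition_trials <- function(epochs, condition) {
  sum(epochs$labels$class == condition)
}

#' Write / read a call-event table as CSV
#'
#' Columns: onset_s, offset_s, duration_ms, peak_freq_khz, class, subclass,
#' isolated, contaminated_post.
#'
#' @param events data.frame of call events.
#' @param path CSV path.
#' @return `read_events` returns the data.frame with logical flags restored.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("isolated", "contaminated_post")) {
    if (col %in% names(ev)) ev[[col]] <- as.logical(ev[[col]])
  }
  ev
}
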