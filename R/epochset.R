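#' Epoched trial container
#'
#' An `epoch_set` holds a `trials x channels x time` numeric array of epoched
#' neural (or simulated) signals together with per-trial condition labels,
#' per-channel region tags, the sampling rate and the epoch window. It is the
#' common currency of the package: generators produce it, the preprocessing
#' steps transform it, and the information-theoretic analyses consume it.
#'
#' The analysis-ready convention is a half-open window `[-100, 350)` ms around
#' stimulus onset. At 500 Hz this gives 225 samples with onset at sample 51
#' (1-based); at the simulator's 100 Hz rate it gives 45 samples.
#'
#' @param data numeric array `[trial, channel, time]`.
#' @param fs sampling rate in Hz.
#' @param window length-2 numeric, `(start_ms, end_ms)` relative to onset;
#'   half-open `[start, end)`.
#' @param labels character or factor of length `n_trials`, values
#'   `"standard"`/`"deviant"`.
#' @param regions character of length `n_channels`, values in
#'   `{"temporal","frontal","other"}`.
#' @param signal_kind one of `"raw"`, `"erp"`, `"bb"`, `"rate"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, window, labels,
                      regions = rep("other", dim(data)[2]),
                      signal_kind = c("raw", "erp", "bb", "rate")) {
  signal_kind <- match.arg(signal_kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trial, channel, time]")
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("`data` must contain only finite values")
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1L])
    stop("`labels` length must equal the number of trials")
  if (!all(labels %in% c("standard", "deviant")))
    stop("`labels` must be 'standard' or 'deviant'")
  regions <- as.character(regions)
  if (length(regions) != dim(data)[2L])
    stop("`regions` length must equal the number of channels")
  if (!all(regions %in% c("temporal", "frontal", "other")))
    stop("`regions` must be 'temporal', 'frontal' or 'other'")
  stopifnot(is.numeric(fs), fs > 0, length(window) == 2L, window[1] < window[2])
  n_time <- dim(data)[3L]
  expected <- round((window[2] - window[1]) / 1000 * fs)
  if (expected != n_time)
    stop(sprintf("window %g..%g ms at %g Hz implies %d samples, data has %d",
                 window[1], window[2], fs, expected, n_time))
  structure(list(data = data, fs = fs, window = as.numeric(window),
                 labels = labels, regions = regions,
                 signal_kind = signal_kind),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%s)\n",
              d[1], d[2], d[3], x$signal_kind))
  cat(sprintf("  fs %g Hz, window [%g, %g) ms; labels: %s\n",
              x$fs, x$window[1], x$window[2],
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Sample times of an epoch_set
#'
#' @param x an `epoch_set`.
#' @return Numeric vector of sample times in ms (left edge of each sample).
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  n <- dim(x$data)[3L]
  x$window[1] + (seq_len(n) - 1) * 1000 / x$fs
}

#' Subset an epoch_set by trials and/or channels
#'
#' @param x an `epoch_set`.
#' @param trials,channels integer or logical indices (default: keep all).
#' @return A new `epoch_set`.
#' @export
epoch_subset <- function(x, trials = NULL, channels = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  tr <- trials %||% seq_len(dim(x$data)[1L])
  ch <- channels %||% seq_len(dim(x$data)[2L])
  epoch_set(x$data[tr, ch, , drop = FALSE], x$fs, x$window,
            x$labels[tr], x$regions[ch], x$signal_kind)
}

#' Write / read an epoch_set as plain text
#'
#' Serializes the trial array in long CSV form (`trial,channel,time,value`)
#' with a JSON sidecar (`<base>.json`) carrying sampling rate, window, labels,
#' regions and signal kind.
#'
#' @param x an `epoch_set`.
#' @param base path prefix; files `<base>.csv` and `<base>.json` are written.
#' @return `write_epochset` returns `base` invisibly; `read_epochset` returns
#'   the reconstructed `epoch_set`.
#' @export
write_epochset <- function(x, base) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  df <- data.frame(
    trial   = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time    = rep(seq_len(d[3]), each = d[1] * d[2]),
    value   = as.vector(x$data))
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  meta <- list(fs = x$fs, window = x$window, labels = x$labels,
               regions = x$regions, signal_kind = x$signal_kind, dim = d)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_epochset
#' @export
read_epochset <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(base, ".csv"))
  d <- as.integer(meta$dim)
  arr <- array(0, d)
  arr[cbind(df$trial, df$channel, df$time)] <- df$value
  epoch_set(arr, meta$fs, meta$window, meta$labels, meta$regions,
            meta$signal_kind)
}
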