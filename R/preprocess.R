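#' Epoching and temporal filtering
#'
#' Epochs are cut relative to block markers: each epoch is 8 s long and
#' begins 2 s after its marker (both configurable). Temporal filtering is a
#' 6th-order Butterworth low-pass with 0.6 Hz cutoff, applied zero-phase
#' (forward-backward) by default on the continuous concentration series
#' before epoching; the literal post-epoching order is available via the
#' `stage` argument of the pipeline functions.
#'
#' @name preprocess
NULL

#' Marker-based epoching of a hemoglobin series
#'
#' One epoch per event marker whose window
#' `[onset + offset, onset + offset + duration)` lies fully inside the
#' record; markers whose window would run past either end are dropped (and
#' counted), never truncated. Sample indices use round-half-even on
#' `time x rate`.
#'
#' @param series a `hemo_series`.
#' @param offset epoch start relative to the marker, in s (default 2).
#' @param duration epoch length in s (default 8).
#' @return An `epoch_set`: list with `data` (array epoch x sample x
#'   channel x chromophore), `labels`, `onsets` (absolute epoch starts, s),
#'   `channels` (channel table), `sampling_rate`, `class_counts`,
#'   `n_dropped`.
#' @export
epoch_series <- function(series, offset = 2, duration = 8) {
  stopifnot(inherits(series, "hemo_series"))
  if (offset <= 0 || duration <= 0) abort_ns("offset and duration must be positive")
  ev <- series$events
  if (is.null(ev) || nrow(ev) == 0L) abort_ns("no event markers in series")
  rate <- series$sampling_rate
  n_samp <- round(duration * rate)
  n_total <- nrow(series$hbo)
  t0 <- series$time[1]
  keep <- logical(nrow(ev))
  starts <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    start_idx <- round((ev$onset[i] + offset - t0) * rate) + 1L
    starts[i] <- start_idx
    keep[i] <- start_idx >= 1L && (start_idx + n_samp - 1L) <= n_total
  }
  n_dropped <- sum(!keep)
  if (!any(keep)) abort_ns("no usable markers: every epoch window falls outside the record")
  if (n_dropped > 0) {
    warning(sprintf("dropped %d marker(s) whose epoch window exceeds the record", n_dropped))
  }
  ev <- ev[keep, , drop = FALSE]
  starts <- starts[keep]
  ids <- colnames(series$hbo)
  dat <- array(
    NA_real_,
    dim = c(nrow(ev), n_samp, length(ids), 2L),
    dimnames = list(NULL, NULL, ids, c("hbo", "hbr"))
  )
  for (i in seq_len(nrow(ev))) {
    idx <- starts[i]:(starts[i] + n_samp - 1L)
    dat[i, , , "hbo"] <- series$hbo[idx, , drop = FALSE]
    dat[i, , , "hbr"] <- series$hbr[idx, , drop = FALSE]
  }
  labels <- ev$label
  structure(
    list(
      data = dat, labels = labels,
      onsets = ev$onset + offset,
      channels = series$montage$channels,
      sampling_rate = rate,
      class_counts = table(labels),
      n_dropped = n_dropped
    ),
    class = "epoch_set"
  )
}

# forward-backward filtering with odd-reflection end padding, so that
# startup transients decay inside the pad instead of contaminating the
# series (plain zero-state filtering distorts any trace with a nonzero
# mean at its edges)
reflect_filtfilt <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 250L)
  head_pad <- 2 * x[1] - x[(pad + 1L):2]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, ext)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# design and apply a zero-phase Butterworth low-pass to the columns of a matrix
butter_lowpass_mat <- function(x, rate, order, cutoff) {
  if (cutoff >= rate / 2) {
    abort_ns(sprintf(
      "cutoff %g Hz is at or above the Nyquist frequency %g Hz", cutoff, rate / 2
    ))
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  apply(x, 2L, function(col) reflect_filtfilt(bf, col))
}

#' Low-pass filter a hemoglobin series or epoch set
#'
#' Applies a Butterworth low-pass (default 6th order, 0.6 Hz) zero-phase
#' (forward-backward, with odd-reflection end padding) to every channel and
#' chromophore trace independently. The single-pass magnitude response is
#' `|H(f)|^2 = 1 / (1 + (f / cutoff)^(2 * order))`; zero-phase application
#' squares it.
#'
#' @param x a `hemo_series` or `epoch_set`.
#' @param order filter order (default 6).
#' @param cutoff high-cut frequency in Hz (default 0.6).
#' @return An object of the same class with filtered traces.
#' @export
lowpass <- function(x, order = 6, cutoff = 0.6) UseMethod("lowpass")

#' @export
lowpass.hemo_series <- function(x, order = 6, cutoff = 0.6) {
  x$hbo <- butter_lowpass_mat(x$hbo, x$sampling_rate, order, cutoff)
  x$hbr <- butter_lowpass_mat(x$hbr, x$sampling_rate, order, cutoff)
  x
}

#' @export
lowpass.epoch_set <- function(x, order = 6, cutoff = 0.6) {
  d <- x$data
  for (i in seq_len(dim(d)[1])) {
    for (c in c("hbo", "hbr")) {
      d[i, , , c] <- butter_lowpass_mat(
        d[i, , , c, drop = TRUE], x$sampling_rate, order, cutoff
      )
    }
  }
  x$data <- d
  x
}

#' Analytic Butterworth magnitude response
#'
#' `|H(f)| = (1 + (f/cutoff)^(2*order))^(-1/2)`, squared when the filter is
#' applied forward-backward (`passes = 2`, the pipeline default).
#'
#' @param f frequency in Hz.
#' @param order filter order.
#' @param cutoff cutoff in Hz.
#' @param passes 1 for single-pass, 2 for zero-phase application.
#' @export
butterworth_gain <- function(f, order = 6, cutoff = 0.6, passes = 2) {
  (1 / sqrt(1 + (f / cutoff)^(2 * order)))^passes
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d samples x %d channels x 2 chromophores at %g Hz\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate
  ))
  cc <- x$class_counts
  cat(
    "  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "),
    sprintf("(%d marker(s) dropped)\n", x$n_dropped)
  )
  invisible(x)
}

#' Write an epoch set as a single long-format TSV
#'
#' Columns: `epoch`, `label`, `time_s` (within-epoch), `channel`,
#' `chromophore`, `value_um`. Round-trips through [read_epochs()].
#'
#' @param epochs an `epoch_set`.
#' @param path output path.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  grid <- expand.grid(
    sample = seq_len(d[2]), channel = dimnames(epochs$data)[[3]],
    chromophore = c("hbo", "hbr"), epoch = seq_len(d[1]),
    stringsAsFactors = FALSE
  )
  out <- data.frame(
    epoch = grid$epoch,
    label = epochs$labels[grid$epoch],
    time_s = (grid$sample - 1L) / epochs$sampling_rate,
    channel = grid$channel,
    chromophore = grid$chromophore,
    value_um = epochs$data[cbind(grid$epoch, grid$sample,
      match(grid$channel, dimnames(epochs$data)[[3]]),
      match(grid$chromophore, c("hbo", "hbr"))
    )]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' Onsets and the channel table are not stored in the long format; the
#' result carries the epoch data, labels and sampling rate (inferred from
#' the time grid), which is all feature extraction needs.
#'
#' @param path input path.
#' @export
read_epochs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  epochs <- sort(unique(df$epoch))
  times <- sort(unique(df$time_s))
  channels <- unique(df$channel)
  rate <- 1 / stats::median(diff(times))
  dat <- array(
    NA_real_,
    dim = c(length(epochs), length(times), length(channels), 2L),
    dimnames = list(NULL, NULL, channels, c("hbo", "hbr"))
  )
  dat[cbind(
    match(df$epoch, epochs), match(df$time_s, times),
    match(df$channel, channels), match(df$chromophore, c("hbo", "hbr"))
  )] <- df$value_um
  labels <- df$label[!duplicated(df$epoch)][order(unique(df$epoch))]
  structure(
    list(
      data = dat, labels = labels, onsets = NULL,
      channels = data.frame(
        id = channels, kind = "long", stringsAsFactors = FALSE
      ),
      sampling_rate = rate, class_counts = table(labels), n_dropped = 0L
    ),
    class = "epoch_set"
  )
}
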