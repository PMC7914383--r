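#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) to every channel, so the filter introduces no phase
#' shift. Length, channel labels and event markers are unchanged.
#'
#' @param recording An `erp_recording`.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < Nyquist`.
#' @param order Butterworth order (default 4).
#' @return The filtered `erp_recording`.
#' @export
bandpass_filter <- function(recording, low = 0.3, high = 30, order = 4) {
  stopifnot(inherits(recording, "erp_recording"))
  ny <- recording$sampling_rate / 2
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && low < high &&
        high < ny)) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", ny, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  out <- recording
  # zero-phase forward-backward pass, all channels at once (C++ kernel)
  out$data <- .filtfilt_mat(recording$data, bf$b / bf$a[1], bf$a / bf$a[1])
  rownames(out$data) <- recording$channel_labels
  out
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts, sample by sample, the mean of the named reference channels
#' (typically the two auricular electrodes) from every channel.
#'
#' @param recording An `erp_recording`.
#' @param reference_channels Character vector of channel labels present in the
#'   recording.
#' @return The re-referenced `erp_recording`.
#' @export
rereference <- function(recording, reference_channels) {
  stopifnot(inherits(recording, "erp_recording"))
  missing_ch <- setdiff(reference_channels, recording$channel_labels)
  if (length(missing_ch)) {
    stop("missing reference channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  ref <- colMeans(recording$data[reference_channels, , drop = FALSE])
  out <- recording
  out$data <- sweep(recording$data, 2, ref, `-`)
  out
}

#' Segment a recording into per-condition analysis windows
#'
#' Extracts, for every event, the analysis window `[start_ms, end_ms)` (half
#' open, relative to event onset) and decimates it by keeping every
#' `decimate`-th sample. At 500 Hz with the default 2500--3000 ms window and
#' decimation 2 this yields epochs of L = 125 samples at an effective 250 Hz.
#'
#' @param recording An `erp_recording`.
#' @param window_ms Numeric length-2: window start and end in ms after onset.
#' @param decimate Integer decimation factor (>= 1). The preceding low-pass
#'   (30 Hz) makes plain sample picking alias-free.
#' @param conditions Condition names expected in the event table; conditions
#'   without events yield empty stacks and a warning.
#' @return An object of class `erp_epochs`: per-condition arrays of
#'   `epochs x channels x L`, the window definition, effective sampling rate
#'   and the source event indices (`provenance`).
#' @export
segment_epochs <- function(recording, window_ms = c(2500, 3000), decimate = 2L,
                           conditions = c("hand", "ball", "none")) {
  stopifnot(inherits(recording, "erp_recording"))
  fs <- recording$sampling_rate
  start_off <- round(window_ms[1] / 1000 * fs)
  end_off <- round(window_ms[2] / 1000 * fs)
  raw_len <- end_off - start_off
  if (raw_len < 1) stop("empty analysis window", call. = FALSE)
  ev <- recording$events
  last_needed <- ev$onset_sample + start_off + raw_len - 1L
  bad <- which(last_needed > ncol(recording$data))
  if (length(bad)) {
    stop("analysis window exceeds recording end for event(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- seq.int(1L, raw_len, by = decimate)
  L <- length(keep)
  n_ch <- nrow(recording$data)
  data <- list()
  provenance <- list()
  for (cond in conditions) {
    rows <- which(ev$condition == cond)
    arr <- array(NA_real_, dim = c(length(rows), n_ch, L))
    for (j in seq_along(rows)) {
      idx <- ev$onset_sample[rows[j]] + start_off + keep - 1L
      arr[j, , ] <- recording$data[, idx]
    }
    data[[cond]] <- arr
    provenance[[cond]] <- rows
  }
  empty <- conditions[vapply(provenance, length, integer(1)) == 0L]
  if (length(empty)) {
    warning("no events for condition(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  structure(
    list(data = data, channel_labels = recording$channel_labels,
         window_ms = window_ms, sampling_rate = fs / decimate,
         decimate = as.integer(decimate), provenance = provenance,
         empty_conditions = empty),
    class = "erp_epochs"
  )
}

#' Reject epochs exceeding an amplitude threshold on frontal channels
#'
#' Drops every epoch whose absolute amplitude strictly exceeds `threshold`
#' microvolts at any sample of any frontal channel (ocular artifact
#' surrogate). Boundary values (`|x| == threshold`) survive. Surviving epochs
#' are returned untouched.
#'
#' @param epochs An `erp_epochs`.
#' @param frontal_channels Channel labels scanned for excursions; must be
#'   present in the epoch collection.
#' @param threshold Positive amplitude threshold in microvolts (default 50).
#' @return A list with `epochs` (pruned collection) and `report` (an
#'   `erp_artifact_report`: data frame of rejected epochs with condition,
#'   source event index, peak amplitude and reason, plus per-condition
#'   surviving counts).
#' @export
reject_artifacts <- function(epochs, frontal_channels, threshold = 50) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  f_idx <- match(frontal_channels, epochs$channel_labels)
  if (anyNA(f_idx)) {
    stop("missing frontal channel(s): ",
         paste(frontal_channels[is.na(f_idx)], collapse = ", "),
         call. = FALSE)
  }
  out <- epochs
  rej <- list()
  for (cond in names(epochs$data)) {
    arr <- epochs$data[[cond]]
    if (dim(arr)[1] == 0L) next
    peak <- apply(abs(arr[, f_idx, , drop = FALSE]), 1, max)
    drop <- which(peak > threshold)
    if (length(drop)) {
      rej[[cond]] <- data.frame(
        condition = cond,
        event_index = epochs$provenance[[cond]][drop],
        peak_amplitude = peak[drop],
        reason = "amplitude_threshold",
        stringsAsFactors = FALSE)
      keep <- setdiff(seq_len(dim(arr)[1]), drop)
      out$data[[cond]] <- arr[keep, , , drop = FALSE]
      out$provenance[[cond]] <- epochs$provenance[[cond]][keep]
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(condition = character(0), event_index = integer(0),
               peak_amplitude = numeric(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(rejected) <- NULL
  report <- structure(
    list(rejected = rejected,
         n_surviving = vapply(out$data, function(a) dim(a)[1], integer(1)),
         threshold = threshold),
    class = "erp_artifact_report")
  list(epochs = out, report = report)
}

#' Exclude epochs by source event index
#'
#' Generic exclusion hook (e.g. trials with detected hand movement on EMG
#' monitoring): removes the epochs whose source event indices are listed.
#'
#' @param epochs An `erp_epochs`.
#' @param indices Integer event indices (as in `epochs$provenance`).
#' @return The pruned `erp_epochs`.
#' @export
exclude_epochs <- function(epochs, indices) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (!length(indices)) return(epochs)
  indices <- as.integer(indices)
  known <- unlist(epochs$provenance, use.names = FALSE)
  bad <- setdiff(indices, known)
  if (length(bad)) {
    stop("unknown epoch indice(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- epochs
  for (cond in names(epochs$data)) {
    keep <- which(!(epochs$provenance[[cond]] %in% indices))
    out$data[[cond]] <- epochs$data[[cond]][keep, , , drop = FALSE]
    out$provenance[[cond]] <- epochs$provenance[[cond]][keep]
  }
  out$empty_conditions <- names(out$data)[
    vapply(out$provenance, length, integer(1)) == 0L]
  out
}

#' @export
print.erp_epochs <- function(x, ...) {
  counts <- vapply(x$data, function(a) dim(a)[1], integer(1))
  cat(sprintf("<erp_epochs> window [%g, %g) ms, L=%d @ %g Hz\n",
              x$window_ms[1], x$window_ms[2], dim(x$data[[1]])[3],
              x$sampling_rate))
  cat("  epochs:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.erp_artifact_report <- function(x, ...) {
  cat(sprintf("<erp_artifact_report> threshold +/-%g uV, %d rejected\n",
              x$threshold, nrow(x$rejected)))
  cat("  surviving:", paste(sprintf("%s=%d", names(x$n_surviving),
                                    x$n_surviving), collapse = ", "), "\n")
  invisible(x)
}
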