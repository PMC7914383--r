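#' Continuous multichannel recording
#'
#' Container for a continuous EEG recording: a channels-by-samples matrix in
#' microvolts, channel labels, the sampling rate, and an event table giving
#' the onset sample (1-based) and condition of every trial.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channel_labels Character vector, one unique label per row of `data`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param events Data frame with columns `onset_sample` (1-based integer) and
#'   `condition` (character).
#' @return An object of class `erp_recording`.
#' @export
recording <- function(data, channel_labels, sampling_rate, events) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must match the number of data rows", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("invalid `sampling_rate`: must be a single positive number",
         call. = FALSE)
  }
  if (!is.data.frame(events) ||
      !all(c("onset_sample", "condition") %in% names(events))) {
    stop("`events` must have columns onset_sample and condition",
         call. = FALSE)
  }
  if (nrow(events) > 0 &&
      (any(events$onset_sample < 1) ||
       any(events$onset_sample > ncol(data)))) {
    stop("event onsets must lie within the recording", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data,
         channel_labels = as.character(channel_labels),
         sampling_rate = sampling_rate,
         events = data.frame(onset_sample = as.integer(events$onset_sample),
                             condition = as.character(events$condition),
                             stringsAsFactors = FALSE)),
    class = "erp_recording"
  )
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<erp_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events)))
  if (nrow(x$events)) {
    tb <- table(x$events$condition)
    cat("  events:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}
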