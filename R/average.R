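#' Average epochs per condition for one electrode set
#'
#' Computes, for each of the four electrodes of a set and each condition, the
#' arithmetic mean waveform over the surviving epochs: the 12 averaged signals
#' that are the objects of the clustering stage. Unequal per-condition epoch
#' counts (after artifact rejection) are permitted and recorded.
#'
#' @param epochs An `erp_epochs`.
#' @param channels Character vector of exactly 4 electrode labels.
#' @param set_name Name of the electrode set (metadata).
#' @param region,hemisphere Optional set tags carried into the result.
#' @return An object of class `erp_averages`: `waveforms` is a 12 x L matrix
#'   (rows ordered condition-major), `meta` a data frame with `electrode` and
#'   `condition` per row, `n_epochs` the per-condition epoch counts.
#' @export
average_conditions <- function(epochs, channels, set_name = "set",
                               region = NA_character_,
                               hemisphere = NA_character_) {
  stopifnot(inherits(epochs, "erp_epochs"))
  ch_idx <- match(channels, epochs$channel_labels)
  if (anyNA(ch_idx)) {
    stop("unknown electrode(s): ",
         paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
  }
  conds <- names(epochs$data)
  n_ep <- vapply(epochs$data, function(a) dim(a)[1], integer(1))
  if (any(n_ep == 0L)) {
    stop("no surviving epochs for condition(s) ",
         paste(conds[n_ep == 0L], collapse = ", "),
         " in electrode set '", set_name, "'", call. = FALSE)
  }
  L <- dim(epochs$data[[1]])[3]
  meta <- expand.grid(electrode = channels, condition = conds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wf <- matrix(NA_real_, nrow = nrow(meta), ncol = L)
  for (r in seq_len(nrow(meta))) {
    arr <- epochs$data[[meta$condition[r]]]
    ei <- ch_idx[match(meta$electrode[r], channels)]
    m <- matrix(arr[, ei, ], nrow = dim(arr)[1])  # epochs x L
    wf[r, ] <- colMeans(m)
  }
  rownames(wf) <- paste(meta$electrode, meta$condition, sep = ".")
  structure(
    list(set_name = set_name, region = region, hemisphere = hemisphere,
         waveforms = wf, meta = meta, n_epochs = n_ep,
         sampling_rate = epochs$sampling_rate, window_ms = epochs$window_ms),
    class = "erp_averages"
  )
}

#' @export
print.erp_averages <- function(x, ...) {
  cat(sprintf("<erp_averages> set '%s' (%s, %s): %d waveforms of length %d\n",
              x$set_name, x$region, x$hemisphere, nrow(x$waveforms),
              ncol(x$waveforms)))
  cat("  epochs used:", paste(sprintf("%s=%d", names(x$n_epochs), x$n_epochs),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Plot averaged waveforms by condition
#'
#' @param x An `erp_averages`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.erp_averages <- function(x, ...) {
  conds <- unique(x$meta$condition)
  cols <- stats::setNames(seq_along(conds) + 1L, conds)
  t_ms <- x$window_ms[1] +
    (seq_len(ncol(x$waveforms)) - 1) / x$sampling_rate * 1000
  graphics::matplot(t_ms, t(x$waveforms), type = "l", lty = 1,
                    col = cols[x$meta$condition],
                    xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = x$set_name, ...)
  graphics::legend("bottomleft", legend = conds, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
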