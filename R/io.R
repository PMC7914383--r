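#' Write / read a recording as plain-text matrix plus events table
#'
#' The signal is stored as a TSV matrix (one row per channel, first column
#' the channel label), the events as a TSV with columns `onset_sample` and
#' `condition`. The sampling rate travels in a small JSON sidecar written
#' next to the signal file (`<signal_path>.meta.json`).
#'
#' @param recording An `erp_recording`.
#' @param signal_path,events_path Output file paths.
#' @return Invisibly, the recording.
#' @export
write_recording <- function(recording, signal_path, events_path) {
  stopifnot(inherits(recording, "erp_recording"))
  df <- data.frame(channel = recording$channel_labels,
                   recording$data, check.names = FALSE)
  colnames(df) <- c("channel", sprintf("s%d", seq_len(ncol(recording$data))))
  write.table(df, signal_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(recording$events, events_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = recording$sampling_rate),
                       paste0(signal_path, ".meta.json"), auto_unbox = TRUE)
  invisible(recording)
}

#' @rdname write_recording
#' @param sampling_rate Sampling rate in Hz; if `NULL`, read from the JSON
#'   sidecar.
#' @export
read_recording <- function(signal_path, events_path, sampling_rate = NULL) {
  df <- read.table(signal_path, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  events <- read.table(events_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  if (is.null(sampling_rate)) {
    meta <- jsonlite::read_json(paste0(signal_path, ".meta.json"))
    sampling_rate <- meta$sampling_rate
  }
  dat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(dat) <- NULL
  recording(dat, df$channel, sampling_rate, events)
}

#' Write averaged waveforms to TSV
#'
#' One row per waveform: set, electrode, condition, then the L sample values.
#'
#' @param averages An `erp_averages`.
#' @param path Output path.
#' @return Invisibly, the averages.
#' @export
write_averages <- function(averages, path) {
  stopifnot(inherits(averages, "erp_averages"))
  df <- data.frame(set = averages$set_name,
                   electrode = averages$meta$electrode,
                   condition = averages$meta$condition,
                   averages$waveforms, check.names = FALSE)
  colnames(df) <- c("set", "electrode", "condition",
                    sprintf("t%d", seq_len(ncol(averages$waveforms))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(averages)
}

#' Write a cluster solution to JSON
#'
#' Stores assignments, inertia, restart count, seed and degeneracy flag.
#'
#' @param solution An `erp_clusters`.
#' @param path Output path.
#' @return Invisibly, the solution.
#' @export
write_clusters <- function(solution, path) {
  stopifnot(inherits(solution, "erp_clusters"))
  jsonlite::write_json(
    list(set = solution$set_name,
         assignments = as.list(stats::setNames(
           as.character(solution$assignments),
           names(solution$assignments))),
         inertia = solution$inertia, k = solution$k,
         n_restarts = solution$n_restarts, seed = solution$seed,
         degenerate = solution$degenerate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(solution)
}

#' Write comparison results to TSV
#'
#' One row per (set, condition pair): table cells, exact and adjusted
#' p-values, rejection flag and block metadata.
#'
#' @param result An `erp_subject_result` or its `comparisons` data frame.
#' @param path Output path.
#' @return Invisibly, the comparisons data frame.
#' @export
write_comparisons <- function(result, path) {
  cmp <- if (inherits(result, "erp_subject_result")) result$comparisons else
    result
  write.table(cmp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cmp)
}

#' Write an artifact report to TSV
#'
#' One row per rejected epoch (condition, source event index, peak frontal
#' amplitude, reason); surviving counts go into a comment header line.
#'
#' @param report An `erp_artifact_report` (from [reject_artifacts()]).
#' @param path Output path.
#' @return Invisibly, the report.
#' @export
write_artifact_report <- function(report, path) {
  stopifnot(inherits(report, "erp_artifact_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# threshold=", report$threshold, " surviving=",
                    paste(sprintf("%s:%d", names(report$n_surviving),
                                  report$n_surviving), collapse = ",")),
             con)
  write.table(report$rejected, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(report)
}

#' Write cluster labels to TSV
#'
#' One row per waveform: set, electrode, condition, cluster label.
#'
#' @param solution An `erp_clusters` with condition metadata.
#' @param path Output path.
#' @return Invisibly, the solution.
#' @export
write_cluster_labels <- function(solution, path) {
  stopifnot(inherits(solution, "erp_clusters"))
  if (is.null(solution$meta)) {
    stop("cluster solution carries no condition metadata", call. = FALSE)
  }
  df <- data.frame(set = solution$set_name,
                   electrode = solution$meta$electrode,
                   condition = solution$meta$condition,
                   label = as.character(solution$assignments),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(solution)
}

#' @rdname write_comparisons
#' @details `write_comparisons_json()` writes the same rows as a JSON array.
#' @export
write_comparisons_json <- function(result, path) {
  cmp <- if (inherits(result, "erp_subject_result")) result$comparisons else
    result
  jsonlite::write_json(cmp, path, auto_unbox = TRUE, digits = NA)
  invisible(cmp)
}

#' Read / write a montage configuration (JSON or YAML)
#'
#' The file holds `sets` (name -> channels/region/hemisphere),
#' `reference_channels` and `frontal_channels`; the format follows the file
#' extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_montage()` returns an `erp_montage`.
#' @export
read_montage <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sets <- lapply(spec$sets, function(s) {
    list(channels = unlist(s$channels), region = s$region,
         hemisphere = s$hemisphere)
  })
  montage_config(sets, unlist(spec$reference_channels),
                 unlist(spec$frontal_channels))
}

#' @rdname read_montage
#' @param montage An `erp_montage` to serialize.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "erp_montage"))
  spec <- list(sets = montage$sets,
               reference_channels = montage$reference_channels,
               frontal_channels = montage$frontal_channels)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(spec, path)
  } else {
    jsonlite::write_json(spec, path, auto_unbox = TRUE)
  }
  invisible(montage)
}

#' Write synthetic ground truth to JSON
#'
#' @param ground_truth The `ground_truth` element of
#'   [generate_experiment()]'s result.
#' @param path Output path.
#' @return Invisibly, the ground truth.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(
    list(differs = ground_truth$differs,
         injected_epochs = ground_truth$injected_epochs,
         conditions = ground_truth$conditions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(ground_truth)
}
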