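# small, fast simulation settings used by the unit tests (the acceptance
# tests use the full study-sized defaults instead)
tiny_config <- function(..., seed = 1L) {
  defaults <- list(sampling_rate = 100, n_epochs_per_condition = 6,
                   epoch_length_ms = 1000, event_time_ms = 400,
                   window_length_ms = 500, inter_trial_gap_ms = 200,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_params <- function(...) {
  pipeline_params(window_ms = c(400, 900), n_restarts = 50, ...)
}

# raw-grid decimated template as the generator lays it down (for exactness
# checks against averaged waveforms)
decimated_template <- function(spec, fs = 100, window_length_ms = 500,
                               decimate = 2) {
  v <- eval_template(spec, fs, window_length_ms)
  v[seq(1, length(v), by = decimate)]
}

# minimal cluster solution for inference tests: labels given per
# (electrode, condition) in condition-major order
make_solution <- function(labels, conditions = c("hand", "ball", "none"),
                          electrodes = paste0("e", 1:4)) {
  meta <- expand.grid(electrode = electrodes, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stopifnot(length(labels) == nrow(meta))
  assignments <- factor(labels, levels = sort(unique(c(labels, "A"))))
  names(assignments) <- paste(meta$electrode, meta$condition, sep = ".")
  structure(list(assignments = assignments, meta = meta,
                 centroids = NULL, inertia = NA_real_, k = 3L,
                 set_name = "fake", n_restarts = 0L, seed = 0L,
                 degenerate = FALSE),
            class = "erp_clusters")
}

# fake subject result carrying only a comparisons table (for summary tests)
make_subject_result <- function(subject, rejected,
                                pair = c("hand x ball", "hand x none",
                                         "ball x none"),
                                region = "sensorimotor",
                                hemisphere = "left",
                                viewed_hand = "right",
                                hand_block = "dominant") {
  grid <- expand.grid(pair = pair, hemisphere = hemisphere,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cmp <- data.frame(pair = grid$pair, region = region,
                    hemisphere = grid$hemisphere,
                    rejected = rep_len(rejected, nrow(grid)),
                    subject = subject,
                    viewed_hand = viewed_hand, hand_block = hand_block,
                    set = paste(region, grid$hemisphere, sep = "_"),
                    p = 0.5, p_adjusted = 0.5,
                    stringsAsFactors = FALSE)
  cmp$rel_hemisphere <- map_hemisphere(cmp$hemisphere, cmp$viewed_hand)
  structure(list(subject = subject, comparisons = cmp),
            class = "erp_subject_result")
}
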