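#' Pipeline parameters
#'
#' Bundles the tunable parameters of the per-subject pipeline with their
#' defaults: 0.3--30 Hz zero-phase band-pass, 2500--3000 ms analysis window
#' decimated by 2 (125 samples at 250 Hz), +/-50 microvolt frontal artifact
#' threshold, k = 3 clusters with 200 k-means++ restarts, alpha = 0.05, and
#' Benjamini-Hochberg family `"per_set"` (the three condition pairs of one
#' electrode set; `"per_subject"` pools all sets of the subject instead).
#'
#' @param band Numeric length-2, band-pass edges in Hz.
#' @param window_ms Numeric length-2, analysis window in ms after event onset.
#' @param decimate Integer decimation factor applied at segmentation.
#' @param artifact_threshold Frontal rejection threshold in microvolts.
#' @param k Number of clusters.
#' @param n_restarts k-means restarts.
#' @param alpha Significance level.
#' @param bh_family `"per_set"` or `"per_subject"`.
#' @return A list of class `erp_params`.
#' @export
pipeline_params <- function(band = c(0.3, 30), window_ms = c(2500, 3000),
                            decimate = 2L, artifact_threshold = 50,
                            k = 3L, n_restarts = 200L, alpha = 0.05,
                            bh_family = c("per_set", "per_subject")) {
  bh_family <- match.arg(bh_family)
  structure(list(band = band, window_ms = window_ms,
                 decimate = as.integer(decimate),
                 artifact_threshold = artifact_threshold, k = as.integer(k),
                 n_restarts = as.integer(n_restarts), alpha = alpha,
                 bh_family = bh_family),
            class = "erp_params")
}

#' Map a hemisphere to contralateral/ipsilateral relative to the viewed hand
#'
#' @param set_hemisphere `"left"` or `"right"` (hemisphere of the electrode
#'   set).
#' @param viewed_hand `"left"` or `"right"` (hand shown in the videos).
#' @return `"contralateral"` if the sides differ, else `"ipsilateral"`.
#' @export
map_hemisphere <- function(set_hemisphere, viewed_hand) {
  ok <- c("left", "right")
  if (!all(set_hemisphere %in% ok) || !all(viewed_hand %in% ok)) {
    stop("hemisphere and hand labels must be 'left' or 'right'",
         call. = FALSE)
  }
  ifelse(set_hemisphere == viewed_hand, "ipsilateral", "contralateral")
}

#' Run the full hierarchical pipeline on one subject's recording
#'
#' Executes filter -> re-reference -> segment -> artifact rejection ->
#' per-condition averaging -> k-means clustering -> exact pairwise
#' independence tests -> Benjamini-Hochberg adjustment, for every electrode
#' set of the montage. A set whose conditions lose all epochs is marked
#' unanalyzable and the run continues. Deterministic given `seed`.
#'
#' @param recording An `erp_recording` containing all montage channels.
#' @param montage An `erp_montage`.
#' @param params An [pipeline_params()] list.
#' @param seed Integer seed driving the clustering restarts.
#' @param subject_id Subject identifier (metadata).
#' @param viewed_hand Hand shown in this block, `"left"` or `"right"`.
#' @param handedness Subject handedness, `"left"` or `"right"`; together with
#'   `viewed_hand` it labels the block `"dominant"` or `"nondominant"`.
#' @param exclude Optional integer event indices to drop (e.g. EMG-detected
#'   movements).
#' @return An object of class `erp_subject_result`: `comparisons` (data frame
#'   with one row per set x condition pair), `solutions`, `averages`,
#'   `artifact_report`, and the run metadata.
#' @export
run_subject <- function(recording, montage = default_montage(),
                        params = pipeline_params(), seed = 1L,
                        subject_id = "S1", viewed_hand = "right",
                        handedness = "right", exclude = integer(0)) {
  stopifnot(inherits(recording, "erp_recording"),
            inherits(montage, "erp_montage"))
  missing_ch <- setdiff(montage_channels(montage), recording$channel_labels)
  if (length(missing_ch)) {
    stop("recording lacks montage channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  rec <- bandpass_filter(recording, params$band[1], params$band[2])
  rec <- rereference(rec, montage$reference_channels)
  # canonical condition order, independent of randomized trial order
  seen <- unique(recording$events$condition)
  known <- c("hand", "ball", "none")
  conds <- c(intersect(known, seen), sort(setdiff(seen, known)))
  ep <- segment_epochs(rec, window_ms = params$window_ms,
                       decimate = params$decimate, conditions = conds)
  if (length(exclude)) ep <- exclude_epochs(ep, exclude)
  rr <- reject_artifacts(ep, montage$frontal_channels,
                         params$artifact_threshold)
  ep <- rr$epochs
  hand_block <- if (viewed_hand == handedness) "dominant" else "nondominant"

  set_seeds <- .derive_seeds(seed, length(montage$sets))
  solutions <- list()
  averages <- list()
  comp_rows <- list()
  for (si in seq_along(montage$sets)) {
    nm <- names(montage$sets)[si]
    s <- montage$sets[[nm]]
    avg <- tryCatch(
      average_conditions(ep, s$channels, set_name = nm, region = s$region,
                         hemisphere = s$hemisphere),
      error = function(e) e)
    if (inherits(avg, "error")) {
      cmp <- data.frame(cond_a = utils::combn(conds, 2)[1, ],
                        cond_b = utils::combn(conds, 2)[2, ],
                        table_cells = NA_character_,
                        table_labels = NA_character_,
                        p = NA_real_, p_adjusted = NA_real_, rejected = NA,
                        stringsAsFactors = FALSE)
      cmp$analyzable <- FALSE
    } else {
      averages[[nm]] <- avg
      sol <- cluster_waveforms(avg, k = params$k,
                               n_restarts = params$n_restarts,
                               seed = set_seeds[si])
      solutions[[nm]] <- sol
      cmp <- test_condition_pairs(sol, conditions = conds,
                                  adjust = identical(params$bh_family,
                                                     "per_set"),
                                  alpha = params$alpha)
      cmp$analyzable <- TRUE
    }
    cmp$set <- nm
    cmp$region <- s$region
    cmp$hemisphere <- s$hemisphere
    comp_rows[[nm]] <- cmp
  }
  comparisons <- do.call(rbind, comp_rows)
  rownames(comparisons) <- NULL
  if (identical(params$bh_family, "per_subject")) {
    ok <- !is.na(comparisons$p)
    comparisons$p_adjusted[ok] <- bh_adjust(comparisons$p[ok])
    comparisons <- decide(comparisons, params$alpha)
    comparisons$rejected[!ok] <- NA
  }
  comparisons$subject <- subject_id
  comparisons$viewed_hand <- viewed_hand
  comparisons$hand_block <- hand_block
  comparisons$rel_hemisphere <- map_hemisphere(comparisons$hemisphere,
                                               viewed_hand)
  comparisons$pair <- paste(comparisons$cond_a, comparisons$cond_b,
                            sep = " x ")
  structure(
    list(subject = subject_id, viewed_hand = viewed_hand,
         handedness = handedness, hand_block = hand_block,
         comparisons = comparisons, solutions = solutions,
         averages = averages, artifact_report = rr$report,
         params = params, seed = as.integer(seed)),
    class = "erp_subject_result"
  )
}

#' @export
print.erp_subject_result <- function(x, ...) {
  cat(sprintf("<erp_subject_result> %s (%s hand view, %s block)\n",
              x$subject, x$viewed_hand, x$hand_block))
  print(x$comparisons[, c("set", "pair", "table_cells", "p", "p_adjusted",
                          "rejected")], row.names = FALSE)
  invisible(x)
}

#' Simulate a group of subjects and run the pipeline on each
#'
#' Generates `n_subjects` independent synthetic recordings from `config`
#' (with per-subject seeds derived from `seed`) and runs [run_subject()] on
#' each.
#'
#' @param n_subjects Number of subjects.
#' @param config An [sim_config()]; its `seed` field is replaced per subject.
#' @param montage,params As in [run_subject()].
#' @param viewed_hand,handedness Block labels shared by all subjects.
#' @param null If `TRUE`, use [generate_null_experiment()] (no true condition
#'   differences).
#' @param seed Master seed.
#' @return List of `erp_subject_result`.
#' @export
simulate_group <- function(n_subjects, config = sim_config(),
                           montage = default_montage(),
                           params = pipeline_params(), viewed_hand = "right",
                           handedness = "right", null = FALSE, seed = 1L) {
  seeds <- matrix(.derive_seeds(seed, 2L * n_subjects), ncol = 2L)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$seed <- seeds[i, 1]
    gen <- if (null) generate_null_experiment(cfg) else
      generate_experiment(cfg)
    run_subject(gen$recording, montage = montage, params = params,
                seed = seeds[i, 2], subject_id = sprintf("S%03d", i),
                viewed_hand = viewed_hand, handedness = handedness)
  })
}

#' Summarize rejections across subjects
#'
#' Counts, for every condition pair, region, hemisphere relative to the
#' viewed hand, and hand block, how many subjects rejected the independence
#' null.
#'
#' @param results List of `erp_subject_result`.
#' @return Data frame of class `erp_rejection_summary` with columns `pair`,
#'   `region`, `hand_block`, `rel_hemisphere`, `n_reject`, `n_subjects`.
#' @export
summarize_group <- function(results) {
  if (!length(results)) stop("need at least one subject result",
                             call. = FALSE)
  if (!all(vapply(results, inherits, logical(1), "erp_subject_result"))) {
    stop("`results` must be a list of erp_subject_result", call. = FALSE)
  }
  all_cmp <- do.call(rbind, lapply(results, `[[`, "comparisons"))
  schemas <- unique(vapply(results, function(r) {
    paste(sort(unique(r$comparisons$set)), collapse = "|")
  }, character(1)))
  if (length(schemas) != 1L) {
    stop("subjects have inconsistent electrode-set schemas", call. = FALSE)
  }
  agg <- stats::aggregate(
    cbind(n_reject = rejected) ~ pair + region + hand_block + rel_hemisphere,
    data = transform(all_cmp, rejected = as.integer(rejected %in% TRUE)),
    FUN = sum)
  n_subj <- stats::aggregate(
    cbind(n_subjects = subject) ~ pair + region + hand_block + rel_hemisphere,
    data = all_cmp,
    FUN = function(s) length(unique(s)))
  out <- merge(agg, n_subj)
  class(out) <- c("erp_rejection_summary", class(out))
  out
}

#' Lay out a rejection summary as a pair-by-hemisphere table
#'
#' Reshapes an [summarize_group()] result for one region into the
#' conventional layout: rows are condition pairs, columns are hand block by
#' hemisphere relative to the viewed hand.
#'
#' @param summary An `erp_rejection_summary`.
#' @param region Region to display (default `"sensorimotor"`).
#' @return Data frame with one row per condition pair.
#' @export
rejection_table <- function(summary, region = "sensorimotor") {
  s <- summary[summary$region == region, , drop = FALSE]
  if (!nrow(s)) stop("no rows for region '", region, "'", call. = FALSE)
  s$col <- paste(s$hand_block, s$rel_hemisphere, sep = ".")
  wide <- stats::reshape(
    s[, c("pair", "col", "n_reject")],
    idvar = "pair", timevar = "col", direction = "wide")
  names(wide) <- sub("^n_reject\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Empirical type-I error of the full pipeline
#'
#' Simulates `n_subjects` null subjects (identical flat templates for every
#' condition) and reports, per condition pair, the proportion of
#' set-comparisons where the pipeline rejected the independence null.
#'
#' @param n_subjects Number of null subjects.
#' @param config,montage,params,seed As in [simulate_group()].
#' @return Data frame with `pair`, `n_tests`, `n_reject`, `rate`, plus the
#'   attribute `overall` (pooled rate).
#' @export
estimate_type1_error <- function(n_subjects = 500, config = sim_config(),
                                 montage = default_montage(),
                                 params = pipeline_params(), seed = 1L) {
  res <- simulate_group(n_subjects, config = config, montage = montage,
                        params = params, null = TRUE, seed = seed)
  cmp <- do.call(rbind, lapply(res, `[[`, "comparisons"))
  cmp <- cmp[!is.na(cmp$rejected), , drop = FALSE]
  agg <- stats::aggregate(
    cbind(n_reject = as.integer(rejected), n_tests = 1L) ~ pair, data = cmp,
    FUN = sum)
  agg$rate <- agg$n_reject / agg$n_tests
  attr(agg, "overall") <- sum(agg$n_reject) / sum(agg$n_tests)
  agg
}
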