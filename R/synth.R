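#' Noise specification for synthetic recordings
#'
#' @param model Noise model: `"ar1"` (default, first-order autoregressive with
#'   EEG-like low-frequency-dominated spectrum), `"white"`, or `"one_over_f"`
#'   (spectrally shaped 1/f noise).
#' @param sd Marginal standard deviation in microvolts (>= 0).
#' @param ar_coefficient AR(1) coefficient, `|ar_coefficient| < 1`; ignored by
#'   the other models.
#' @param artifact_rate Probability that an epoch carries a frontal-channel
#'   excursion injected by [generate_experiment()] (0 disables injection).
#' @param artifact_amplitude Magnitude (microvolts) beyond which the injected
#'   excursion is displaced.
#' @param reference_scale Multiplier on `sd` for the reference (auricular)
#'   channels. Ear electrodes sit away from the cortical sources and carry far
#'   less background EEG than scalp channels; leaving them at full scalp
#'   noise would make re-referencing inject a large shared component into
#'   every channel.
#' @return An object of class `erp_noise`.
#' @export
noise_spec <- function(model = c("ar1", "white", "one_over_f"), sd = 10,
                       ar_coefficient = 0.95, artifact_rate = 0,
                       artifact_amplitude = 120, reference_scale = 0.2) {
  model <- match.arg(model)
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0) {
    stop("invalid `sd`: must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(ar_coefficient) || abs(ar_coefficient) >= 1) {
    stop("invalid `ar_coefficient`: need |ar_coefficient| < 1", call. = FALSE)
  }
  if (!is.numeric(artifact_rate) || artifact_rate < 0 || artifact_rate > 1) {
    stop("invalid `artifact_rate`: must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(reference_scale) || reference_scale < 0) {
    stop("invalid `reference_scale`: must be nonnegative", call. = FALSE)
  }
  structure(list(model = model, sd = sd, ar_coefficient = ar_coefficient,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 reference_scale = reference_scale),
            class = "erp_noise")
}

#' Configuration of a synthetic ERP experiment
#'
#' Encodes the design of one simulated recording session: acquisition
#' parameters, trial structure, condition templates, per-channel effect gains
#' and the noise model. The defaults mirror a passive action-observation
#' design: 500 Hz sampling, three conditions (`hand`, `ball`, `none`) with 60
#' trials each, 3 s trials separated by a 1 s inter-trial gap, and an
#' event-locked component confined to the 500 ms analysis window starting
#' 2500 ms after trial onset.
#'
#' @param montage An `erp_montage`; simulated channels are exactly the montage
#'   channels.
#' @param sampling_rate Hz.
#' @param n_epochs_per_condition Trials per condition (>= 1).
#' @param epoch_length_ms Trial (video) length in ms.
#' @param event_time_ms Start of the analysis window within the trial, ms.
#' @param window_length_ms Length of the analysis window, ms.
#' @param inter_trial_gap_ms Gap between consecutive trials, ms (fixation).
#' @param conditions Character vector of condition names.
#' @param templates Named list of [template_spec()] objects, one per condition.
#' @param gains Named numeric vector of per-channel effect gains; defaults to
#'   1 on sensorimotor-region channels and 0 elsewhere (temporal control,
#'   reference and frontal channels carry no event-locked signal).
#' @param template_overrides Named list: electrode set name -> (condition ->
#'   `erp_template`), replacing the global template on that set's channels.
#'   Used e.g. to blur one condition contrast in a single hemisphere.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; identical config + seed gives bit-identical data.
#' @return An object of class `erp_sim_config`.
#' @export
sim_config <- function(montage = default_montage(),
                       sampling_rate = 500,
                       n_epochs_per_condition = 60,
                       epoch_length_ms = 3000,
                       event_time_ms = 2500,
                       window_length_ms = 500,
                       inter_trial_gap_ms = 1000,
                       conditions = c("hand", "ball", "none"),
                       templates = default_templates(),
                       gains = NULL,
                       template_overrides = list(),
                       noise = noise_spec(),
                       seed = 1L) {
  stopifnot(inherits(montage, "erp_montage"), inherits(noise, "erp_noise"))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("invalid `sampling_rate`: must be positive", call. = FALSE)
  }
  if (!.is_wholenumber(n_epochs_per_condition) || n_epochs_per_condition < 1) {
    stop("invalid `n_epochs_per_condition`: must be a positive integer",
         call. = FALSE)
  }
  if (event_time_ms + window_length_ms > epoch_length_ms) {
    stop("invalid `event_time_ms`: analysis window overflows ",
         "`epoch_length_ms`", call. = FALSE)
  }
  if (!all(conditions %in% names(templates))) {
    stop("invalid `templates`: missing template for condition(s) ",
         paste(setdiff(conditions, names(templates)), collapse = ", "),
         call. = FALSE)
  }
  channels <- montage_channels(montage)
  if (is.null(gains)) {
    gains <- stats::setNames(numeric(length(channels)), channels)
    for (s in montage$sets) {
      if (identical(s$region, "sensorimotor")) gains[s$channels] <- 1
    }
  }
  if (is.null(names(gains)) || !all(names(gains) %in% channels)) {
    stop("invalid `gains`: must be named by montage channels", call. = FALSE)
  }
  if (any(gains < 0)) {
    stop("invalid `gains`: effect gains must be nonnegative", call. = FALSE)
  }
  full_gains <- stats::setNames(numeric(length(channels)), channels)
  full_gains[names(gains)] <- gains
  if (length(template_overrides)) {
    bad <- setdiff(names(template_overrides), names(montage$sets))
    if (length(bad)) {
      stop("invalid `template_overrides`: unknown set(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(montage = montage, sampling_rate = sampling_rate,
         n_epochs_per_condition = as.integer(n_epochs_per_condition),
         epoch_length_ms = epoch_length_ms, event_time_ms = event_time_ms,
         window_length_ms = window_length_ms,
         inter_trial_gap_ms = inter_trial_gap_ms,
         conditions = conditions, templates = templates, gains = full_gains,
         template_overrides = template_overrides, noise = noise,
         seed = as.integer(seed)),
    class = "erp_sim_config"
  )
}

# effective (gain-scaled, override-resolved) raw template per channel/condition
.effective_templates <- function(config) {
  mont <- config$montage
  channels <- montage_channels(mont)
  set_of <- stats::setNames(rep(NA_character_, length(channels)), channels)
  for (nm in names(mont$sets)) set_of[mont$sets[[nm]]$channels] <- nm
  out <- list()
  for (ch in channels) {
    per_cond <- list()
    for (cond in config$conditions) {
      spec <- config$templates[[cond]]
      snm <- set_of[[ch]]
      if (!is.na(snm) && !is.null(config$template_overrides[[snm]][[cond]])) {
        spec <- config$template_overrides[[snm]][[cond]]
      }
      per_cond[[cond]] <- config$gains[[ch]] *
        eval_template(spec, config$sampling_rate, config$window_length_ms)
    }
    out[[ch]] <- per_cond
  }
  out
}

# ground-truth "templates differ" flags per electrode set and condition pair
.ground_truth_differs <- function(config, eff) {
  mont <- config$montage
  conds <- config$conditions
  pairs <- utils::combn(conds, 2)
  rows <- list()
  for (nm in names(mont$sets)) {
    chs <- mont$sets[[nm]]$channels
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      differ <- any(vapply(chs, function(ch) {
        max(abs(eff[[ch]][[a]] - eff[[ch]][[b]])) > 0
      }, logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, cond_a = a, cond_b = b, differ = differ,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# one channel of continuous noise
.gen_noise <- function(model, n, sd, ar) {
  if (sd == 0) return(numeric(n))
  if (model == "white") return(rnorm(n, 0, sd))
  if (model == "ar1") {
    burn <- 200L
    innov <- rnorm(n + burn, 0, sd * sqrt(1 - ar^2))
    x <- stats::filter(innov, ar, method = "recursive")
    return(as.numeric(x[(burn + 1):(burn + n)]))
  }
  # one_over_f: shape a white spectrum by 1/sqrt(f), rescale to sd
  w <- rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  W <- W / sqrt(pmax(f, 1))
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

#' Generate a synthetic ERP experiment
#'
#' Simulates a continuous multichannel recording under an [sim_config()]:
#' trials of all conditions are interleaved in random order, each channel
#' receives independent noise, and inside each trial's analysis window the
#' channel's effective condition template (template times per-channel gain) is
#' added. Ground truth records, per electrode set and condition pair, whether
#' the effective templates differ, plus the indices of any artifact-injected
#' epochs.
#'
#' @param config An `erp_sim_config`.
#' @return A list with elements `recording` (an `erp_recording`) and
#'   `ground_truth` (list with `differs`, a data frame of per-set pairwise
#'   flags, and `injected_epochs`, integer trial indices).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "erp_sim_config"))
  fs <- config$sampling_rate
  epoch_samples <- round(config$epoch_length_ms / 1000 * fs)
  gap_samples <- round(config$inter_trial_gap_ms / 1000 * fs)
  trial_samples <- epoch_samples + gap_samples
  conds <- config$conditions
  n_per <- config$n_epochs_per_condition
  n_trials <- n_per * length(conds)
  total <- n_trials * trial_samples
  channels <- montage_channels(config$montage)
  eff <- .effective_templates(config)
  win_off <- round(config$event_time_ms / 1000 * fs)

  res <- withr::with_seed(config$seed, {
    trial_cond <- sample(rep(conds, each = n_per))
    onsets <- (seq_len(n_trials) - 1L) * trial_samples + 1L
    dat <- matrix(0, nrow = length(channels), ncol = total,
                  dimnames = list(channels, NULL))
    ref_scale <- config$noise$reference_scale %||% 1
    for (i in seq_along(channels)) {
      sd_i <- config$noise$sd *
        if (channels[i] %in% config$montage$reference_channels)
          ref_scale else 1
      dat[i, ] <- .gen_noise(config$noise$model, total, sd_i,
                             config$noise$ar_coefficient)
    }
    active <- channels[vapply(channels, function(ch) {
      any(vapply(eff[[ch]], function(v) any(v != 0), logical(1)))
    }, logical(1))]
    wlen <- length(eff[[channels[1]]][[conds[1]]])
    for (t in seq_len(n_trials)) {
      idx <- onsets[t] + win_off + seq_len(wlen) - 1L
      for (ch in active) {
        dat[ch, idx] <- dat[ch, idx] + eff[[ch]][[trial_cond[t]]]
      }
    }
    list(dat = dat, trial_cond = trial_cond, onsets = onsets)
  })

  rec <- recording(res$dat, channels, fs,
                   data.frame(onset_sample = res$onsets,
                              condition = res$trial_cond,
                              stringsAsFactors = FALSE))
  injected <- integer(0)
  if (config$noise$artifact_rate > 0) {
    inj <- inject_artifacts(rec, rate = config$noise$artifact_rate,
                            amplitude = config$noise$artifact_amplitude,
                            channels = config$montage$frontal_channels,
                            seed = config$seed + 1L,
                            window_offset = win_off,
                            window_length = round(config$window_length_ms /
                                                    1000 * fs))
    rec <- inj$recording
    injected <- inj$injected_epochs
  }
  list(recording = rec,
       ground_truth = list(differs = .ground_truth_differs(config, eff),
                           injected_epochs = injected,
                           conditions = conds))
}

#' Generate a null synthetic experiment
#'
#' Identical to [generate_experiment()] but with the same (flat) template for
#' every condition, so no condition pair truly differs anywhere; used to
#' estimate the empirical type-I error of the full pipeline.
#'
#' @param config An `erp_sim_config`; its templates are replaced by flat ones.
#' @return As [generate_experiment()]; every `differ` flag is `FALSE`.
#' @export
generate_null_experiment <- function(config) {
  stopifnot(inherits(config, "erp_sim_config"))
  flat <- template_spec("flat")
  config$templates <- stats::setNames(
    rep(list(flat), length(config$conditions)), config$conditions)
  config$template_overrides <- list()
  generate_experiment(config)
}

#' Inject frontal-channel artifacts into a recording
#'
#' In a seeded random subset of epochs, one sample on one of the given
#' channels is displaced to `1.25 * amplitude` microvolts (random sign), i.e.
#' beyond `+/- amplitude`. The displaced sample is placed inside the epoch's
#' analysis window on the decimation-retained grid, so downstream threshold
#' rejection operating on segmented windows can detect exactly the injected
#' epochs.
#'
#' @param recording An `erp_recording`.
#' @param rate Injection probability per epoch, in `[0, 1]`.
#' @param amplitude Threshold magnitude (microvolts) the excursion exceeds.
#' @param channels Channel labels eligible for displacement.
#' @param seed Integer seed.
#' @param window_offset Offset (samples) from event onset to the analysis
#'   window start.
#' @param window_length Analysis window length in raw samples.
#' @param decimate Decimation factor later applied by [segment_epochs()];
#'   injected samples land on the retained grid.
#' @return List with `recording` (modified) and `injected_epochs` (sorted
#'   integer indices into the event table).
#' @export
inject_artifacts <- function(recording, rate, amplitude, channels, seed = 1L,
                             window_offset = round(2.5 * recording$sampling_rate),
                             window_length = round(0.5 * recording$sampling_rate),
                             decimate = 2L) {
  stopifnot(inherits(recording, "erp_recording"))
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop("`rate` must lie in [0, 1]", call. = FALSE)
  }
  missing_ch <- setdiff(channels, recording$channel_labels)
  if (length(missing_ch)) {
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  n_ev <- nrow(recording$events)
  if (rate == 0 || n_ev == 0) {
    return(list(recording = recording, injected_epochs = integer(0)))
  }
  grid <- seq.int(1L, window_length, by = decimate)
  out <- withr::with_seed(as.integer(seed), {
    hit <- which(rbinom(n_ev, 1, rate) == 1L)
    dat <- recording$data
    for (i in hit) {
      ch <- if (length(channels) == 1L) channels else sample(channels, 1L)
      pos <- recording$events$onset_sample[i] + window_offset +
        grid[sample.int(length(grid), 1L)] - 1L
      dat[ch, pos] <- sample(c(-1, 1), 1L) * 1.25 * amplitude
    }
    list(dat = dat, hit = hit)
  })
  rec2 <- recording
  rec2$data <- out$dat
  list(recording = rec2, injected_epochs = sort(out$hit))
}
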