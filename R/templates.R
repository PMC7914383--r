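#' Event-locked waveform template
#'
#' Describes the deterministic event-locked component added inside the
#' analysis window of a synthetic epoch. Three shapes are available:
#'
#' * `"negative_ramp"`: a linear drift from 0 down to `-amplitude` microvolts
#'   across its support -- a readiness-potential-like anticipatory negativity;
#' * `"biphasic_bump"`: one full sine cycle (positive lobe then negative lobe)
#'   peaking at `amplitude` microvolts;
#' * `"flat"`: identically zero (amplitude is forced to 0).
#'
#' @param shape One of `"negative_ramp"`, `"biphasic_bump"`, `"flat"`.
#' @param amplitude Peak magnitude in microvolts (>= 0).
#' @param onset_ms,offset_ms Support of the template in milliseconds relative
#'   to the start of the analysis window; zero outside `[onset, offset)`.
#' @return An object of class `erp_template`.
#' @export
template_spec <- function(shape = c("negative_ramp", "biphasic_bump", "flat"),
                          amplitude = 10, onset_ms = 0, offset_ms = 500) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("invalid `amplitude`: must be a single nonnegative number",
         call. = FALSE)
  }
  if (shape == "flat") amplitude <- 0
  if (offset_ms <= onset_ms) {
    stop("invalid template support: `offset_ms` must exceed `onset_ms`",
         call. = FALSE)
  }
  structure(list(shape = shape, amplitude = amplitude,
                 onset_ms = onset_ms, offset_ms = offset_ms),
            class = "erp_template")
}

#' Evaluate a template on the raw sampling grid of the analysis window
#'
#' @param spec An `erp_template`.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_length_ms Length of the analysis window in ms.
#' @return Numeric vector of `round(window_length_ms / 1000 * sampling_rate)`
#'   samples (microvolts).
#' @export
eval_template <- function(spec, sampling_rate, window_length_ms = 500) {
  stopifnot(inherits(spec, "erp_template"))
  n <- round(window_length_ms / 1000 * sampling_rate)
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  y <- numeric(n)
  on <- spec$onset_ms
  off <- spec$offset_ms
  inside <- t_ms >= on & t_ms < off
  if (spec$shape == "negative_ramp") {
    y[inside] <- -spec$amplitude * (t_ms[inside] - on) / (off - on)
  } else if (spec$shape == "biphasic_bump") {
    y[inside] <- spec$amplitude * sin(2 * pi * (t_ms[inside] - on) / (off - on))
  }
  y
}

#' Default condition templates
#'
#' Hand movement: negative ramp (anticipatory negativity before an observed
#' grasp); ball movement: biphasic bump (a deliberately different, equally
#' energetic shape for the tactile-event prediction); no movement: flat.
#'
#' @param amplitude Peak magnitude in microvolts for the non-flat templates.
#' @return Named list of `erp_template` objects with entries `hand`, `ball`,
#'   `none`.
#' @export
default_templates <- function(amplitude = 10) {
  list(hand = template_spec("negative_ramp", amplitude = amplitude),
       ball = template_spec("biphasic_bump", amplitude = amplitude),
       none = template_spec("flat"))
}
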