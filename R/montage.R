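#' Electrode montage configuration
#'
#' A montage names the four-electrode sets that enter the clustering analysis,
#' the reference channels used for re-referencing, and the frontal channels
#' scanned for ocular artifacts. Each set carries a `region` tag
#' (`"sensorimotor"` for sets of interest, `"temporal"` for negative-control
#' sets) and a `hemisphere` tag (`"left"` / `"right"`) used when rejection
#' counts are reported relative to the viewed hand.
#'
#' @param sets Named list; each element is a list with fields `channels`
#'   (character vector of exactly 4 channel labels), `region` and `hemisphere`.
#' @param reference_channels Character vector of reference channel labels
#'   (typically the two auricular electrodes).
#' @param frontal_channels Character vector of frontal channel labels used for
#'   artifact detection.
#' @return An object of class `erp_montage`.
#' @seealso [default_montage()]
#' @export
montage_config <- function(sets, reference_channels, frontal_channels) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list of electrode sets", call. = FALSE)
  }
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (!is.character(s$channels) || length(s$channels) != 4L) {
      stop("electrode set '", nm, "' must contain exactly 4 channels",
           call. = FALSE)
    }
    if (is.null(s$hemisphere) || !s$hemisphere %in% c("left", "right")) {
      stop("electrode set '", nm, "' needs hemisphere 'left' or 'right'",
           call. = FALSE)
    }
    if (is.null(s$region)) {
      stop("electrode set '", nm, "' needs a region tag", call. = FALSE)
    }
    if (any(s$channels %in% reference_channels)) {
      stop("electrode set '", nm, "' overlaps the reference channels",
           call. = FALSE)
    }
  }
  set_channels <- unlist(lapply(sets, `[[`, "channels"), use.names = FALSE)
  if (anyDuplicated(set_channels)) {
    stop("electrode sets must be disjoint", call. = FALSE)
  }
  structure(
    list(sets = sets,
         reference_channels = as.character(reference_channels),
         frontal_channels = as.character(frontal_channels)),
    class = "erp_montage"
  )
}

#' Default sensorimotor/temporal montage
#'
#' Four electrode sets on a 10-10-labelled subset of a dense geodesic net:
#' left and right sensorimotor sets (C3, Cp3, C5, Cp5 and C4, Cp4, C6, Cp6),
#' and left and right temporal control sets (device-numbered channels, with
#' T9/T10 aliases where they exist). The reference pair is the two auricular
#' electrodes (A1, A2) and the artifact channels are Fp2, FpZ, Fp1.
#'
#' @return An `erp_montage` object.
#' @export
default_montage <- function() {
  montage_config(
    sets = list(
      sensorimotor_left = list(
        channels = c("C3", "Cp3", "C5", "Cp5"),
        region = "sensorimotor", hemisphere = "left"),
      sensorimotor_right = list(
        channels = c("C4", "Cp4", "C6", "Cp6"),
        region = "sensorimotor", hemisphere = "right"),
      temporal_left = list(
        channels = c("E48", "E43", "T9", "E49"),
        region = "temporal", hemisphere = "left"),
      temporal_right = list(
        channels = c("E113", "T10", "E119", "E129"),
        region = "temporal", hemisphere = "right")
    ),
    reference_channels = c("A1", "A2"),
    frontal_channels = c("Fp2", "FpZ", "Fp1")
  )
}

#' All channel labels referenced by a montage
#' @param montage An `erp_montage`.
#' @return Character vector of unique channel labels.
#' @export
montage_channels <- function(montage) {
  stopifnot(inherits(montage, "erp_montage"))
  unique(c(unlist(lapply(montage$sets, `[[`, "channels"), use.names = FALSE),
           montage$reference_channels, montage$frontal_channels))
}

#' @export
print.erp_montage <- function(x, ...) {
  cat("<erp_montage>\n")
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("  %-20s [%s, %s] %s\n", nm, s$region, s$hemisphere,
                paste(s$channels, collapse = " ")))
  }
  cat("  reference:", paste(x$reference_channels, collapse = " "), "\n")
  cat("  frontal:  ", paste(x$frontal_channels, collapse = " "), "\n")
  invisible(x)
}
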