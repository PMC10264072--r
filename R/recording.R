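#' Construct a multi-channel recording
#'
#' A `pico_recording` bundles equal-length sampled EMG/ENG channels with
#' the stimulus train, water-bolus events, and free-form metadata. Channel
#' names follow the muscle/nerve convention: `diaphragm`, `submental`,
#' `laryngeal` plus optional `xii`, `x` and an `ecg` reference. The
#' diaphragm and laryngeal channels are always required; the submental
#' channel may be absent only when `xii` is present (the hypoglossal ENG
#' then serves as the swallow-duration fallback).
#'
#' @param channels Named list of equal-length numeric vectors (a.u.).
#' @param sampling_rate Sampling rate in Hz.
#' @param stimuli data.frame of laser pulses with columns `onset` (s),
#'   `duration_ms`, optional `power_label`; sorted, non-overlapping.
#' @param water_events Numeric vector of water-bolus times, s.
#' @param metadata Free-form named list (genotype tag, seed, units, ...).
#' @return A list of class `pico_recording`.
#' @export
recording <- function(channels, sampling_rate, stimuli = empty_stimuli(),
                      water_events = numeric(), metadata = list()) {
  rec <- structure(
    list(channels = channels, sampling_rate = sampling_rate,
         stimuli = stimuli, water_events = water_events, metadata = metadata),
    class = "pico_recording"
  )
  validate_recording(rec)
  rec
}

#' @export
print.pico_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf(
    "pico_recording: %d channel(s) [%s], %.1f s @ %g Hz, %d stimuli, %d water events\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    n / x$sampling_rate, x$sampling_rate, nrow(x$stimuli), length(x$water_events)
  ))
  invisible(x)
}

empty_stimuli <- function() {
  data.frame(onset = numeric(), duration_ms = numeric(),
             power_label = character(), stringsAsFactors = FALSE)
}

validate_stimuli <- function(stimuli) {
  if (!is.data.frame(stimuli) || !all(c("onset", "duration_ms") %in% names(stimuli))) {
    stop("stimuli must be a data.frame with columns 'onset' and 'duration_ms'",
         call. = FALSE)
  }
  if (nrow(stimuli) == 0) return(invisible(stimuli))
  if (any(stimuli$onset < 0) || any(stimuli$duration_ms <= 0)) {
    stop("stimulus onsets must be >= 0 and durations > 0", call. = FALSE)
  }
  if (is.unsorted(stimuli$onset, strictly = TRUE)) {
    stop("stimuli must be sorted by onset", call. = FALSE)
  }
  offs <- stimuli$onset + stimuli$duration_ms / 1000
  if (nrow(stimuli) > 1 && any(stimuli$onset[-1] < offs[-nrow(stimuli)])) {
    stop("stimuli must not overlap", call. = FALSE)
  }
  invisible(stimuli)
}

validate_recording <- function(rec) {
  ch <- rec$channels
  if (!is.list(ch) || length(ch) == 0 || is.null(names(ch)) ||
      any(names(ch) == "") || anyDuplicated(names(ch))) {
    stop("channels must be a uniquely named, non-empty list", call. = FALSE)
  }
  lens <- vapply(ch, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("all channel series must share one length", call. = FALSE)
  }
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  for (required in c("diaphragm", "laryngeal")) {
    if (!required %in% names(ch)) {
      stop(sprintf("missing required channel '%s'", required), call. = FALSE)
    }
  }
  if (!"submental" %in% names(ch) && !"xii" %in% names(ch)) {
    stop("missing required channel 'submental' (no 'xii' fallback present)",
         call. = FALSE)
  }
  validate_stimuli(rec$stimuli)
  if (any(rec$water_events < 0)) stop("water_events must be >= 0", call. = FALSE)
  invisible(rec)
}

#' Recording duration in seconds
#' @param rec A `pico_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  length(rec$channels[[1]]) / rec$sampling_rate
}
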