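# Motor-burst detection on rectified-smoothed envelopes and segmentation
# of the diaphragm trace into respiratory cycles.

#' Detect motor bursts on an envelope
#'
#' Bursts are maximal intervals where the envelope exceeds
#' `baseline_mean + k_onset * baseline_SD`, extended by hysteresis down to
#' `baseline_mean + k_offset * baseline_SD`, after merging bursts separated
#' by gaps shorter than `min_gap_ms` and discarding runs shorter than
#' `min_duration_ms`. The peak is the envelope maximum within the burst.
#'
#' Baseline statistics come from an explicit stimulus-free window when one
#' is supplied. With `baseline = NULL` they are estimated robustly from
#' the whole trace (median and 1.4826 * MAD), which tolerates rhythmic
#' activity occupying up to half the record - necessary for the diaphragm
#' channel, where no activity-free window exists. The baseline SD is taken
#' from the rectified (pre-smoothing) signal when the envelope carries it:
#' smoothing shrinks the envelope's own spread far below the variability a
#' threshold must clear, and an envelope-SD criterion would fire on
#' ordinary noise excursions.
#'
#' @param envelope A `pico_envelope` from [rectify_smooth()], or a numeric
#'   vector (then `sampling_rate` is required).
#' @param sampling_rate Sampling rate in Hz if `envelope` is numeric.
#' @param baseline Either `NULL` (robust estimate) or a length-2 numeric
#'   `c(start, end)` in seconds delimiting a quiet window.
#' @param k_onset,k_offset Detection and hysteresis-termination thresholds
#'   in baseline-SD multiples.
#' @param min_duration_ms Minimum burst duration, ms.
#' @param min_gap_ms Bursts closer than this are merged, ms.
#' @param channel Channel name stored in the output.
#' @return data.frame of bursts: `channel`, `onset`, `offset`, `peak_time`
#'   (s), `peak_amplitude` (a.u.), `duration_ms`; sorted, non-overlapping.
#' @export
detect_bursts <- function(envelope, sampling_rate = NULL, baseline = NULL,
                          k_onset = 3, k_offset = 1, min_duration_ms = 15,
                          min_gap_ms = 10, channel = NA_character_) {
  rectified <- NULL
  if (inherits(envelope, "pico_envelope")) {
    fs <- envelope$sampling_rate
    if (is.na(channel) && !is.null(envelope$provenance$channel)) {
      channel <- envelope$provenance$channel
    }
    rectified <- envelope$rectified
    env <- envelope$samples
  } else {
    if (is.null(sampling_rate)) {
      stop("sampling_rate required for a bare numeric envelope", call. = FALSE)
    }
    fs <- sampling_rate
    env <- as.numeric(envelope)
  }
  if (length(env) == 0) stop("empty envelope", call. = FALSE)
  if (any(env < 0)) stop("envelope must be non-negative", call. = FALSE)

  if (!is.null(baseline)) {
    i0 <- max(1L, floor(baseline[1] * fs) + 1L)
    i1 <- min(length(env), ceiling(baseline[2] * fs))
    if (i1 <= i0) stop("baseline window is empty", call. = FALSE)
    m <- mean(env[i0:i1])
    s <- if (!is.null(rectified)) stats::sd(rectified[i0:i1])
         else stats::sd(env[i0:i1])
  } else {
    m <- stats::median(env)
    s <- if (!is.null(rectified)) stats::mad(rectified)
         else stats::mad(env)
  }
  if (!is.finite(s) || s <= 0) s <- max(m, .Machine$double.eps) * 1e-6
  thr_on <- m + k_onset * s
  thr_off <- m + k_offset * s

  above <- env > thr_off
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  if (length(starts)) {
    seeded <- vapply(seq_along(starts), function(i) {
      any(env[starts[i]:ends[i]] > thr_on)
    }, logical(1))
    starts <- starts[seeded]
    ends <- ends[seeded]
  }
  # merge gaps shorter than min_gap
  gap_smp <- round(min_gap_ms / 1000 * fs)
  if (length(starts) > 1) {
    keep_start <- c(TRUE, (starts[-1] - ends[-length(ends)]) >= gap_smp)
    grp <- cumsum(keep_start)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  # discard short runs
  min_smp <- round(min_duration_ms / 1000 * fs)
  if (length(starts)) {
    long_enough <- (ends - starts + 1L) >= min_smp
    starts <- starts[long_enough]
    ends <- ends[long_enough]
  }
  if (length(starts) == 0) {
    return(data.frame(channel = character(), onset = numeric(),
                      offset = numeric(), peak_time = numeric(),
                      peak_amplitude = numeric(), duration_ms = numeric(),
                      stringsAsFactors = FALSE))
  }
  peak_idx <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(env[seg])]
  }, numeric(1))
  out <- data.frame(
    channel = channel,
    onset = (starts - 1) / fs,
    offset = (ends - 1) / fs,
    peak_time = (peak_idx - 1) / fs,
    peak_amplitude = env[peak_idx],
    stringsAsFactors = FALSE
  )
  out$duration_ms <- (out$offset - out$onset) * 1000
  rownames(out) <- NULL
  if (!is.null(baseline) &&
      any(out$onset < baseline[2] & out$offset > baseline[1])) {
    warning("baseline window overlaps detected activity; threshold may be inflated")
  }
  out
}

#' Segment the diaphragm burst train into respiratory cycles
#'
#' The respiratory cycle runs from one diaphragm burst onset to the onset
#' of the subsequent diaphragm activity, so n bursts yield n - 1 breaths.
#' The diaphragm inter-burst interval (offset of the diaphragm activity to
#' the onset of the subsequent breath) is reported per cycle.
#'
#' @param diaphragm_bursts Burst data.frame from [detect_bursts()] run on
#'   the diaphragm envelope (>= 2 bursts).
#' @return data.frame of breaths: `insp_onset`, `insp_peak_time`,
#'   `insp_peak_amplitude`, `insp_offset`, `next_insp_onset`,
#'   `cycle_duration` (s), `ibi_ms`.
#' @export
segment_breaths <- function(diaphragm_bursts) {
  b <- diaphragm_bursts[order(diaphragm_bursts$onset), ]
  n <- nrow(b)
  if (n < 2) stop("need at least 2 diaphragm bursts to segment breaths", call. = FALSE)
  out <- data.frame(
    insp_onset = b$onset[-n],
    insp_peak_time = b$peak_time[-n],
    insp_peak_amplitude = b$peak_amplitude[-n],
    insp_offset = b$offset[-n],
    next_insp_onset = b$onset[-1]
  )
  out$cycle_duration <- out$next_insp_onset - out$insp_onset
  out$ibi_ms <- (out$next_insp_onset - out$insp_offset) * 1000
  out
}

#' Separate control breaths from stimulus-perturbed breaths
#'
#' A breath is a control cycle only if no laser pulse and no water bolus
#' falls inside `[insp_onset, next_insp_onset)`. Control cycles supply the
#' expected-phase denominator for the phase and phase-shift statistics.
#'
#' @param breaths Breath data.frame from [segment_breaths()].
#' @param stimuli Stimulus data.frame (`onset`, `duration_ms`) or numeric
#'   onsets.
#' @param water_events Numeric water-bolus times, s.
#' @return A list with `breaths` (input plus logical `control` column),
#'   `control_breaths`, and `flagged_breaths`.
#' @export
exclude_perturbed_breaths <- function(breaths, stimuli = NULL,
                                      water_events = numeric()) {
  if (is.data.frame(stimuli)) {
    s_on <- stimuli$onset
    s_off <- stimuli$onset + stimuli$duration_ms / 1000
  } else {
    s_on <- as.numeric(stimuli)
    s_off <- s_on
  }
  pts <- c(water_events)
  control <- vapply(seq_len(nrow(breaths)), function(i) {
    lo <- breaths$insp_onset[i]
    hi <- breaths$next_insp_onset[i]
    hit_stim <- length(s_on) && any(s_on < hi & s_off >= lo)
    hit_water <- length(pts) && any(pts >= lo & pts < hi)
    !(isTRUE(hit_stim) || isTRUE(hit_water))
  }, logical(1))
  breaths$control <- control
  list(breaths = breaths,
       control_breaths = breaths[control, , drop = FALSE],
       flagged_breaths = breaths[!control, , drop = FALSE])
}
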