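# Respiratory phase, phase-shift (reset) curves, behavior-probability
# curves, swallow-timing histograms, and the reset regression.
#
# Conventions: the respiratory cycle runs from one diaphragm onset to the
# next; the expected phase is the mean duration of the control
# (unstimulated) cycles of the session; the phase shift is the duration
# of the cycle containing the stimulus divided by the duration of the
# nearest preceding control cycle, so 1 means no reset.

# locate the containing breath and its reference control cycle
locate_cycle <- function(onset, breaths) {
  idx <- findInterval(onset, breaths$insp_onset)
  if (idx < 1 || onset >= breaths$next_insp_onset[idx]) {
    return(list(idx = NA_integer_, ref = NA_integer_))
  }
  control <- if ("control" %in% names(breaths)) breaths$control else
    rep(TRUE, nrow(breaths))
  ref <- NA_integer_
  if (idx > 1) {
    for (j in (idx - 1):1) {
      if (control[j]) { ref <- j; break }
    }
  }
  list(idx = idx, ref = ref)
}

#' Respiratory phase of a stimulus
#'
#' Elapsed time from the onset of the inspiration containing the stimulus
#' to the stimulus onset, divided by the expected phase: the mean duration
#' of the session's control (unstimulated) cycles. Phase 0 is inspiration
#' onset; values above 1 can occur when the containing cycle outlasts the
#' expected one and are retained.
#'
#' @param onset Stimulus onset time(s), s (vectorized).
#' @param breaths Breath table, ideally with the `control` column from
#'   [exclude_perturbed_breaths()].
#' @return Numeric phase(s); `NA` where no containing breath exists or no
#'   control cycle is available (such samples are excluded upstream).
#' @export
respiratory_phase <- function(onset, breaths) {
  expected <- expected_phase(breaths)
  vapply(onset, function(o) {
    loc <- locate_cycle(o, breaths)
    if (is.na(loc$idx) || !is.finite(expected)) return(NA_real_)
    (o - breaths$insp_onset[loc$idx]) / expected
  }, numeric(1))
}

#' Expected phase of a session
#'
#' The mean duration of the control (unstimulated) respiratory cycles;
#' falls back to all cycles when no control flags are present.
#'
#' @param breaths Breath table.
#' @return Expected cycle duration, s.
#' @export
expected_phase <- function(breaths) {
  d <- if ("control" %in% names(breaths)) {
    breaths$cycle_duration[breaths$control]
  } else {
    breaths$cycle_duration
  }
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Respiratory phase shift (reset) elicited by a stimulus
#'
#' Duration of the respiratory cycle containing the stimulus divided by
#' the duration of the nearest preceding control cycle. 1 means no reset;
#' values above 1 a delayed next inspiration; below 1 an earlier onset.
#'
#' @inheritParams respiratory_phase
#' @return Numeric ratio(s); `NA` where not computable.
#' @export
phase_shift <- function(onset, breaths) {
  vapply(onset, function(o) {
    loc <- locate_cycle(o, breaths)
    if (is.na(loc$idx) || is.na(loc$ref)) return(NA_real_)
    breaths$cycle_duration[loc$idx] / breaths$cycle_duration[loc$ref]
  }, numeric(1))
}

#' Per-stimulus phase samples for the reset analysis
#'
#' Builds the (respiratory phase, phase shift, class, group) table for the
#' laser stimuli of a classified session. Stimuli in the first breath or
#' without a preceding control cycle are excluded. The swallow group
#' contains exactly the swallow-classified stimuli; laryngeal activation
#' and no response form the non-swallow group.
#'
#' @param events Event table from [classify_session()].
#' @param breaths Breath table with `control` flags.
#' @return data.frame: `stimulus_id`, `respiratory_phase`, `phase_shift`,
#'   `behavior_class`, `group`.
#' @export
phase_samples <- function(events, breaths) {
  laser <- events[events$trigger == "laser", , drop = FALSE]
  ph <- respiratory_phase(laser$stim_onset, breaths)
  sh <- phase_shift(laser$stim_onset, breaths)
  keep <- is.finite(ph) & is.finite(sh)
  if (any(!keep)) {
    message(sum(!keep), " stimulus/stimuli without a valid preceding control cycle excluded")
  }
  data.frame(
    stimulus_id = laser$event_id[keep],
    respiratory_phase = ph[keep],
    phase_shift = sh[keep],
    behavior_class = laser$class[keep],
    group = ifelse(laser$class[keep] == "swallow", "swallow", "non_swallow"),
    stringsAsFactors = FALSE
  )
}

#' Bin a per-stimulus value over the respiratory phase
#'
#' Mean +/- SD of `value` in `n_bins` equal bins over the phase interval
#' `[0, 1]`; bins are half-open `[i/n, (i+1)/n)` with the last bin closed.
#' Out-of-range samples (phase > 1) are excluded from the bins and counted
#' in the `overflow` attribute.
#'
#' @param phase Numeric phases (>= 0).
#' @param value Values to aggregate (same length).
#' @param n_bins Number of bins (default 10).
#' @return data.frame: `bin`, `lo`, `hi`, `center`, `mean`, `sd`, `n`;
#'   attribute `overflow` counts out-of-range samples.
#' @export
bin_curve <- function(phase, value, n_bins = 10) {
  if (length(phase) == 0) stop("no samples to bin", call. = FALSE)
  if (length(phase) != length(value)) stop("phase/value length mismatch", call. = FALSE)
  in_range <- phase >= 0 & phase <= 1
  idx <- pmin(floor(phase[in_range] * n_bins) + 1L, n_bins)
  v <- value[in_range]
  out <- data.frame(
    bin = seq_len(n_bins),
    lo = (seq_len(n_bins) - 1) / n_bins,
    hi = seq_len(n_bins) / n_bins
  )
  out$center <- (out$lo + out$hi) / 2
  out$mean <- vapply(seq_len(n_bins), function(b) {
    if (any(idx == b)) mean(v[idx == b]) else NA_real_
  }, numeric(1))
  out$sd <- vapply(seq_len(n_bins), function(b) {
    if (sum(idx == b) > 1) stats::sd(v[idx == b]) else NA_real_
  }, numeric(1))
  out$n <- vapply(seq_len(n_bins), function(b) sum(idx == b), numeric(1))
  attr(out, "overflow") <- sum(!in_range)
  out
}

#' Phase-resolved behavior probability curves
#'
#' For each respiratory-phase bin and behavior class, the probability is
#' the mean of the class indicator over the stimuli in that bin (a "0 or
#' 1" per stimulus). Classes are exhaustive and exclusive, so the three
#' probabilities sum to exactly 1 in every non-empty bin; empty bins are
#' reported as missing, not 0.
#'
#' @param events Event table from [classify_session()] with a
#'   `respiratory_phase` column (see [analyze_recording()]), laser trials.
#' @param n_bins Number of phase bins.
#' @return Long data.frame: `class`, `bin`, `center`, `probability`, `n`.
#' @export
probability_curves <- function(events, n_bins = 10) {
  laser <- events[events$trigger == "laser" & is.finite(events$respiratory_phase), ,
                  drop = FALSE]
  if (nrow(laser) == 0) stop("no laser events with a valid phase", call. = FALSE)
  classes <- c("swallow", "laryngeal_activation", "no_response")
  out <- do.call(rbind, lapply(classes, function(cl) {
    curve <- bin_curve(laser$respiratory_phase,
                       as.numeric(laser$class == cl), n_bins)
    data.frame(class = cl, bin = curve$bin, center = curve$center,
               probability = curve$mean, n = curve$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Swallow-timing table and histogram
#'
#' For every swallow, the onset phase (inspiration onset to swallow onset,
#' divided by the containing cycle duration) and the onset time relative
#' to the inspiratory diaphragm peak (ms; negative = before the peak),
#' plus the 1/10-bin histogram of onset phases.
#'
#' @param events Event table from [classify_session()].
#' @param breaths Breath table.
#' @param trigger Which swallows to use (default laser-evoked).
#' @param n_bins Histogram bins.
#' @return A list: `samples` (per-swallow table) and `histogram` (counts
#'   per phase bin).
#' @export
swallow_timing <- function(events, breaths, trigger = "laser", n_bins = 10) {
  sw <- events[events$class == "swallow" & events$trigger %in% trigger &
                 is.finite(events$submental_onset), , drop = FALSE]
  onset_phase <- rep(NA_real_, nrow(sw))
  rel_peak <- rep(NA_real_, nrow(sw))
  for (i in seq_len(nrow(sw))) {
    o <- sw$submental_onset[i]
    idx <- findInterval(o, breaths$insp_onset)
    if (idx < 1 || o >= breaths$next_insp_onset[idx]) next
    onset_phase[i] <- (o - breaths$insp_onset[idx]) / breaths$cycle_duration[idx]
    rel_peak[i] <- (o - breaths$insp_peak_time[idx]) * 1000
  }
  keep <- is.finite(onset_phase)
  if (any(!keep)) message(sum(!keep), " swallow(s) outside any breath excluded")
  samples <- data.frame(
    event_id = sw$event_id[keep],
    onset_phase = onset_phase[keep],
    onset_rel_insp_peak_ms = rel_peak[keep],
    stringsAsFactors = FALSE
  )
  hist <- if (nrow(samples)) {
    curve <- bin_curve(samples$onset_phase, samples$onset_phase, n_bins)
    data.frame(bin = curve$bin, lo = curve$lo, hi = curve$hi,
               center = curve$center, count = curve$n)
  } else {
    data.frame(bin = seq_len(n_bins), lo = (seq_len(n_bins) - 1) / n_bins,
               hi = seq_len(n_bins) / n_bins,
               center = (seq_len(n_bins) - 0.5) / n_bins,
               count = rep(0, n_bins))
  }
  list(samples = samples, histogram = hist)
}

#' Reset regression for one response group
#'
#' Pearson correlation and simple linear regression of the phase shift on
#' the respiratory phase for the swallow or non-swallow group, with the
#' two-sided p-value from the t-distribution on n - 2 degrees of freedom.
#'
#' @param samples Phase-sample table from [phase_samples()].
#' @param group `"swallow"` or `"non_swallow"`.
#' @return A list: `r`, `slope`, `intercept`, `p`, `n`.
#' @export
reset_correlation <- function(samples, group = c("swallow", "non_swallow")) {
  group <- match.arg(group)
  s <- samples[samples$group == group, , drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 samples in group '", group, "'", call. = FALSE)
  x <- s$respiratory_phase
  y <- s$phase_shift
  if (stats::sd(x) == 0) {
    stop("zero variance in respiratory phase; correlation undefined", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    # a constant shift carries no reset: the regression is flat and the
    # correlation coefficient is undefined
    return(list(r = NA_real_, slope = 0, intercept = y[1], p = NA_real_,
                n = nrow(s)))
  }
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), p = ct$p.value, n = nrow(s))
}
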