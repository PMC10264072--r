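# End-to-end analysis of one recording: condition every channel, detect
# bursts, segment breaths, classify all stimuli and water boluses, and
# compute the phase/reset statistics.

EMG_CHANNELS <- c("diaphragm", "submental", "laryngeal", "xii", "x")

#' Analyze a recording end to end
#'
#' Runs the full chain on a `pico_recording`: zero-phase band-pass, ECG
#' artifact excision (using the `ecg` reference channel when present),
#' rectify-smooth envelopes, burst detection with robust baselines, breath
#' segmentation (with Schluckatmung bursts removed from the rhythmic
#' train), control-cycle flagging, behavior classification with all
#' swallow metrics, phase samples, probability curves, binned phase-shift
#' curves, swallow-timing histograms, and the per-group reset regressions.
#' The analysis is deterministic: repeated runs on the same recording give
#' identical outputs.
#'
#' @param rec A `pico_recording`.
#' @param params A `pico_params` from [analysis_params()].
#' @return A list of class `pico_analysis`: `events`, `bursts`, `breaths`,
#'   `phase_samples`, `probability`, `shift_curves`, `timing`, `reset`,
#'   `baseline`, `params`.
#' @export
analyze_recording <- function(rec, params = analysis_params()) {
  validate_recording(rec)
  fs <- rec$sampling_rate
  ref <- rec$channels$ecg

  burst_list <- list()
  for (ch in intersect(names(rec$channels), EMG_CHANNELS)) {
    x <- rec$channels[[ch]]
    # excise the artifact before filtering: the compact ECG spike would
    # otherwise be smeared over the FIR kernel length and escape the
    # excision epochs
    if (params$ecg_removal) {
      x <- remove_ecg(x, fs, reference = ref)$signal
    }
    x <- bandpass_filter(x, fs,
                         low = params$bandpass_low,
                         high = params$bandpass_high,
                         transition = params$bandpass_transition)
    env <- rectify_smooth(x, fs, window_ms = params$smooth_ms, channel = ch)
    burst_list[[ch]] <- detect_bursts(
      env,
      k_onset = params$k_onset, k_offset = params$k_offset,
      min_duration_ms = params$min_duration_ms,
      min_gap_ms = params$min_gap_ms, channel = ch
    )
  }
  bursts <- do.call(rbind, burst_list)
  rownames(bursts) <- NULL

  # Schluckatmung bursts (diaphragm activity inside a swallow-related
  # submental burst) are not rhythmic inspirations: drop them from the
  # breath train before segmenting.
  dia <- burst_list$diaphragm
  sub_ch <- if ("submental" %in% names(burst_list)) "submental" else "xii"
  sub <- burst_list[[sub_ch]]
  is_schluck <- rep(FALSE, nrow(dia))
  if (nrow(sub) > 0 && nrow(dia) > 0) {
    for (j in seq_len(nrow(sub))) {
      is_schluck <- is_schluck |
        (dia$onset >= sub$onset[j] & dia$onset <= sub$offset[j])
    }
  }
  schluck_bursts <- dia[is_schluck, , drop = FALSE]
  breaths <- segment_breaths(dia[!is_schluck, , drop = FALSE])
  flagged <- exclude_perturbed_breaths(breaths, rec$stimuli, rec$water_events)
  breaths <- flagged$breaths

  events <- classify_session(rec, bursts, breaths, schluck_bursts, params)
  events$respiratory_phase <- respiratory_phase(events$stim_onset, breaths)
  events$phase_shift <- phase_shift(events$stim_onset, breaths)

  samples <- phase_samples(events, breaths)
  prob <- probability_curves(events, n_bins = params$n_bins)
  shift_curves <- do.call(rbind, lapply(c("swallow", "non_swallow"), function(g) {
    s <- samples[samples$group == g, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    curve <- bin_curve(s$respiratory_phase, s$phase_shift, params$n_bins)
    cbind(group = g, curve)
  }))
  timing <- swallow_timing(events, breaths, n_bins = params$n_bins)
  reset <- list()
  for (g in c("swallow", "non_swallow")) {
    reset[[g]] <- tryCatch(reset_correlation(samples, g), error = function(e) NULL)
  }

  structure(
    list(events = events, bursts = bursts, breaths = breaths,
         phase_samples = samples, probability = prob,
         shift_curves = shift_curves, timing = timing, reset = reset,
         baseline = attr(events, "baseline"), params = params),
    class = "pico_analysis"
  )
}

#' @export
print.pico_analysis <- function(x, ...) {
  tab <- table(x$events$class[x$events$trigger == "laser"])
  cat("pico_analysis\n")
  cat(sprintf("  laser responses: %s\n",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  sw <- x$events$swallow_duration_ms[x$events$class == "swallow" &
                                       x$events$trigger == "laser" &
                                       !x$events$atypical]
  if (length(sw)) {
    cat(sprintf("  laser swallow duration: %.0f +/- %.0f ms (n=%d)\n",
                mean(sw), stats::sd(sw), length(sw)))
  }
  for (g in names(x$reset)) {
    r <- x$reset[[g]]
    if (!is.null(r)) {
      cat(sprintf("  reset %s: r=%.2f slope=%.2f p=%.2g (n=%d)\n",
                  g, r$r, r$slope, r$p, r$n))
    }
  }
  invisible(x)
}

#' Write all analysis tables as CSV
#'
#' Writes `events.csv`, `bursts.csv`, `breaths.csv`, `phase_samples.csv`,
#' `probability_curves.csv`, `phase_shift_curves.csv`,
#' `swallow_timing.csv`, `swallow_histogram.csv`, `reset_stats.csv` into
#' `path`. Output is deterministic (byte-identical for identical input).
#'
#' @param analysis A `pico_analysis`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_analysis <- function(analysis, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
  put <- function(df, name) write_events_table(df, file.path(path, name))
  put(analysis$events, "events.csv")
  put(analysis$bursts, "bursts.csv")
  put(analysis$breaths, "breaths.csv")
  put(analysis$phase_samples, "phase_samples.csv")
  put(analysis$probability, "probability_curves.csv")
  put(analysis$shift_curves, "phase_shift_curves.csv")
  put(analysis$timing$samples, "swallow_timing.csv")
  put(analysis$timing$histogram, "swallow_histogram.csv")
  rs <- do.call(rbind, lapply(names(analysis$reset), function(g) {
    r <- analysis$reset[[g]]
    if (is.null(r)) return(NULL)
    data.frame(group = g, r = r$r, slope = r$slope, intercept = r$intercept,
               p = r$p, n = r$n)
  }))
  if (!is.null(rs)) put(rs, "reset_stats.csv")
  invisible(path)
}

#' Simulate and analyze one session
#'
#' Convenience wrapper: generate a synthetic session and run the full
#' analysis on it.
#'
#' @param config A `pico_config`.
#' @param params A `pico_params`.
#' @return A list: `recording`, `ground_truth`, `analysis`.
#' @export
simulate_session <- function(config = generator_config(),
                             params = analysis_params()) {
  sess <- generate_recording(config)
  analysis <- analyze_recording(sess$recording, params)
  list(recording = sess$recording, ground_truth = sess$ground_truth,
       analysis = analysis)
}
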