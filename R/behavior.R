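# Stimulus-response classification and swallow-related metric extraction.
#
# Behavior definitions follow the published criteria: a swallow is a
# delayed response outlasting the laser with submental-then-laryngeal peak
# order; a laryngeal activation is laryngeal activity locked to the pulse
# (onset to offset of the laser) with no diaphragm activity during the
# pulse; anything else is no response. Responses matching neither template
# fully (e.g. reversed peak order) are kept as no_response with an
# "atypical" flag and excluded from swallow/laryngeal statistics.

burst_subset <- function(bursts, ch) {
  bursts[bursts$channel == ch, , drop = FALSE]
}

#' Classify one stimulus response
#'
#' Ordered decision rule over the detected bursts in the response window
#' `[stim onset, stim offset + response_horizon]`:
#' 1. swallow - a submental (or XII fallback) burst and a laryngeal burst
#'    occur in the window, the laryngeal offset exceeds the laser offset by
#'    `outlast_margin_ms`, and the laryngeal peak follows the submental
#'    peak (positive swallow sequence);
#' 2. laryngeal activation - a laryngeal burst starts within
#'    `onset_tolerance_ms` of laser onset, ends within `lock_tolerance_ms`
#'    of laser offset, and no diaphragm burst starts during the pulse;
#' 3. otherwise no response; partial matches get `atypical = TRUE`.
#'
#' @param stim_onset Laser onset, s.
#' @param stim_duration_ms Laser pulse duration, ms.
#' @param bursts Burst data.frame (all channels, from [detect_bursts()]).
#' @param params A `pico_params`.
#' @param swallow_channel Channel carrying the swallow burst: `"submental"`,
#'   or `"xii"` when the submental muscles are unavailable.
#' @param claimed Optional character vector of burst keys already assigned
#'   to earlier stimuli (see [classify_session()]).
#' @return A list: `class`, `atypical`, and the matched `sub` / `lar`
#'   burst rows (or `NULL`).
#' @export
classify_response <- function(stim_onset, stim_duration_ms, bursts, params,
                              swallow_channel = "submental",
                              claimed = character()) {
  if (!swallow_channel %in% bursts$channel &&
      !swallow_channel %in% c("submental", "xii")) {
    stop("missing required channel: ", swallow_channel, call. = FALSE)
  }
  off <- stim_onset + stim_duration_ms / 1000
  win_end <- off + params$response_horizon_ms / 1000
  b_sub <- burst_subset(bursts, swallow_channel)
  b_lar <- burst_subset(bursts, "laryngeal")
  b_dia <- burst_subset(bursts, "diaphragm")

  key <- function(df, i) paste(df$channel[i], df$onset[i])
  candidates <- function(df, lo, hi) {
    idx <- which(df$onset >= lo & df$onset <= hi)
    if (length(idx) == 0) return(integer())
    free <- idx[!(key(df, idx) %in% claimed)]
    if (length(free) == 0) {
      warning("candidate burst already assigned to an earlier stimulus")
    }
    free
  }

  sub_idx <- candidates(b_sub, stim_onset - params$onset_tolerance_ms / 1000,
                        win_end)
  lar_idx <- candidates(b_lar, stim_onset - params$onset_tolerance_ms / 1000,
                        win_end)

  # rule 1: first submental/laryngeal pair (in time order) with the
  # laryngeal burst outlasting the pulse and the peaks in swallow order
  for (si in sub_idx) {
    for (li in lar_idx) {
      if (b_lar$offset[li] > off + params$outlast_margin_ms / 1000 &&
          b_lar$peak_time[li] - b_sub$peak_time[si] > 0) {
        return(list(class = "swallow", atypical = FALSE,
                    sub = b_sub[si, , drop = FALSE],
                    lar = b_lar[li, , drop = FALSE]))
      }
    }
  }
  # rule 2: any laryngeal burst locked to the pulse, with a silent
  # diaphragm during the pulse
  dia_in_stim <- nrow(b_dia) > 0 &&
    any(b_dia$onset >= stim_onset & b_dia$onset <= off)
  if (!dia_in_stim) {
    for (li in lar_idx) {
      if (abs(b_lar$onset[li] - stim_onset) <= params$onset_tolerance_ms / 1000 &&
          b_lar$offset[li] <= off + params$lock_tolerance_ms / 1000) {
        return(list(class = "laryngeal_activation", atypical = FALSE,
                    sub = NULL, lar = b_lar[li, , drop = FALSE]))
      }
    }
  }
  atypical <- length(sub_idx) > 0 || length(lar_idx) > 0
  list(class = "no_response", atypical = atypical,
       sub = if (length(sub_idx)) b_sub[sub_idx[1], , drop = FALSE] else NULL,
       lar = if (length(lar_idx)) b_lar[lar_idx[1], , drop = FALSE] else NULL)
}

#' Swallow-related metrics for one classified swallow
#'
#' Computes the published swallow metrics: swallow duration (submental
#' onset to termination, XII fallback), swallow sequence (laryngeal peak
#' minus submental peak, positive for the normal rostrocaudal order),
#' Schluckatmung duration (swallow-related diaphragm burst, when present),
#' and inspiratory delay (swallow-related laryngeal offset to the onset of
#' the subsequent breath).
#'
#' @param sub Matched submental (or XII) burst row.
#' @param lar Matched laryngeal burst row, or `NULL`.
#' @param schluck_bursts Diaphragm bursts identified as swallow-related
#'   (Schluckatmung), not rhythmic inspirations.
#' @param breaths Breath table from [segment_breaths()].
#' @return A list of metrics in ms (`NA` where not computable).
#' @export
measure_swallow <- function(sub, lar = NULL, schluck_bursts = NULL,
                            breaths = NULL) {
  out <- list(
    swallow_duration_ms = (sub$offset - sub$onset) * 1000,
    swallow_sequence_ms = NA_real_,
    schluckatmung_duration_ms = NA_real_,
    inspiratory_delay_ms = NA_real_
  )
  if (!is.null(lar)) {
    out$swallow_sequence_ms <- (lar$peak_time - sub$peak_time) * 1000
    if (!is.null(breaths)) {
      nxt <- breaths$insp_onset[breaths$insp_onset > lar$offset]
      if (length(nxt) == 0) {
        last_next <- breaths$next_insp_onset[nrow(breaths)]
        if (last_next > lar$offset) nxt <- last_next
      }
      if (length(nxt)) out$inspiratory_delay_ms <- (min(nxt) - lar$offset) * 1000
    }
  }
  if (!is.null(schluck_bursts) && nrow(schluck_bursts) > 0) {
    hit <- schluck_bursts$onset >= sub$onset - 0.02 &
      schluck_bursts$onset <= sub$offset
    if (any(hit)) {
      out$schluckatmung_duration_ms <- schluck_bursts$duration_ms[which(hit)[1]]
    }
  }
  out
}

#' Per-channel baseline (water-swallow) amplitudes
#'
#' The "% of max" amplitude scale is defined per channel as the maximum
#' burst peak amplitude over the water-evoked swallows in the session. A
#' session with no water swallow on a channel cannot be normalized and is
#' flagged, with amplitudes left in a.u.
#'
#' @param water_events Event data.frame rows with `trigger == "water"` and
#'   `class == "swallow"`, carrying `<channel>_amp` columns.
#' @param channels Channel names to normalize.
#' @return A list: `amps` (named maxima, a.u., `NA` where unavailable) and
#'   `no_baseline` (channels without a water swallow).
#' @export
compute_baseline <- function(water_events, channels = c("submental", "laryngeal")) {
  amps <- vapply(channels, function(ch) {
    col <- paste0(ch, "_amp")
    if (!col %in% names(water_events)) return(NA_real_)
    v <- water_events[[col]][water_events$class == "swallow"]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else max(v)
  }, numeric(1))
  list(amps = amps, no_baseline = channels[!is.finite(amps)])
}

#' Classify every stimulus and water bolus in a session
#'
#' Runs [classify_response()] over the laser train and the water boluses,
#' extracts the swallow metrics, and normalizes burst amplitudes to the
#' session's water-swallow baseline ("% of max"). Bursts claimed by an
#' earlier stimulus are not reused.
#'
#' @param rec A `pico_recording`.
#' @param bursts Combined burst data.frame (all channels).
#' @param breaths Breath table from [segment_breaths()] (rhythmic
#'   inspirations only).
#' @param schluck_bursts Diaphragm bursts identified as Schluckatmung.
#' @param params A `pico_params`.
#' @return data.frame, one row per event, with class, flags, all swallow
#'   metrics (ms), per-channel durations and amplitudes (a.u. and % of
#'   max), ready for [write_events_table()].
#' @export
classify_session <- function(rec, bursts, breaths, schluck_bursts = NULL,
                             params = analysis_params()) {
  swallow_channel <- if ("submental" %in% names(rec$channels)) "submental" else "xii"
  claimed <- character()
  rows <- list()

  describe <- function(event_id, trigger, onset, dur_ms, res) {
    sub <- res$sub
    lar <- res$lar
    met <- if (res$class == "swallow") {
      measure_swallow(sub, lar, schluck_bursts, breaths)
    } else {
      list(swallow_duration_ms = NA_real_, swallow_sequence_ms = NA_real_,
           schluckatmung_duration_ms = NA_real_, inspiratory_delay_ms = NA_real_)
    }
    list(
      event_id = event_id, trigger = trigger, class = res$class,
      atypical = res$atypical, stim_onset = onset, stim_duration_ms = dur_ms,
      swallow_duration_ms = met$swallow_duration_ms,
      swallow_sequence_ms = met$swallow_sequence_ms,
      schluckatmung_duration_ms = met$schluckatmung_duration_ms,
      inspiratory_delay_ms = met$inspiratory_delay_ms,
      laryngeal_duration_ms = if (!is.null(lar) && res$class != "no_response")
        lar$duration_ms else NA_real_,
      submental_onset = if (!is.null(sub) && res$class == "swallow")
        sub$onset else NA_real_,
      submental_duration_ms = if (!is.null(sub) && res$class == "swallow")
        sub$duration_ms else NA_real_,
      submental_amp = if (!is.null(sub) && res$class == "swallow")
        sub$peak_amplitude else NA_real_,
      laryngeal_amp = if (!is.null(lar) && res$class != "no_response")
        lar$peak_amplitude else NA_real_
    )
  }

  claim <- function(res) {
    for (b in list(res$sub, res$lar)) {
      if (!is.null(b)) claimed <<- c(claimed, paste(b$channel, b$onset))
    }
  }

  if (nrow(rec$stimuli) > 0) {
    for (k in seq_len(nrow(rec$stimuli))) {
      on <- rec$stimuli$onset[k]
      d <- rec$stimuli$duration_ms[k]
      res <- classify_response(on, d, bursts, params,
                               swallow_channel = swallow_channel,
                               claimed = claimed)
      if (res$class != "no_response") claim(res)
      rows[[length(rows) + 1L]] <-
        describe(sprintf("S%03d", k), "laser", on, d, res)
    }
  }
  if (length(rec$water_events) > 0) {
    for (k in seq_along(rec$water_events)) {
      on <- rec$water_events[k]
      # a bolus has no pulse to outlast: treat it as a zero-length stimulus
      # with the water response window
      p2 <- params
      p2$response_horizon_ms <- params$water_horizon_ms
      p2$outlast_margin_ms <- -1e6  # outlast condition vacuous for water
      res <- classify_response(on, 1e-6, bursts, p2,
                               swallow_channel = swallow_channel,
                               claimed = claimed)
      if (res$class == "laryngeal_activation") {
        # laryngeal-only activity without a pulse is not a swallow
        res <- list(class = "no_response", atypical = TRUE,
                    sub = NULL, lar = res$lar)
      }
      if (res$class != "no_response") claim(res)
      rows[[length(rows) + 1L]] <-
        describe(sprintf("W%03d", k), "water", on, NA_real_, res)
    }
  }
  events <- as.data.frame(data.table::rbindlist(rows))

  wdf <- events[events$trigger == "water", , drop = FALSE]
  wdf[[paste0(swallow_channel, "_amp")]] <- wdf$submental_amp
  bl <- compute_baseline(wdf, channels = c(swallow_channel, "laryngeal"))
  events$submental_amp_pct <- if (is.finite(bl$amps[[swallow_channel]])) {
    events$submental_amp / bl$amps[[swallow_channel]] * 100
  } else NA_real_
  events$laryngeal_amp_pct <- if (is.finite(bl$amps[["laryngeal"]])) {
    events$laryngeal_amp / bl$amps[["laryngeal"]] * 100
  } else NA_real_
  attr(events, "baseline") <- bl
  attr(events, "swallow_channel") <- swallow_channel
  events
}
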