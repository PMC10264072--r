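# Seeded synthetic multi-channel session generator with ground truth.
#
# A session emulates the statistical structure of an anesthetized-mouse
# recording: rhythmic diaphragm bursts at the breathing period, a water
# bolus block followed by the randomized laser protocol, phase-dependent
# evoked behaviors (all-or-none swallows vs. laser-locked laryngeal
# activation), ECG spikes on every channel, and broadband noise. The
# generator keeps exact per-event ground truth so the analysis chain can
# be scored against known labels.

#' Render one motor burst as a waveform segment
#'
#' Bursts are amplitude-modulated band-limited oscillations: the default
#' carrier is a constant-modulus frequency-modulated cosine whose
#' instantaneous frequency hops randomly within 300-600 Hz, so the
#' 200-700 Hz analysis band-pass retains the burst while its
#' rectified-smoothed envelope tracks the designed shape with negligible
#' stochastic ripple (real swallow EMG has similarly well-defined peak
#' timing). The envelope is a tapered plateau (raised-cosine ramps)
#' carrying a peak at `peak_frac` of the duration, so onset and offset
#' stay sharp while the peak time is well defined. A deterministic
#' `"tone"` carrier (450 Hz cosine) is available for timing tests.
#'
#' Draws from the current RNG stream; seed upstream for reproducibility.
#'
#' @param duration_ms Burst duration in ms (> 0).
#' @param amplitude Carrier amplitude, a.u. (0 gives a flat segment).
#' @param sampling_rate Sampling rate, Hz.
#' @param peak_frac Peak position as a fraction of the duration.
#' @param ramp_ms Raised-cosine attack and decay ramps, ms; a length-2
#'   vector `c(attack, decay)` or a single value for both. The defaults
#'   mimic the gradual recruitment/derecruitment of motor units and place
#'   the threshold-crossing edges of the smoothed envelope on the nominal
#'   burst support.
#' @param bump Relative height of the peak above the plateau.
#' @param carrier `"noise"` (default) or `"tone"`.
#' @param carrier_band Frequency band of the noise carrier, Hz.
#' @return Numeric vector of `round(duration_ms / 1000 * sampling_rate)`
#'   samples; energy is confined to the burst interval.
#' @export
render_burst <- function(duration_ms, amplitude, sampling_rate,
                         peak_frac = 0.5, ramp_ms = c(15, 25), bump = 0.3,
                         carrier = c("noise", "tone"),
                         carrier_band = c(300, 600)) {
  if (duration_ms <= 0) stop("burst duration must be positive", call. = FALSE)
  carrier <- match.arg(carrier)
  d <- duration_ms / 1000
  n <- max(round(d * sampling_rate), 2L)
  t <- (seq_len(n) - 1) / sampling_rate
  ramp_ms <- rep(ramp_ms, length.out = 2)
  r1 <- ramp_ms[1] / 1000
  r2 <- ramp_ms[2] / 1000
  if (r1 + r2 > 0.8 * d) {
    shrink <- 0.8 * d / (r1 + r2)
    r1 <- r1 * shrink
    r2 <- r2 * shrink
  }
  env <- rep(1, n)
  attack <- t < r1
  env[attack] <- 0.5 * (1 - cos(pi * t[attack] / r1))
  decay <- t > d - r2
  env[decay] <- 0.5 * (1 - cos(pi * (d - t[decay]) / r2))
  tp <- min(max(peak_frac * d, r1), d - r2)
  w <- min(0.35 * d, 0.08)
  near <- abs(t - tp) < w
  env[near] <- env[near] * (1 + bump * 0.5 * (1 + cos(pi * (t[near] - tp) / w)))
  if (carrier == "tone") {
    x <- cos(2 * pi * 450 * t)
  } else {
    # frequency-modulated cosine: frequency redrawn every 10 ms
    n_seg <- max(ceiling(d / 0.010), 1L)
    f_seg <- stats::runif(n_seg, carrier_band[1], carrier_band[2])
    f_inst <- f_seg[pmin(floor(t / 0.010) + 1L, n_seg)]
    phase <- 2 * pi * cumsum(f_inst) / sampling_rate +
      stats::runif(1, 0, 2 * pi)
    x <- cos(phase)
  }
  amplitude * env * x
}

# biphasic ECG spike template, unit peak, ~8 ms support
ecg_template <- function(sampling_rate, sigma_ms = 0.6, width_ms = 8) {
  tt <- seq(-width_ms / 2, width_ms / 2, by = 1000 / sampling_rate) / 1000
  sg <- sigma_ms / 1000
  g <- -(tt / sg) * exp(-tt^2 / (2 * sg^2))
  g / max(abs(g))
}

#' Schedule laser pulses at random respiratory phases
#'
#' Each pulse duration appears exactly `pulses_per_duration` times, the
#' order is shuffled, and each pulse is dropped at an independently
#' uniform respiratory phase of a breath, skipping breaths where it would
#' overlap the previous pulse. Draws from the current RNG stream.
#'
#' @param breath_onsets Numeric vector of inspiratory onsets, s (>= 2).
#' @param config A `pico_config`; only the pulse protocol fields are used.
#' @param min_gap_s Minimum gap between consecutive pulses, s.
#' @return data.frame of stimulus events: `onset` (s), `duration_ms`,
#'   `phase` (the drawn phase in [0, 1)), `breath` (1-based index).
#' @export
schedule_stimuli <- function(breath_onsets, config, min_gap_s = 0.05) {
  if (length(breath_onsets) < 2) {
    stop("need at least 2 breath onsets to schedule stimuli", call. = FALSE)
  }
  durations <- sample(rep(config$pulse_durations, config$pulses_per_duration))
  n_pulses <- length(durations)
  periods <- diff(breath_onsets)
  onset <- numeric(n_pulses)
  phase <- numeric(n_pulses)
  breath <- integer(n_pulses)
  k <- 1L
  last_off <- -Inf
  for (b in seq_along(periods)) {
    if (k > n_pulses) break
    phi <- stats::runif(1)
    s0 <- breath_onsets[b] + phi * periods[b]
    if (s0 > last_off + min_gap_s) {
      onset[k] <- s0
      phase[k] <- phi
      breath[k] <- b
      last_off <- s0 + durations[k] / 1000
      k <- k + 1L
    }
  }
  if (k <= n_pulses) {
    stop("session too short to place all pulses (capacity error)", call. = FALSE)
  }
  data.frame(onset = onset, duration_ms = durations, phase = phase,
             breath = breath)
}

# draw the behavior class for a phase from the policy table
draw_class <- function(phi, policy) {
  row <- which(phi >= policy$phase_lo & phi < policy$phase_hi)
  if (length(row) == 0) row <- nrow(policy)  # phi == 1 boundary
  p <- unlist(policy[row[1], c("swallow", "laryngeal_activation", "no_response")])
  sample(names(p), 1, prob = p)
}

# draw swallow burst geometry for one evoked or water swallow
make_swallow <- function(s0, stim_off, cfg, water = FALSE) {
  if (water) {
    lat <- max(stats::rnorm(1, cfg$water_latency_mean, cfg$water_latency_sd), 20) / 1000
    lp <- lnorm_params(cfg$water_swallow_duration_mean, cfg$water_swallow_duration_sd)
    af <- stats::rnorm(1, cfg$water_swallow_amp_mean, cfg$water_swallow_amp_sd)
    af <- min(max(af, 0.3), 1.0)
  } else {
    lat <- max(stats::rnorm(1, cfg$swallow_latency_mean, cfg$swallow_latency_sd), 10) / 1000
    lp <- lnorm_params(cfg$swallow_duration_mean, cfg$swallow_duration_sd)
    af <- max(stats::rnorm(1, cfg$laser_swallow_amp_mean, cfg$laser_swallow_amp_sd),
              cfg$laser_swallow_amp_min)
  }
  dur <- stats::rlnorm(1, lp$meanlog, lp$sdlog) / 1000
  sub_on <- s0 + lat
  sub_off <- sub_on + dur
  sub_peak <- sub_on + 0.4 * dur
  seqd <- max(stats::rnorm(1, cfg$swallow_sequence_delay_mean,
                           cfg$swallow_sequence_delay_sd), 10) / 1000
  lar_dur <- dur * min(max(stats::rnorm(1, 1.05, 0.08), 0.7), 1.4)
  lar_peak <- sub_peak + seqd
  lar_on <- max(lar_peak - 0.45 * lar_dur, sub_on + 0.005)
  lar_off <- lar_on + lar_dur
  if (!is.null(stim_off)) {
    # airway protection outlasts the pulse: the laryngeal burst must end
    # comfortably after laser offset even for long pulses
    min_off <- stim_off + 0.06
    if (lar_off < min_off) lar_off <- min_off
  }
  amp <- cfg$amplitude
  list(
    sub_on = sub_on, sub_off = sub_off, sub_peak = sub_peak,
    sub_amp = amp[["submental"]] * af * stats::rnorm(1, 1, 0.05),
    lar_on = lar_on, lar_off = lar_off, lar_peak = lar_peak,
    lar_amp = amp[["laryngeal"]] * af * stats::rnorm(1, 1, 0.05),
    duration_ms = dur * 1000,
    schluck = stats::runif(1) < cfg$schluckatmung_prob && !water
  )
}

#' Generate a synthetic session with ground truth
#'
#' Builds the breath train, delivers the water bolus block and the
#' randomized laser protocol, draws per-stimulus behaviors from the phase
#' policy, renders all channels (bursts + ECG + noise), and returns the
#' `pico_recording` together with exact per-event ground truth. Identical
#' config and seed produce bit-identical output.
#'
#' Behavioral structure: swallows are all-or-none (duration drawn
#' independently of the pulse duration) and, with `reset_policy`, reset
#' the rhythm so the next inspiration starts `swallow_ibi` after the
#' swallow-related laryngeal offset; laryngeal activations start and stop
#' with the pulse (duration = pulse duration times
#' `laryngeal_response_gain` plus edge jitter) and leave the rhythm
#' untouched; a pulse that would clip the next inspiratory onset cannot
#' produce the diaphragm-silent laryngeal pattern and yields no response;
#' no-response trials render nothing.
#'
#' @param config A `pico_config` from [generator_config()].
#' @return A list with `recording` (a `pico_recording`) and
#'   `ground_truth` (a `pico_ground_truth`: `$events` one row per
#'   stimulus/bolus, `$breaths`, `$ecg_times`, `$config`).
#' @export
generate_recording <- function(config) {
  validate_config(config)
  cfg <- config
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  fs <- cfg$sampling_rate
  n <- round(cfg$session_duration * fs)
  n_pulses <- length(cfg$pulse_durations) * cfg$pulses_per_duration
  durations_ms <- sample(rep(cfg$pulse_durations, cfg$pulses_per_duration))
  W <- cfg$water_bolus_count

  water_breaths <- if (W > 0) seq(3L, by = 2L, length.out = W) else integer()
  laser_start <- if (W > 0) max(water_breaths) + 3L else 3L
  laser_breaths <- if (n_pulses > 0) {
    seq(laser_start, by = 2L, length.out = n_pulses)
  } else integer()

  # per-channel burst lists: onset, dur, amp, peak (absolute s)
  bursts <- list(diaphragm = list(), submental = list(), laryngeal = list())
  add_burst <- function(ch, onset, dur, amp, peak) {
    bursts[[ch]][[length(bursts[[ch]]) + 1L]] <<-
      list(onset = onset, dur = dur, amp = amp, peak = peak)
  }

  events <- list()
  gt_breaths <- list()
  t <- 0.5
  i <- 1L
  k_l <- 0L
  k_w <- 0L
  horizon <- cfg$session_duration - 1.2

  while (t < horizon) {
    p <- max(stats::rnorm(1, cfg$breath_period_mean,
                          cfg$breath_period_cv * cfg$breath_period_mean),
             0.4 * cfg$breath_period_mean)
    dia_dur <- max(stats::rnorm(1, cfg$insp_burst_duration, 0.01), 0.05)
    dia_amp <- cfg$amplitude[["diaphragm"]] * max(stats::rnorm(1, 1, 0.05), 0.5)
    next_t <- t + p

    ev <- NULL
    if (k_l < n_pulses && length(laser_breaths) && i == laser_breaths[k_l + 1L]) {
      k_l <- k_l + 1L
      phi <- stats::runif(1)
      d_ms <- durations_ms[k_l]
      s0 <- t + phi * p
      s_off <- s0 + d_ms / 1000
      cls <- draw_class(phi, cfg$behavior_policy)
      if (cls == "laryngeal_activation" && s_off + 0.05 > next_t) {
        # a pulse clipping the next inspiratory onset cannot produce the
        # diaphragm-silent, pulse-locked laryngeal pattern; such trials
        # yield no separable motor response and leave the rhythm alone
        cls <- "no_response"
      }
      ev <- list(event_id = sprintf("S%03d", k_l), trigger = "laser",
                 class = cls, stim_onset = s0, stim_duration_ms = d_ms,
                 phase = phi)
      if (cls == "swallow") {
        sw <- make_swallow(s0, s_off, cfg)
        add_burst("submental", sw$sub_on, sw$sub_off - sw$sub_on, sw$sub_amp, sw$sub_peak)
        add_burst("laryngeal", sw$lar_on, sw$lar_off - sw$lar_on, sw$lar_amp, sw$lar_peak)
        if (sw$sub_on < t + dia_dur) {
          # swallow interrupts the ongoing inspiration
          dia_dur <- max(sw$sub_on - t, 0.04)
        }
        if (sw$schluck) {
          sch_on <- sw$sub_on + 0.01
          sch_dur <- max(0.5 * (sw$sub_off - sw$sub_on), 0.04)
          add_burst("diaphragm", sch_on, sch_dur,
                    0.4 * cfg$amplitude[["diaphragm"]], sch_on + 0.5 * sch_dur)
          ev$dia_onset <- sch_on
          ev$dia_offset <- sch_on + sch_dur
        }
        ev <- c(ev, sw[c("sub_on", "sub_off", "sub_peak", "sub_amp",
                         "lar_on", "lar_off", "lar_peak", "lar_amp",
                         "duration_ms")])
        ev$laryngeal_duration_ms <- (sw$lar_off - sw$lar_on) * 1000
        if (cfg$reset_policy) {
          next_t <- sw$lar_off + max(stats::rnorm(1, cfg$swallow_ibi,
                                                  cfg$swallow_ibi_sd), 0.1)
          ev$reset <- TRUE
        }
      } else if (cls == "laryngeal_activation") {
        lar_on <- s0 + stats::runif(1, 0.002, cfg$laryngeal_onset_jitter_ms / 1000 + 0.005)
        ldur <- max(d_ms / 1000 * cfg$laryngeal_response_gain +
                      stats::rnorm(1, 0, cfg$laryngeal_offset_jitter_ms / 1000), 0.02)
        lar_off <- lar_on + ldur
        la <- cfg$amplitude[["laryngeal"]] *
          max(stats::rnorm(1, cfg$laryngeal_act_amp_mean, cfg$laryngeal_act_amp_sd), 0.2)
        add_burst("laryngeal", lar_on, ldur, la, lar_on + 0.5 * ldur)
        ev$lar_on <- lar_on
        ev$lar_off <- lar_off
        ev$lar_peak <- lar_on + 0.5 * ldur
        ev$lar_amp <- la
        ev$laryngeal_duration_ms <- ldur * 1000
      }
    } else if (k_w < W && length(water_breaths) && i == water_breaths[k_w + 1L]) {
      k_w <- k_w + 1L
      bolus <- t + stats::runif(1, 0.1, 0.5) * p
      ev <- list(event_id = sprintf("W%03d", k_w), trigger = "water",
                 stim_onset = bolus, stim_duration_ms = NA_real_,
                 phase = (bolus - t) / p)
      if (stats::runif(1) < cfg$water_swallow_prob) {
        sw <- make_swallow(bolus, NULL, cfg, water = TRUE)
        add_burst("submental", sw$sub_on, sw$sub_off - sw$sub_on, sw$sub_amp, sw$sub_peak)
        add_burst("laryngeal", sw$lar_on, sw$lar_off - sw$lar_on, sw$lar_amp, sw$lar_peak)
        if (sw$sub_on < t + dia_dur) dia_dur <- max(sw$sub_on - t, 0.04)
        ev$class <- "swallow"
        ev <- c(ev, sw[c("sub_on", "sub_off", "sub_peak", "sub_amp",
                         "lar_on", "lar_off", "lar_peak", "lar_amp",
                         "duration_ms")])
        ev$laryngeal_duration_ms <- (sw$lar_off - sw$lar_on) * 1000
        if (cfg$reset_policy) {
          next_t <- sw$lar_off + max(stats::rnorm(1, cfg$swallow_ibi,
                                                  cfg$swallow_ibi_sd), 0.1)
          ev$reset <- TRUE
        }
      } else {
        ev$class <- "no_response"
      }
    }

    add_burst("diaphragm", t, dia_dur, dia_amp, t + 0.75 * dia_dur)
    gt_breaths[[i]] <- list(insp_onset = t, insp_duration = dia_dur,
                            insp_peak_time = t + 0.75 * dia_dur)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
    t <- next_t
    i <- i + 1L
  }

  if (k_l < n_pulses || k_w < W) {
    stop(sprintf(
      "session too short to place all events (placed %d/%d pulses, %d/%d boluses); increase session_duration",
      k_l, n_pulses, k_w, W), call. = FALSE)
  }

  # ---- render channels -------------------------------------------------
  ch_names <- c("diaphragm", "submental", "laryngeal")
  if (cfg$include_xii) ch_names <- c(ch_names, "xii")
  if (cfg$include_x) ch_names <- c(ch_names, "x")
  channels <- lapply(ch_names, function(ch) stats::rnorm(n, 0, cfg$noise_sd))
  names(channels) <- ch_names

  # ENG channels mirror their muscle counterparts with independent gains
  if (cfg$include_xii) {
    bursts$xii <- lapply(bursts$submental, function(b) {
      b$amp <- b$amp / cfg$amplitude[["submental"]] * cfg$amplitude[["xii"]]
      b
    })
  }
  if (cfg$include_x) {
    bursts$x <- lapply(bursts$laryngeal, function(b) {
      b$amp <- b$amp / cfg$amplitude[["laryngeal"]] * cfg$amplitude[["x"]]
      b
    })
  }

  for (ch in names(bursts)) {
    if (!ch %in% names(channels)) next
    for (b in bursts[[ch]]) {
      if (b$dur <= 0) next
      seg <- render_burst((b$dur) * 1000, b$amp, fs,
                          peak_frac = (b$peak - b$onset) / b$dur)
      i0 <- round(b$onset * fs) + 1L
      i1 <- min(i0 + length(seg) - 1L, n)
      if (i0 > n || i1 < i0) next
      channels[[ch]][i0:i1] <- channels[[ch]][i0:i1] + seg[seq_len(i1 - i0 + 1L)]
    }
  }

  # ECG artifact on all channels + clean reference channel
  tmpl <- ecg_template(fs)
  ecg_base <- seq(0.2, cfg$session_duration - 0.1, by = 1 / cfg$ecg_rate)
  ecg_times <- ecg_base + stats::rnorm(length(ecg_base), 0, 0.002)
  ecg_times <- ecg_times[ecg_times > 0.05 & ecg_times < cfg$session_duration - 0.05]
  ecg_ref <- numeric(n)
  half <- (length(tmpl) - 1) %/% 2
  for (tt in ecg_times) {
    c0 <- round(tt * fs) + 1L
    i0 <- c0 - half
    i1 <- i0 + length(tmpl) - 1L
    if (i0 < 1L || i1 > n) next
    ecg_ref[i0:i1] <- ecg_ref[i0:i1] + tmpl
  }
  for (ch in names(channels)) {
    g <- cfg$ecg_channel_gain[[ch]]
    if (is.null(g) || is.na(g)) g <- 0.3
    channels[[ch]] <- channels[[ch]] + cfg$ecg_amplitude * g * ecg_ref
  }
  if (cfg$include_ecg_channel) {
    channels$ecg <- cfg$ecg_amplitude * ecg_ref + stats::rnorm(n, 0, 0.01)
  }

  stim_idx <- vapply(events, function(e) e$trigger == "laser", logical(1))
  stim_df <- if (any(stim_idx)) {
    data.frame(
      onset = vapply(events[stim_idx], `[[`, numeric(1), "stim_onset"),
      duration_ms = vapply(events[stim_idx], `[[`, numeric(1), "stim_duration_ms"),
      power_label = "0.75 mW",
      stringsAsFactors = FALSE
    )
  } else empty_stimuli()
  water_times <- vapply(events[!stim_idx], `[[`, numeric(1), "stim_onset")

  rec <- recording(
    channels = channels,
    sampling_rate = fs,
    stimuli = stim_df,
    water_events = as.numeric(water_times),
    metadata = list(genotype = cfg$genotype, seed = cfg$seed, units = "a.u.",
                    generator = "picoswallow")
  )

  gt_events <- data.table::rbindlist(lapply(events, function(e) {
    full <- list(event_id = NA_character_, trigger = NA_character_,
                 class = NA_character_, stim_onset = NA_real_,
                 stim_duration_ms = NA_real_, phase = NA_real_,
                 sub_on = NA_real_, sub_off = NA_real_, sub_peak = NA_real_,
                 sub_amp = NA_real_, lar_on = NA_real_, lar_off = NA_real_,
                 lar_peak = NA_real_, lar_amp = NA_real_,
                 dia_onset = NA_real_, dia_offset = NA_real_,
                 duration_ms = NA_real_, laryngeal_duration_ms = NA_real_,
                 reset = FALSE)
    full[names(e)] <- e
    full
  }))
  gt_events <- as.data.frame(gt_events)
  names(gt_events)[names(gt_events) == "duration_ms"] <- "swallow_duration_ms"

  gt <- structure(
    list(events = gt_events,
         breaths = as.data.frame(data.table::rbindlist(gt_breaths)),
         ecg_times = ecg_times,
         config = cfg),
    class = "pico_ground_truth"
  )
  list(recording = rec, ground_truth = gt)
}

#' @export
print.pico_ground_truth <- function(x, ...) {
  cat(sprintf("pico_ground_truth: %d events (%s), %d breaths\n",
              nrow(x$events),
              paste(names(table(x$events$class)), table(x$events$class),
                    sep = "=", collapse = ", "),
              nrow(x$breaths)))
  invisible(x)
}
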