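#' Default phase-dependent behavior policy
#'
#' The probability of each evoked behavior class as a function of the
#' respiratory phase at which the laser pulse arrives. Swallows dominate
#' during inspiration and early expiration, laryngeal activation dominates
#' late in expiration, and a no-motor-response outcome occurs everywhere at
#' a moderate rate. The paper reports the qualitative phase preference but
#' no per-bin rates, so the numbers here are generator defaults, not
#' literature values.
#'
#' @return A data.frame with columns `phase_lo`, `phase_hi`, `swallow`,
#'   `laryngeal_activation`, `no_response`. Rows partition `[0, 1]`; the
#'   three class probabilities in each row sum to 1.
#' @export
default_behavior_policy <- function() {
  data.frame(
    phase_lo = c(0.0, 0.3, 0.6),
    phase_hi = c(0.3, 0.6, 1.0),
    swallow = c(0.80, 0.50, 0.05),
    laryngeal_activation = c(0.05, 0.30, 0.70),
    no_response = c(0.15, 0.20, 0.25)
  )
}

#' Synthetic-session generator configuration
#'
#' Builds and validates the full parameter set for
#' [generate_recording()]. Defaults describe a ChATcre:Vglut2FlpO:ChR2-like
#' session: 0.7 s breathing period (CV 0.1), 5 kHz sampling, the standard
#' laser protocol of 25 pulses at each of 40/80/120/160/200 ms delivered at
#' random respiratory phases, 20 water boluses, laser-evoked swallow
#' durations of 114 +/- 19 ms and water-evoked durations of 191 +/- 63 ms.
#' Swallow and water-swallow durations are drawn from a lognormal
#' distribution moment-matched to the requested mean/SD so that durations
#' stay positive without biasing the mean.
#'
#' @param sampling_rate Sampling rate in Hz. Must be at least twice the
#'   700 Hz upper band-pass edge.
#' @param session_duration Session length in seconds.
#' @param breath_period_mean,breath_period_cv Mean respiratory cycle (s)
#'   and its coefficient of variation.
#' @param insp_burst_duration Diaphragm (inspiratory) burst duration in s.
#' @param pulse_durations Laser pulse durations in ms.
#' @param pulses_per_duration Number of pulses delivered per duration.
#' @param behavior_policy Phase-to-class probability table, see
#'   [default_behavior_policy()].
#' @param swallow_duration_mean,swallow_duration_sd Laser-evoked swallow
#'   (submental burst) duration mean/SD in ms.
#' @param water_swallow_duration_mean,water_swallow_duration_sd Water-evoked
#'   swallow duration mean/SD in ms.
#' @param swallow_latency_mean,swallow_latency_sd Submental onset latency
#'   after laser onset, ms.
#' @param water_latency_mean,water_latency_sd Submental onset latency after
#'   the water bolus, ms.
#' @param swallow_sequence_delay_mean,swallow_sequence_delay_sd Delay from
#'   submental to laryngeal peak activation (the swallow sequence), ms.
#' @param swallow_ibi,swallow_ibi_sd Post-swallow inspiratory delay: time
#'   from the swallow-related laryngeal offset to the next inspiratory
#'   onset when the rhythm is reset, s.
#' @param schluckatmung_prob Probability that a swallow carries a
#'   swallow-related diaphragm burst (Schluckatmung).
#' @param laryngeal_response_gain Laryngeal-activation burst duration as a
#'   multiple of the laser pulse duration.
#' @param laryngeal_onset_jitter_ms,laryngeal_offset_jitter_ms Jitter of
#'   the stimulus-locked laryngeal burst edges, ms.
#' @param laryngeal_act_amp_mean,laryngeal_act_amp_sd Amplitude factor of
#'   laryngeal-activation bursts (fraction of the channel amplitude).
#' @param laser_swallow_amp_mean,laser_swallow_amp_sd,laser_swallow_amp_min
#'   Amplitude factor of laser-evoked swallow bursts relative to the
#'   channel amplitude; the floor keeps every swallow detectable.
#' @param water_swallow_amp_mean,water_swallow_amp_sd Amplitude factor of
#'   water-evoked swallow bursts (these define the "% of max" baseline).
#' @param water_bolus_count Number of water boluses.
#' @param water_swallow_prob Probability that a bolus evokes a swallow.
#' @param amplitude Named numeric vector of per-channel amplitude scales
#'   (arbitrary units) for `diaphragm`, `submental`, `laryngeal`, `xii`, `x`.
#' @param ecg_rate Heart rate in Hz.
#' @param ecg_amplitude ECG spike amplitude in a.u. (before per-channel gain).
#' @param ecg_channel_gain Named per-channel gain applied to the ECG spike.
#' @param noise_sd Broadband noise SD in a.u. The nominal per-channel SNR is
#'   `amplitude / noise_sd`.
#' @param reset_policy Logical; if `TRUE` a triggered swallow resets the
#'   respiratory rhythm (the next inspiration starts `swallow_ibi` after the
#'   swallow-related laryngeal offset). Non-swallow responses leave the
#'   rhythm untouched except that an ongoing laryngeal-activation pulse
#'   defers an inspiration due during the pulse to just after pulse offset.
#' @param include_xii,include_x Render hypoglossal (XII) / vagal (X) ENG
#'   channels mirroring the submental / laryngeal bursts.
#' @param include_ecg_channel Include a clean ECG reference channel.
#' @param genotype Free-text genotype tag stored in metadata.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `pico_config`.
#' @export
generator_config <- function(sampling_rate = 5000,
                             session_duration = 240,
                             breath_period_mean = 0.7,
                             breath_period_cv = 0.1,
                             insp_burst_duration = 0.15,
                             pulse_durations = c(40, 80, 120, 160, 200),
                             pulses_per_duration = 25,
                             behavior_policy = default_behavior_policy(),
                             swallow_duration_mean = 114,
                             swallow_duration_sd = 19,
                             water_swallow_duration_mean = 191,
                             water_swallow_duration_sd = 63,
                             swallow_latency_mean = 30,
                             swallow_latency_sd = 8,
                             water_latency_mean = 100,
                             water_latency_sd = 30,
                             swallow_sequence_delay_mean = 60,
                             swallow_sequence_delay_sd = 15,
                             swallow_ibi = 0.35,
                             swallow_ibi_sd = 0.05,
                             schluckatmung_prob = 0.1,
                             laryngeal_response_gain = 1.0,
                             laryngeal_onset_jitter_ms = 3,
                             laryngeal_offset_jitter_ms = 8,
                             laryngeal_act_amp_mean = 0.6,
                             laryngeal_act_amp_sd = 0.1,
                             laser_swallow_amp_mean = 0.45,
                             laser_swallow_amp_sd = 0.12,
                             laser_swallow_amp_min = 0.25,
                             water_swallow_amp_mean = 0.8,
                             water_swallow_amp_sd = 0.08,
                             water_bolus_count = 20,
                             water_swallow_prob = 1.0,
                             amplitude = c(diaphragm = 1, submental = 1,
                                           laryngeal = 1, xii = 1, x = 1),
                             ecg_rate = 7,
                             ecg_amplitude = 0.4,
                             ecg_channel_gain = c(diaphragm = 1, submental = 0.4,
                                                  laryngeal = 0.4, xii = 0.25,
                                                  x = 0.25),
                             noise_sd = 0.1,
                             reset_policy = TRUE,
                             include_xii = FALSE,
                             include_x = FALSE,
                             include_ecg_channel = TRUE,
                             genotype = "ChATcre:Vglut2FlpO:ChR2",
                             seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pico_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid generator config: ", msg, call. = FALSE)
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_cfg(sprintf("'%s' must be positive and finite", field))
    }
  }
  for (f in c("sampling_rate", "session_duration", "breath_period_mean",
              "insp_burst_duration", "pulse_durations", "pulses_per_duration",
              "swallow_duration_mean", "swallow_duration_sd",
              "water_swallow_duration_mean", "water_swallow_duration_sd",
              "swallow_latency_mean", "swallow_sequence_delay_mean",
              "swallow_ibi", "ecg_rate", "noise_sd")) {
    num_pos(f)
  }
  if (cfg$sampling_rate < 2 * 700) {
    stop_cfg("sampling_rate must be at least 1400 Hz (twice the 700 Hz band edge)")
  }
  if (cfg$breath_period_cv < 0) stop_cfg("breath_period_cv must be >= 0")
  bp <- cfg$behavior_policy
  needed <- c("phase_lo", "phase_hi", "swallow", "laryngeal_activation", "no_response")
  if (!is.data.frame(bp) || !all(needed %in% names(bp))) {
    stop_cfg("behavior_policy must be a data.frame with columns phase_lo, phase_hi, swallow, laryngeal_activation, no_response")
  }
  bp <- bp[order(bp$phase_lo), ]
  if (abs(bp$phase_lo[1]) > 1e-9 || abs(bp$phase_hi[nrow(bp)] - 1) > 1e-9 ||
      (nrow(bp) > 1 && any(abs(bp$phase_hi[-nrow(bp)] - bp$phase_lo[-1]) > 1e-9))) {
    stop_cfg("behavior_policy intervals must partition [0, 1]")
  }
  psum <- bp$swallow + bp$laryngeal_activation + bp$no_response
  if (any(bp$swallow < 0 | bp$laryngeal_activation < 0 | bp$no_response < 0) ||
      any(abs(psum - 1) > 1e-9)) {
    stop_cfg("behavior_policy class probabilities must be non-negative and sum to 1 in every interval")
  }
  if (cfg$water_bolus_count < 0) stop_cfg("water_bolus_count must be >= 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    stop_cfg("seed must be a single finite number")
  }
  invisible(cfg)
}

#' Analysis parameter set
#'
#' Parameters of the processing and classification chain used by
#' [analyze_recording()]. Defaults follow the published processing
#' (band-pass 200-700 Hz with a 40 Hz transition, 20 ms rectify-smooth)
#' and quantify its verbal behavior definitions: a swallow must outlast
#' the laser by at least `outlast_margin`, a laryngeal activation must be
#' locked to the pulse within `onset_tolerance` / `lock_tolerance`.
#'
#' @param bandpass_low,bandpass_high,bandpass_transition Band-pass edges and
#'   transition width, Hz.
#' @param smooth_ms Envelope moving-average window, ms.
#' @param ecg_removal Remove ECG artifact epochs before enveloping.
#' @param k_onset,k_offset Burst detection / hysteresis-termination
#'   thresholds in baseline-SD multiples.
#' @param min_duration_ms,min_gap_ms Minimum burst duration and
#'   burst-merging gap, ms.
#' @param response_horizon_ms Response window length after stimulus offset
#'   within which evoked bursts are sought.
#' @param outlast_margin_ms Minimum time the swallow-related laryngeal
#'   burst must outlast the laser pulse.
#' @param onset_tolerance_ms Maximum laryngeal onset deviation from laser
#'   onset for a stimulus-locked laryngeal activation.
#' @param lock_tolerance_ms Maximum laryngeal offset overshoot past laser
#'   offset for a stimulus-locked laryngeal activation.
#' @param water_horizon_ms Response window after a water bolus.
#' @param n_bins Number of respiratory-phase bins for curves/histograms.
#' @return A list of class `pico_params`.
#' @export
analysis_params <- function(bandpass_low = 200,
                            bandpass_high = 700,
                            bandpass_transition = 40,
                            smooth_ms = 20,
                            ecg_removal = TRUE,
                            k_onset = 3,
                            k_offset = 1,
                            min_duration_ms = 15,
                            min_gap_ms = 10,
                            response_horizon_ms = 500,
                            outlast_margin_ms = 20,
                            onset_tolerance_ms = 30,
                            lock_tolerance_ms = 40,
                            water_horizon_ms = 600,
                            n_bins = 10) {
  p <- as.list(environment())
  if (p$bandpass_low >= p$bandpass_high) {
    stop("bandpass_low must be below bandpass_high", call. = FALSE)
  }
  if (p$smooth_ms <= 0 || p$n_bins < 1) {
    stop("smooth_ms must be positive and n_bins >= 1", call. = FALSE)
  }
  class(p) <- "pico_params"
  p
}

# lognormal parameters matching a target mean/sd on the natural scale
lnorm_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}
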