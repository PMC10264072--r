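# Shared session cache: heavy synthetic sessions are generated once per
# test run and reused across files.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, config, analyze = TRUE) {
  if (is.null(.session_cache[[key]])) {
    sess <- generate_recording(config)
    if (analyze) sess$analysis <- analyze_recording(sess$recording)
    .session_cache[[key]] <- sess
  }
  .session_cache[[key]]
}

# full default session (125 pulses, 20 water boluses)
default_session <- function(seed) {
  cached_session(paste0("default_", seed), generator_config(seed = seed))
}

# ChATcre:Ai32-like parameterization used for water/laser duration recovery
ai32_config <- function(seed) {
  generator_config(genotype = "ChATcre:Ai32",
                   swallow_duration_mean = 199, swallow_duration_sd = 125,
                   water_swallow_duration_mean = 290,
                   water_swallow_duration_sd = 125,
                   seed = seed)
}

ai32_session <- function(seed) {
  cached_session(paste0("ai32_", seed), ai32_config(seed))
}

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(session_duration = 60, pulses_per_duration = 3,
         water_bolus_count = 5, seed = seed),
    list(...)
  )
  do.call(generator_config, args)
}

small_session <- function(seed = 1) {
  cached_session(paste0("small_", seed), small_config(seed))
}

# simple constant-period breath table for constructed-case tests
make_breaths <- function(onsets, insp_dur = 0.15, control = TRUE) {
  n <- length(onsets)
  data.frame(
    insp_onset = onsets[-n],
    insp_peak_time = onsets[-n] + 0.75 * insp_dur,
    insp_peak_amplitude = 1,
    insp_offset = onsets[-n] + insp_dur,
    next_insp_onset = onsets[-1],
    cycle_duration = diff(onsets),
    ibi_ms = (diff(onsets) - insp_dur) * 1000,
    control = control
  )
}

make_burst <- function(channel, onset, offset, peak_time = NULL,
                       peak_amplitude = 1) {
  if (is.null(peak_time)) peak_time <- (onset + offset) / 2
  data.frame(channel = channel, onset = onset, offset = offset,
             peak_time = peak_time, peak_amplitude = peak_amplitude,
             duration_ms = (offset - onset) * 1000,
             stringsAsFactors = FALSE)
}
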