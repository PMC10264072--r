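test_that("identical config and seed give bit-identical sessions", {
  cfg <- small_config(seed = 11)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
})

test_that("the laser protocol delivers every pulse duration the configured number of times", {
  sess <- default_session(1)
  gl <- sess$ground_truth$events[sess$ground_truth$events$trigger == "laser", ]
  expect_equal(nrow(gl), 125)
  expect_equal(unname(table(gl$stim_duration_ms)), rep(25L, 5),
               ignore_attr = TRUE)
  expect_equal(nrow(sess$recording$stimuli), 125)
  # stimuli sorted and non-overlapping by construction
  offs <- sess$recording$stimuli$onset + sess$recording$stimuli$duration_ms / 1000
  expect_true(all(diff(sess$recording$stimuli$onset) > 0))
  expect_true(all(sess$recording$stimuli$onset[-1] >= offs[-125]))
})

test_that("a null behavior policy leaves non-diaphragm channels without bursts", {
  policy <- data.frame(phase_lo = 0, phase_hi = 1, swallow = 0,
                       laryngeal_activation = 0, no_response = 1)
  cfg <- small_config(seed = 3, behavior_policy = policy,
                      water_bolus_count = 0)
  sess <- generate_recording(cfg)
  expect_true(all(sess$ground_truth$events$class == "no_response"))
  fs <- sess$recording$sampling_rate
  for (ch in c("submental", "laryngeal")) {
    x <- remove_ecg(sess$recording$channels[[ch]], fs,
                    reference = sess$recording$channels$ecg)$signal
    env <- rectify_smooth(bandpass_filter(x, fs), fs, 20)
    expect_lte(nrow(detect_bursts(env, channel = ch)), 1)
  }
})

test_that("scheduled stimulus phases are uniform and counts are conserved", {
  onsets <- cumsum(c(0.5, rep(0.7, 2200)))
  cfg <- generator_config(pulses_per_duration = 200)
  set.seed(1)
  st <- schedule_stimuli(onsets, cfg)
  expect_equal(nrow(st), 1000)
  ks <- stats::ks.test(st$phase, "punif")
  expect_gt(ks$p.value, 0.01)

  # 200 breaths comfortably hold 125 non-overlapping pulses
  set.seed(2)
  st2 <- schedule_stimuli(cumsum(c(0.5, rep(0.7, 199))), generator_config())
  expect_equal(nrow(st2), 125)
  offs <- st2$onset + st2$duration_ms / 1000
  expect_true(all(st2$onset[-1] > offs[-nrow(st2)]))

  set.seed(3)
  st3 <- schedule_stimuli(cumsum(c(0.5, rep(0.7, 30))),
                          generator_config(pulses_per_duration = 1))
  expect_equal(sort(st3$duration_ms), c(40, 80, 120, 160, 200))

  expect_error(schedule_stimuli(0.5, generator_config()), "breath onsets")
})

test_that("render_burst confines energy to the burst and is additive for disjoint bursts", {
  fs <- 5000
  expect_error(render_burst(-5, 1, fs), "positive")
  set.seed(1)
  expect_true(all(render_burst(100, 0, fs) == 0))

  # envelope above half-max only within [onset - 10 ms, offset + 25 ms]
  set.seed(2)
  seg <- render_burst(100, 1, fs)
  pad <- round(0.3 * fs)
  x <- c(numeric(pad), seg, numeric(pad))
  env <- rectify_smooth(x, fs, 20)$samples
  hi <- which(env > max(env) / 2)
  on_i <- pad + 1
  off_i <- pad + length(seg)
  expect_gte(min(hi), on_i - round(0.010 * fs))
  expect_lte(max(hi), off_i + round(0.025 * fs))

  # disjoint bursts: envelopes add where supports do not interact
  set.seed(3)
  s1 <- render_burst(80, 1, fs)
  s2 <- render_burst(80, 0.5, fs)
  x1 <- c(numeric(pad), s1, numeric(3 * pad))
  x2 <- c(numeric(2 * pad + length(s1)), s2,
          numeric(length(x1) - 2 * pad - length(s1) - length(s2)))
  e_sum <- rectify_smooth(x1 + x2, fs, 20)$samples
  e_sep <- rectify_smooth(x1, fs, 20)$samples + rectify_smooth(x2, fs, 20)$samples
  expect_equal(e_sum, e_sep, tolerance = 1e-12)
})

test_that("swallows are all-or-none while laryngeal activations are laser-locked", {
  gt <- do.call(rbind, lapply(1:3, function(s) default_session(s)$ground_truth$events))
  sw <- gt[gt$trigger == "laser" & gt$class == "swallow", ]
  expect_gte(nrow(sw), 100)
  expect_lt(abs(cor(sw$stim_duration_ms, sw$swallow_duration_ms)), 0.2)
  la <- gt[gt$class == "laryngeal_activation", ]
  expect_gt(cor(la$stim_duration_ms, la$laryngeal_duration_ms,
                method = "spearman"), 0.9)
})

test_that("invalid configurations and over-full sessions are rejected", {
  expect_error(generator_config(sampling_rate = 1000), "1400")
  expect_error(generator_config(swallow_duration_mean = -5), "positive")
  bad_policy <- data.frame(phase_lo = 0, phase_hi = 1, swallow = 0.5,
                           laryngeal_activation = 0.4, no_response = 0.2)
  expect_error(generator_config(behavior_policy = bad_policy), "sum to 1")
  expect_error(generate_recording(generator_config(session_duration = 30)),
               "too short")
})
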