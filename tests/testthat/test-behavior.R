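default_params <- analysis_params()

test_that("the ordered decision rule reproduces the published behavior templates", {
  # swallow: delayed submental + laryngeal outlasting the pulse, peaks in order
  bursts <- rbind(
    make_burst("submental", 1.03, 1.15, peak_time = 1.08),
    make_burst("laryngeal", 1.07, 1.22, peak_time = 1.13)
  )
  res <- classify_response(1.0, 80, bursts, default_params)
  expect_equal(res$class, "swallow")
  expect_false(res$atypical)

  # laryngeal activation: burst spanning exactly the 200 ms pulse, silent diaphragm
  bursts2 <- make_burst("laryngeal", 1.005, 1.205)
  res2 <- classify_response(1.0, 200, bursts2, default_params)
  expect_equal(res2$class, "laryngeal_activation")

  # a diaphragm burst starting inside the pulse vetoes laryngeal activation
  bursts3 <- rbind(bursts2, make_burst("diaphragm", 1.1, 1.25))
  res3 <- classify_response(1.0, 200, bursts3, default_params)
  expect_equal(res3$class, "no_response")
  expect_true(res3$atypical)

  # no bursts in the window: clean no response
  res4 <- classify_response(1.0, 80, bursts[0, ], default_params)
  expect_equal(res4$class, "no_response")
  expect_false(res4$atypical)

  # reversed peak order (laryngeal before submental) inside the window: atypical
  bursts5 <- rbind(
    make_burst("submental", 1.03, 1.15, peak_time = 1.13),
    make_burst("laryngeal", 1.05, 1.14, peak_time = 1.07)
  )
  res5 <- classify_response(1.0, 80, bursts5, default_params)
  expect_equal(res5$class, "no_response")
  expect_true(res5$atypical)
})

test_that("swallow metrics follow the onset/offset/peak definitions", {
  sub <- make_burst("submental", 1.000, 1.250, peak_time = 1.100)
  lar <- make_burst("laryngeal", 1.050, 1.300, peak_time = 1.160)
  breaths <- make_breaths(c(0.2, 0.9, 1.65, 2.35))
  met <- measure_swallow(sub, lar, breaths = breaths)
  expect_equal(met$swallow_duration_ms, 250)
  expect_equal(met$swallow_sequence_ms, 60)
  # laryngeal offset 1.300 -> next inspiration at 1.65: 350 ms delay
  expect_equal(met$inspiratory_delay_ms, 350)

  sch <- make_burst("diaphragm", 1.06, 1.18)
  met2 <- measure_swallow(sub, lar, schluck_bursts = sch, breaths = breaths)
  expect_equal(met2$schluckatmung_duration_ms, 120)

  met3 <- measure_swallow(sub, NULL)
  expect_true(is.na(met3$swallow_sequence_ms))
  expect_true(is.na(met3$inspiratory_delay_ms))
})

test_that("the % of max scale is anchored to the maximum water-swallow amplitude", {
  w <- data.frame(class = "swallow",
                  submental_amp = c(0.8, 1.0, 0.9),
                  laryngeal_amp = c(0.7, 0.75, 0.72))
  bl <- compute_baseline(w, c("submental", "laryngeal"))
  expect_equal(unname(bl$amps["submental"]), 1.0)
  expect_length(bl$no_baseline, 0)
  expect_equal(0.43 / bl$amps[["submental"]] * 100, 43)

  one <- compute_baseline(w[1, ], c("submental"))
  expect_equal(unname(one$amps), 0.8)

  none <- compute_baseline(w[0, ], c("submental"))
  expect_true(is.na(none$amps[["submental"]]))
  expect_equal(none$no_baseline, "submental")
})

test_that("XII serves as the swallow channel when the submental EMG is absent", {
  sess <- cached_session("xii", small_config(seed = 8, include_xii = TRUE),
                         analyze = FALSE)
  rec <- sess$recording
  rec$channels$submental <- NULL
  an <- analyze_recording(rec)
  gl <- sess$ground_truth$events[sess$ground_truth$events$trigger == "laser", ]
  el <- an$events[an$events$trigger == "laser", ]
  agree <- mean(gl$class == el$class)
  expect_gte(agree, 0.9)
  expect_equal(attr(an$events, "swallow_channel"), "xii")
})

test_that("measured water swallows are longer than laser-evoked swallows on average", {
  ev <- do.call(rbind, lapply(1:3, function(s) default_session(s)$analysis$events))
  laser <- ev$swallow_duration_ms[ev$trigger == "laser" & ev$class == "swallow" &
                                    !ev$atypical]
  water <- ev$swallow_duration_ms[ev$trigger == "water" & ev$class == "swallow"]
  expect_gt(length(water), 30)
  expect_gt(mean(water), mean(laser))
})
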