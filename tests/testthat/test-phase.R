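test_that("respiratory phase and phase shift follow their defining ratios", {
  br <- make_breaths(seq(0, 7, by = 0.7))
  # stimulus at inspiration onset
  expect_equal(respiratory_phase(br$insp_onset[3], br), 0)
  # 0.35 s into a 0.70 s expected phase
  expect_equal(respiratory_phase(br$insp_onset[3] + 0.35, br), 0.5)
  # unperturbed cycles shift by 1
  expect_equal(phase_shift(br$insp_onset[4] + 0.1, br), 1)

  # containing cycle 1.05 s, preceding control 0.70 s
  on2 <- c(0, 0.7, 1.4, 2.45, 3.15)
  br2 <- make_breaths(on2)
  br2$control <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(phase_shift(1.5, br2), 1.05 / 0.7)

  # stimulus before the first breath or in the first cycle is excluded
  expect_true(is.na(respiratory_phase(-0.5, br)))
})

test_that("phases above 1 are retained but counted as overflow in curves", {
  on <- c(0, 0.7, 1.4, 2.8, 3.5)  # third cycle lasts 1.4 s
  br <- make_breaths(on)
  br$control <- c(TRUE, TRUE, FALSE, TRUE)
  ph <- respiratory_phase(2.6, br)  # 1.2 s into the long cycle
  expect_gt(ph, 1)
  curve <- bin_curve(c(0.1, 0.5, ph), c(1, 1, 2), n_bins = 10)
  expect_equal(attr(curve, "overflow"), 1)
  expect_equal(sum(curve$n), 2)
})

test_that("bin_curve uses half-open tenth-of-cycle bins", {
  curve <- bin_curve(0.05, 3, n_bins = 10)
  expect_equal(curve$n[1], 1)
  expect_equal(curve$mean[1], 3)
  # constant values give zero spread in every occupied bin
  set.seed(31)
  ph <- runif(200)
  c2 <- bin_curve(ph, rep(1.25, 200))
  expect_true(all(abs(c2$mean[c2$n > 0] - 1.25) < 1e-12))
  expect_true(all(c2$sd[c2$n > 1] == 0))
  # uniform phases fill bins evenly
  set.seed(32)
  c3 <- bin_curve(runif(1000), rnorm(1000))
  expect_true(all(abs(c3$n - 100) <= 30))
  expect_error(bin_curve(numeric(), numeric()), "no samples")
})

test_that("behavior probabilities are exhaustive and recover the generator policy", {
  ev <- do.call(rbind, lapply(1:3, function(s) {
    e <- default_session(s)$analysis$events
    e[, c("trigger", "class", "respiratory_phase")]
  }))
  prob <- probability_curves(ev)
  for (b in unique(prob$bin)) {
    p <- prob$probability[prob$bin == b]
    if (all(is.finite(p))) expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # generator policy: P(swallow) = 0.8 for phases below 0.3
  laser <- ev[ev$trigger == "laser" & is.finite(ev$respiratory_phase), ]
  early <- laser[laser$respiratory_phase < 0.25, ]
  expect_gt(nrow(early), 60)
  expect_lt(abs(mean(early$class == "swallow") - 0.8), 0.12)

  # an empty bin reports a missing probability, not zero
  ev2 <- data.frame(trigger = "laser", class = c("swallow", "no_response"),
                    respiratory_phase = c(0.05, 0.12))
  p2 <- probability_curves(ev2)
  expect_true(all(is.na(p2$probability[p2$bin == 10])))
})

test_that("swallow timing is measured from inspiration onset and diaphragm peak", {
  br <- make_breaths(c(1, 1.5, 2.0), insp_dur = 0.2)
  # insp peak at onset + 0.75 * 0.2 = 1.15
  ev <- data.frame(event_id = c("S1", "S2"), class = "swallow",
                   trigger = "laser",
                   submental_onset = c(1.15, 1.6))
  tim <- swallow_timing(ev, br)
  expect_equal(tim$samples$onset_rel_insp_peak_ms[1], 0)
  expect_equal(tim$samples$onset_phase[1], 0.3)
  expect_equal(tim$samples$onset_phase[2], 0.2)

  # synthetic sessions place swallow onsets postinspiratory (bins 3-5)
  hist_all <- Reduce(`+`, lapply(1:3, function(s) {
    default_session(s)$analysis$timing$histogram$count
  }))
  expect_true(which.max(hist_all) %in% 3:5)
})

test_that("the reset regression matches a closed-form least-squares oracle", {
  # perfectly collinear samples
  s <- data.frame(respiratory_phase = seq(0.1, 0.9, by = 0.1),
                  phase_shift = 0.4 + 1.3 * seq(0.1, 0.9, by = 0.1),
                  group = "swallow")
  r <- reset_correlation(s, "swallow")
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 1.3, tolerance = 1e-12)
  expect_equal(r$intercept, 0.4, tolerance = 1e-12)

  # constant shift: flat regression, undefined r
  s2 <- s
  s2$phase_shift <- 1
  r2 <- reset_correlation(s2, "swallow")
  expect_equal(r2$slope, 0)
  expect_true(is.na(r2$r))

  # zero phase variance is an error
  s3 <- s
  s3$respiratory_phase <- 0.5
  expect_error(reset_correlation(s3, "swallow"), "zero variance")

  # oracle equivalence on real samples to 1e-12
  ps <- default_session(1)$analysis$phase_samples
  for (g in c("swallow", "non_swallow")) {
    got <- reset_correlation(ps, g)
    x <- ps$respiratory_phase[ps$group == g]
    y <- ps$phase_shift[ps$group == g]
    n <- length(x)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    r_bf <- sxy / sqrt(sxx * syy)
    slope_bf <- sxy / sxx
    icpt_bf <- mean(y) - slope_bf * mean(x)
    tstat <- r_bf * sqrt((n - 2) / (1 - r_bf^2))
    p_bf <- 2 * stats::pt(-abs(tstat), df = n - 2)
    expect_equal(got$r, r_bf, tolerance = 1e-12)
    expect_equal(got$slope, slope_bf, tolerance = 1e-12)
    expect_equal(got$intercept, icpt_bf, tolerance = 1e-12)
    expect_equal(got$p, p_bf, tolerance = 1e-12)
  }
})

test_that("control cycle pairs have unit mean phase shift", {
  sess <- default_session(2)
  br <- sess$analysis$breaths
  ctrl <- which(br$control)
  pairs <- ctrl[c(diff(ctrl) == 1, FALSE)]
  ratio <- br$cycle_duration[pairs + 1] / br$cycle_duration[pairs]
  cv <- sd(br$cycle_duration[ctrl]) / mean(br$cycle_duration[ctrl])
  expect_lt(abs(mean(ratio) - 1), 3 * cv / sqrt(length(ratio)) + cv^2)
})
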