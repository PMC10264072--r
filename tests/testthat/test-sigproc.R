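test_that("band-pass keeps the pass band and rejects out-of-band tones", {
  fs <- 5000
  t <- (0:(2 * fs - 1)) / fs
  mid <- (0.4 * fs):(1.6 * fs)
  gain_db <- function(f0) {
    x <- sin(2 * pi * f0 * t)
    y <- bandpass_filter(x, fs)
    20 * log10(sd(y[mid]) / sd(x[mid]))
  }
  expect_gt(gain_db(450), -1)
  expect_lt(abs(gain_db(450)), 1)
  expect_lt(gain_db(50), -40)
  expect_lt(gain_db(760), -40)
  expect_true(all(bandpass_filter(numeric(1000), fs) == 0))
  expect_error(bandpass_filter(rnorm(100), 1000, low = 200, high = 700),
               "sampling_rate")
})

test_that("rectify-smooth is an exact shrinking-edge moving average of the rectified signal", {
  fs <- 5000
  for (c0 in c(2, -2)) {
    env <- rectify_smooth(rep(c0, 500), fs, 20)
    expect_s3_class(env, "pico_envelope")
    expect_equal(env$samples, rep(abs(c0), 500))
  }
  # unit impulse at 5 kHz with a 20 ms window: plateau of exactly 1/100
  x <- numeric(1000)
  x[500] <- 1
  env <- rectify_smooth(x, fs, 20)$samples
  expect_equal(sum(env > 0), 100)
  expect_equal(unique(round(env[env > 0], 12)), 1 / 100)
  expect_error(rectify_smooth(rnorm(10), 10, window_ms = 20), "sample period")
  # brute-force shrinking-window oracle
  set.seed(6)
  y <- rnorm(500)
  bf <- sapply(seq_along(y), function(i) {
    mean(abs(y[max(1, i - 49):min(length(y), i + 50)]))
  })
  expect_equal(rectify_smooth(y, fs, 20)$samples, bf, tolerance = 1e-12)
})

test_that("rectify-smooth is monotone under pointwise scaling", {
  set.seed(7)
  x <- rnorm(2000)
  e1 <- rectify_smooth(x, 5000, 20)$samples
  e2 <- rectify_smooth(2 * x, 5000, 20)$samples
  expect_true(all(e2 >= e1))
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("the processing chain is zero-phase: envelope peaks stay on the designed peak", {
  fs <- 5000
  set.seed(5)
  for (peak_frac in c(0.3, 0.5, 0.75)) {
    seg <- render_burst(150, 1, fs, peak_frac = peak_frac, carrier = "tone")
    pad <- round(0.25 * fs)
    x <- c(numeric(pad), seg, numeric(pad))
    env <- rectify_smooth(bandpass_filter(x, fs), fs, 20)$samples
    peak_t <- (which.max(env) - 1) / fs
    designed <- (pad) / fs + peak_frac * 0.150
    expect_lt(abs(peak_t - designed), 0.002)
  }
})

test_that("ECG epochs are excised on the reference R-peaks and suppress the artifact", {
  fs <- 5000
  dur <- 20
  n <- dur * fs
  set.seed(11)
  x <- rnorm(n, 0, 0.02)
  tmpl <- picoswallow:::ecg_template(fs)
  r_times <- seq(0.5, dur - 0.5, by = 1 / 7)
  ref <- numeric(n)
  half <- (length(tmpl) - 1) %/% 2
  for (tt in r_times) {
    i0 <- round(tt * fs) + 1 - half
    ref[i0:(i0 + length(tmpl) - 1)] <- ref[i0:(i0 + length(tmpl) - 1)] + tmpl
  }
  y <- x + 0.5 * ref
  out <- remove_ecg(y, fs, reference = 0.5 * ref)
  # epochs aligned to the true R-peaks within 2 ms
  centers <- (out$epochs$onset + out$epochs$offset) / 2
  expect_equal(length(centers), length(r_times))
  expect_lt(max(abs(centers - r_times)), 0.002)
  # artifact RMS inside the excised epochs drops by at least 80 %
  idx <- unlist(lapply(seq_len(nrow(out$epochs)), function(k) {
    (round(out$epochs$onset[k] * fs):round(out$epochs$offset[k] * fs)) + 1
  }))
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out$signal[idx]), 0.2 * rms(y[idx]))
  # signal outside the epochs untouched
  expect_equal(out$signal[-idx], y[-idx], tolerance = 1e-12)
})

test_that("auto-detection finds the artifact unaided and leaves clean traces alone", {
  fs <- 5000
  n <- 10 * fs
  set.seed(12)
  x <- rnorm(n, 0, 0.02)
  tmpl <- picoswallow:::ecg_template(fs)
  half <- (length(tmpl) - 1) %/% 2
  r_times <- seq(0.5, 9.5, by = 1 / 7)
  y <- x
  for (tt in r_times) {
    i0 <- round(tt * fs) + 1 - half
    y[i0:(i0 + length(tmpl) - 1)] <- y[i0:(i0 + length(tmpl) - 1)] + 0.5 * tmpl
  }
  out <- remove_ecg(y, fs)
  expect_gte(length(out$r_peaks), length(r_times) - 1)

  clean <- rnorm(n, 0, 0.02)
  expect_warning(out2 <- remove_ecg(clean, fs), "no regular ECG")
  expect_identical(out2$signal, clean)
})
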