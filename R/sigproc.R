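# Signal conditioning: zero-phase FIR band-pass, rectify + moving-average
# smoothing, and ECG artifact excision. These reproduce the published
# processing chain (band-pass 200-700 Hz with a 40 Hz transition gap,
# rectification, 20 ms smoothing, heart-artifact removal).

.fir_cache <- new.env(parent = emptyenv())

# Linear-phase Hamming-windowed band-pass kernel. -6 dB points are pushed
# half a transition width outside the requested pass band so the band edges
# themselves sit near unity gain; Hamming gives ~53 dB stop-band attenuation.
design_bandpass_fir <- function(sampling_rate, low, high, transition) {
  key <- paste(sampling_rate, low, high, transition, sep = "_")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  ntaps <- ceiling(3.3 * sampling_rate / transition)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  nyq <- sampling_rate / 2
  lo <- max(low - transition / 2, 1) / nyq
  hi <- min(high + transition / 2, nyq - 1) / nyq
  h <- signal::fir1(ntaps - 1, c(lo, hi), type = "pass")
  h <- as.numeric(h)
  .fir_cache[[key]] <- h
  h
}

# Same-length convolution of x with a symmetric odd-length kernel via FFT,
# compensating the (L-1)/2 group delay: zero phase overall.
fft_filter_same <- function(x, h) {
  n <- length(x)
  L <- length(h)
  m <- n + L - 1
  nfft <- stats::nextn(m, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  half <- (L - 1) / 2
  y[(half + 1):(half + n)]
}

#' Zero-phase band-pass filter
#'
#' Filters an EMG/ENG trace with a linear-phase FIR band-pass applied with
#' group-delay compensation, so burst timing is preserved exactly. Output
#' has the same length as the input. Stop-band attenuation is >= 40 dB
#' beyond the transition band; pass-band ripple is well under 1 dB.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate, Hz. Must exceed `2 * high`.
#' @param low,high Pass-band edges, Hz.
#' @param transition Transition width, Hz.
#' @return Filtered numeric signal of the same length.
#' @export
bandpass_filter <- function(x, sampling_rate, low = 200, high = 700,
                            transition = 40) {
  if (low >= high) stop("'low' must be below 'high'", call. = FALSE)
  if (sampling_rate <= 2 * high) {
    stop(sprintf(
      "sampling_rate (%g Hz) too low for a %g Hz band edge; need at least %g Hz",
      sampling_rate, high, 2 * high
    ), call. = FALSE)
  }
  if (length(x) == 0) return(numeric())
  h <- design_bandpass_fir(sampling_rate, low, high, transition)
  fft_filter_same(x, h)
}

new_envelope <- function(samples, sampling_rate, provenance = list()) {
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 provenance = provenance),
            class = "pico_envelope")
}

#' @export
print.pico_envelope <- function(x, ...) {
  cat(sprintf("pico_envelope: %d samples @ %g Hz (%s)\n",
              length(x$samples), x$sampling_rate,
              paste(names(x$provenance), unlist(x$provenance),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Rectify and smooth a signal into an envelope
#'
#' Full-wave rectification followed by a centered moving average of the
#' given window. The window shrinks at the trace boundaries so the output
#' keeps the input length; everywhere else the average runs over exactly
#' `round(window_ms / 1000 * sampling_rate)` samples.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate, Hz.
#' @param window_ms Smoothing window in ms (default 20 ms).
#' @param channel Optional channel name recorded in the provenance.
#' @return A `pico_envelope` (non-negative samples, same length as `x`).
#' @export
rectify_smooth <- function(x, sampling_rate, window_ms = 20, channel = NA) {
  if (window_ms <= 0) stop("window_ms must be positive", call. = FALSE)
  w <- round(window_ms / 1000 * sampling_rate)
  if (w < 1) {
    stop("smoothing window shorter than one sample period", call. = FALSE)
  }
  n <- length(x)
  if (n == 0) stop("empty signal", call. = FALSE)
  r <- abs(x)
  half_lo <- floor((w - 1) / 2)
  half_hi <- ceiling((w - 1) / 2)
  cs <- cumsum(r)
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sums <- cs[hi] - c(0, cs)[lo]
  env <- sums / (hi - lo + 1L)
  out <- new_envelope(env, sampling_rate,
                      provenance = list(channel = channel,
                                        window_ms = window_ms))
  # the rectified (pre-smoothing) trace carries the baseline variability
  # that burst-detection thresholds are set against
  out$rectified <- r
  out
}

# local maxima of v above thr, thinned to a minimum spacing (keep larger)
find_peaks <- function(v, thr, min_dist) {
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(v >= thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]]
  if (length(cand) == 0) return(integer())
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer()
  for (p in cand) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Remove ECG artifact epochs from an EMG/ENG trace
#'
#' Heart artifacts appear as brief periodic spikes on every channel. Each
#' R-peak-aligned epoch (`+/- epoch_ms`) is replaced by linear
#' interpolation between the samples flanking the epoch; the signal
#' outside the epochs is untouched. R-peaks are taken from a reference
#' channel when one is supplied; otherwise they are detected on the target
#' itself as large, regularly spaced spikes. If no regular artifact can be
#' found (and no reference is given) the input is returned unchanged with
#' a warning.
#'
#' Epochs falling inside ongoing high-amplitude EMG activity are skipped
#' by default: there the artifact is masked by the burst and excision
#' would only punch holes into genuine signal (set `skip_masked = FALSE`
#' to excise unconditionally).
#'
#' @param x Numeric signal (raw or band-passed).
#' @param sampling_rate Sampling rate, Hz.
#' @param reference Optional ECG reference channel (same length/rate).
#' @param epoch_ms Half-width of the excision epoch around each R-peak.
#' @param skip_masked Skip epochs whose surroundings carry EMG activity
#'   well above the quiet-signal scale.
#' @return A list with `signal` (cleaned trace), `epochs` (data.frame of
#'   excised intervals in s), and `r_peaks` (R-peak times in s).
#' @export
remove_ecg <- function(x, sampling_rate, reference = NULL, epoch_ms = 10,
                       skip_masked = TRUE) {
  n <- length(x)
  half <- round(epoch_ms / 1000 * sampling_rate)
  min_dist <- round(0.04 * sampling_rate)
  if (!is.null(reference)) {
    a <- abs(reference)
    peaks <- find_peaks(a, 0.4 * max(a), min_dist)
  } else {
    a <- abs(x)
    thr <- stats::median(a) + 8 * stats::mad(a)
    peaks <- find_peaks(a, thr, min_dist)
    regular <- FALSE
    if (length(peaks) >= 5) {
      ipi <- diff(peaks) / sampling_rate
      regular <- stats::sd(ipi) / mean(ipi) < 0.25
    }
    if (!regular) {
      warning("no regular ECG artifact detected and no reference given; signal returned unchanged")
      return(list(signal = x,
                  epochs = data.frame(onset = numeric(), offset = numeric()),
                  r_peaks = numeric()))
    }
  }
  if (skip_masked && length(peaks)) {
    # context: +/- 2.5 epochs around the peak, with the spike core blanked
    quiet <- stats::median(abs(x))
    ctx <- round(2.5 * half)
    core <- round(0.6 * half)
    masked <- vapply(peaks, function(p) {
      i0 <- max(p - ctx, 1L)
      i1 <- min(p + ctx, n)
      seg <- abs(x[i0:i1])
      rel <- abs(seq.int(i0, i1) - p) > core
      # upper quartile so that epochs even partially covered by a burst
      # (edges included) count as masked
      stats::quantile(seg[rel], 0.75, names = FALSE) > 2 * quiet
    }, logical(1))
    peaks <- peaks[!masked]
  }
  y <- x
  eon <- numeric(length(peaks))
  eoff <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    i0 <- max(peaks[k] - half, 1L)
    i1 <- min(peaks[k] + half, n)
    v0 <- if (i0 > 1) y[i0 - 1] else y[i1 + 1]
    v1 <- if (i1 < n) y[i1 + 1] else y[i0 - 1]
    y[i0:i1] <- v0 + (v1 - v0) * seq(0, 1, length.out = i1 - i0 + 1)
    eon[k] <- (i0 - 1) / sampling_rate
    eoff[k] <- (i1 - 1) / sampling_rate
  }
  list(signal = y,
       epochs = data.frame(onset = eon, offset = eoff),
       r_peaks = (peaks - 1) / sampling_rate)
}
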