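# Calibrated SPL / spectrogram analysis and first-heart-tone trigger
# detection: the acoustic cardiac triggering signal chain.

#' Derive the Pa-per-unit calibration constant from a reference tone
#'
#' Given a recording of a (near-)sinusoidal calibration tone of known
#' level (e.g. a 94 dB pistonphone tone), returns the constant `c` such
#' that `20*log10(c * RMS(tone) / 20e-6) == reference_db`.
#'
#' @param tone A [channel_trace()] of the calibration tone (any units).
#' @param reference_db Known tone level in dB SPL re 20 uPa.
#' @return Calibration constant in Pa per unit.
#' @export
calibrate_spl <- function(tone, reference_db = 94) {
  x <- if (inherits(tone, "channel_trace")) tone$samples else as.numeric(tone)
  rms <- sqrt(mean(x^2))
  if (!is.finite(rms) || rms == 0)
    cg_stop("calibration tone is silent", "cg_calibration_error")
  P_REF * 10^(reference_db / 20) / rms
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Short-time SPL spectrogram
#'
#' Hann-windowed short-time power spectra converted to dB SPL re 20 uPa.
#' Cell powers are normalized so that the sum over frequency bins equals
#' the mean-square pressure of the window (Parseval with window-power
#' correction), so band sums are calibrated band powers.
#'
#' @param trace A [channel_trace()]; samples multiplied by `calibration`
#'   must be in Pa.
#' @param window_s Analysis window length, seconds (`window_s * rate >= 16`).
#' @param overlap Fractional overlap between consecutive windows in \[0, 1).
#' @param calibration Pa per unit (1 if the trace is already in Pa).
#' @return An object of class `spectrogram_grid` with fields `times`,
#'   `freqs`, `power` (Pa^2, freq x time), `spl` (dB) and `calibration`.
#' @export
compute_spectrogram <- function(trace, window_s = 0.25, overlap = 0.5,
                                calibration = 1) {
  rate <- trace$rate
  x <- trace$samples * calibration
  nwin <- round(window_s * rate)
  if (nwin < 16) cg_argument_error("window must span at least 16 samples")
  if (nwin > length(x)) cg_argument_error("window longer than trace")
  if (overlap < 0 || overlap >= 1)
    cg_argument_error("overlap must lie in [0, 1)")
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- hann_window(nwin)
  segs <- vapply(starts, function(s) x[s:(s + nwin - 1L)] * w,
                 numeric(nwin))
  X <- stats::mvfft(segs)
  nf <- nwin %/% 2L + 1L
  P <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (nwin * sum(w^2))
  if (nf > 2L) {
    dbl <- 2:(if (nwin %% 2L == 0L) nf - 1L else nf)
    P[dbl, ] <- 2 * P[dbl, ]
  }
  spl <- 10 * log10(pmax(P, 1e-30) / P_REF^2)
  spl <- pmax(spl, -150)
  structure(list(
    times = trace$t0 + (starts - 1L + nwin / 2) / rate,
    freqs = (seq_len(nf) - 1L) * rate / nwin,
    power = P, spl = spl, calibration = calibration),
    class = "spectrogram_grid")
}

#' @export
print.spectrogram_grid <- function(x, ...) {
  cat(sprintf("<spectrogram_grid: %d freqs x %d frames, %.1f-%.1f Hz>\n",
              length(x$freqs), length(x$times), min(x$freqs), max(x$freqs)))
  invisible(x)
}

window_frames <- function(grid, t0, t1) {
  which(grid$times >= t0 & grid$times <= t1)
}

#' Band-limited SPL over a time window
#'
#' Energy is summed over the frequency band and averaged over the frames
#' whose centers fall in the window, expressed in dB re 20 uPa.
#'
#' @param grid A [compute_spectrogram()] result.
#' @param f_lo,f_hi Band edges in Hz (`f_lo < f_hi`).
#' @param t0,t1 Window in seconds (`t0 < t1`); defaults to the whole grid.
#' @return An object of class `spl_measurement` with fields `band`,
#'   `window` and `spl`.
#' @export
band_spl <- function(grid, f_lo, f_hi, t0 = -Inf, t1 = Inf) {
  if (f_lo >= f_hi) cg_argument_error("need f_lo < f_hi")
  if (t0 >= t1) cg_argument_error("need t0 < t1")
  fb <- which(grid$freqs >= f_lo & grid$freqs <= f_hi)
  tb <- window_frames(grid, t0, t1)
  if (!length(fb) || !length(tb))
    cg_argument_error("empty band/window selection")
  p <- mean(colSums(grid$power[fb, tb, drop = FALSE]))
  structure(list(band = c(f_lo, f_hi),
                 window = c(max(t0, min(grid$times)),
                            min(t1, max(grid$times))),
                 spl = max(10 * log10(max(p, 1e-30) / P_REF^2), -150)),
            class = "spl_measurement")
}

#' @export
print.spl_measurement <- function(x, ...) {
  cat(sprintf("<spl_measurement: %.1f dB SPL in %.0f-%.0f Hz, %.2f-%.2f s>\n",
              x$spl, x$band[1], x$band[2], x$window[1], x$window[2]))
  invisible(x)
}

as_window_matrix <- function(w) {
  if (is.data.frame(w)) w <- as.matrix(w[, 1:2])
  if (is.list(w) && !is.matrix(w)) w <- do.call(rbind, w)
  w <- matrix(as.numeric(w), ncol = 2)
  w
}

#' Acoustic signal-to-noise ratio in a frequency band
#'
#' Band SPL averaged over cardiac-activity windows minus band SPL averaged
#' over gradient-noise-only windows, in dB.
#'
#' @param grid A [compute_spectrogram()] result.
#' @param cardiac_windows,noise_windows Two-column matrices (or lists of
#'   pairs) of window start/end times in seconds; the two sets must be
#'   nonempty and disjoint.
#' @param f_lo,f_hi Band edges in Hz.
#' @return SNR in dB.
#' @export
acoustic_snr <- function(grid, cardiac_windows, noise_windows,
                         f_lo = 10, f_hi = 50) {
  cw <- as_window_matrix(cardiac_windows)
  nw <- as_window_matrix(noise_windows)
  if (!nrow(cw) || !nrow(nw))
    cg_argument_error("both window sets must be nonempty")
  for (i in seq_len(nrow(cw)))
    for (j in seq_len(nrow(nw)))
      if (cw[i, 1] < nw[j, 2] && nw[j, 1] < cw[i, 2])
        cg_argument_error("cardiac and noise windows overlap")
  band_power <- function(wins) {
    frames <- unique(unlist(lapply(seq_len(nrow(wins)), function(i)
      window_frames(grid, wins[i, 1], wins[i, 2]))))
    if (!length(frames)) cg_argument_error("window set selects no frames")
    fb <- which(grid$freqs >= f_lo & grid$freqs <= f_hi)
    mean(colSums(grid$power[fb, frames, drop = FALSE]))
  }
  10 * log10(max(band_power(cw), 1e-30) / max(band_power(nw), 1e-30))
}

# ---------------------------------------------------------------------------
# First-heart-tone trigger detection

# Parabolic interpolation of a local extremum from three points.
parabolic_peak <- function(y_prev, y0, y_next) {
  den <- y_prev - 2 * y0 + y_next
  if (abs(den) < 1e-300) return(0)
  max(min(0.5 * (y_prev - y_next) / den, 1), -1)
}

# Peak time, height, and Gaussian-model width/onset from an analytic
# envelope around index `i0`. Times in samples (1-based, fractional).
estimate_burst <- function(env, rate, i0, search_s = 0.15) {
  n <- length(env)
  lo <- max(1L, i0 - round(0.05 * rate))
  hi <- min(n, i0 + round(search_s * rate))
  ip <- lo + which.max(env[lo:hi]) - 1L
  dp <- if (ip > 1L && ip < n)
    parabolic_peak(env[ip - 1L], env[ip], env[ip + 1L]) else 0
  tp <- ip + dp
  h <- env[ip]
  half <- h / 2
  # left half-height crossing
  l <- ip
  lmin <- max(1L, ip - round(0.25 * rate))
  while (l > lmin && env[l] >= half) l <- l - 1L
  tl <- if (env[l] < half && l < ip)
    l + (half - env[l]) / (env[l + 1L] - env[l]) else NA_real_
  r <- ip
  rmax <- min(n, ip + round(0.25 * rate))
  while (r < rmax && env[r] >= half) r <- r + 1L
  tr <- if (env[r] < half && r > ip)
    r - (half - env[r]) / (env[r - 1L] - env[r]) else NA_real_
  if (is.na(tl) || is.na(tr)) return(NULL)
  fwhm <- (tr - tl) / rate
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  list(t_peak = (tp - 1) / rate, height = h, sigma = sigma,
       onset = (tp - 1) / rate - 3 * sigma)
}

# Spectral centroid (Hz) of a signal segment, over bins >= 10% of max.
spectral_centroid <- function(x, rate) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  nfft <- 2^ceiling(log2(max(n, 64)))
  X <- stats::fft(c(x - mean(x), rep(0, nfft - n)))
  nf <- nfft %/% 2 + 1
  P <- Mod(X[seq_len(nf)])^2
  f <- (seq_len(nf) - 1) * rate / nfft
  keep <- P >= 0.1 * max(P)
  sum(f[keep] * P[keep]) / sum(P[keep])
}

# The filter chain broadens and shifts a narrowband burst envelope, which
# would bias a Gaussian-model onset estimate. The detector calibrates
# itself by passing a synthetic probe burst (matched to the measured
# carrier frequency and envelope width) through its own chain and
# subtracting the onset error it observes on the probe.
onset_probe_bias <- function(rate, spec, f_meas, sigma_meas,
                             zero_phase = TRUE, n_iter = 2L) {
  f_p <- f_meas
  sigma_p <- sigma_meas
  run_probe <- function(f_p, sigma_p) {
    dur <- 6 * sigma_p
    t_on <- max(0.5, 6 * sigma_p)
    total <- t_on + dur + 0.5
    t <- seq(0, total, by = 1 / rate)
    x <- pcg_burst(t, t_on, dur, f_p, 1)
    xf <- if (is.null(spec)) x else apply_filter(spec, x, zero_phase)
    env <- analytic_envelope(xf)
    ip <- which.max(env)
    est <- estimate_burst(env, rate, ip)
    if (is.null(est)) return(NULL)
    seg <- xf[max(1, round((est$t_peak - 3 * est$sigma) * rate)):
              min(length(xf), round((est$t_peak + 3 * est$sigma) * rate))]
    list(bias = est$onset - t_on, sigma = est$sigma,
         f = spectral_centroid(seg, rate))
  }
  res <- NULL
  for (k in seq_len(n_iter)) {
    res <- run_probe(f_p, sigma_p)
    if (is.null(res)) return(0)
    sigma_p <- max(sigma_p + (sigma_meas - res$sigma), 2e-3)
    if (is.finite(res$f) && res$f > 1)
      f_p <- max(f_p + (f_meas - res$f), 5)
  }
  res <- run_probe(f_p, sigma_p)
  if (is.null(res)) 0 else res$bias
}

#' Detect first-heart-tone (S1) triggers in a phonocardiogram
#'
#' Signal chain: inverse Chebyshev low-pass (zero-phase) -> envelope
#' (rectify + 25 ms moving average) -> adaptive threshold (60\% of the
#' running peak over the trailing 3 s, with a half-maximum floor) ->
#' rising-edge burst detection with a refractory period. Each detected
#' burst is then refined to its onset with a Gaussian envelope model on
#' the analytic envelope, self-calibrated against the filter's envelope
#' broadening, and quantized to the trace's sampling grid. Conceptually
#' each emitted time is the leading edge of a rectangular trigger pulse
#' of width `pulse_width_ms`.
#'
#' @param pcg A [channel_trace()] (ACT or MIC).
#' @param spec Optional `filter_spec`; by default a third-order inverse
#'   Chebyshev low-pass with stopband edge `min(105, 0.45 * rate)` Hz is
#'   designed for the trace's rate (105 Hz is above Nyquist for the
#'   200 Hz ACT logging rate).
#' @param refractory_ms Minimum spacing between triggers, ms.
#' @param pulse_width_ms Width of the conceptual output pulse, ms
#'   (metadata only).
#' @return A [trigger_train()] of modality `ACT`.
#' @export
detect_s1_triggers <- function(pcg, spec = NULL, refractory_ms = 300,
                               pulse_width_ms = 10) {
  rate <- pcg$rate
  x <- pcg$samples
  if (!length(x) || all(x == 0))
    return(trigger_train("ACT", numeric(0)))
  if (is.null(spec))
    spec <- design_heart_sound_filter(rate,
                                      cutoff = min(105, 0.45 * rate))
  xf <- apply_filter(spec, x, zero_phase = TRUE)
  env <- moving_average(abs(xf), round(0.025 * rate))
  gmax <- max(env)
  if (gmax <= 0) return(trigger_train("ACT", numeric(0)))
  thr <- pmax(0.6 * running_max(env, round(3 * rate)), 0.5 * gmax)
  above <- env >= thr & env > 0
  rising <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rising)) return(trigger_train("ACT", numeric(0)))
  henv <- analytic_envelope(xf)
  refr <- refractory_ms / 1000
  bursts <- list()
  last <- -Inf
  for (i in rising) {
    t_cross <- (i - 1) / rate
    if (t_cross - last < refr) next
    est <- estimate_burst(henv, rate, i)
    if (is.null(est)) next
    bursts[[length(bursts) + 1L]] <- c(est$t_peak, est$sigma, est$onset, i)
    last <- t_cross
  }
  if (!length(bursts)) return(trigger_train("ACT", numeric(0)))
  bm <- do.call(rbind, bursts)
  sigma_med <- stats::median(bm[, 2])
  i_med <- bm[which.min(abs(bm[, 2] - sigma_med)), 4]
  est_med <- estimate_burst(henv, rate, i_med)
  seg <- xf[max(1, round((est_med$t_peak - 3 * sigma_med) * rate)):
            min(length(xf), round((est_med$t_peak + 3 * sigma_med) * rate))]
  f_med <- spectral_centroid(seg, rate)
  if (!is.finite(f_med) || f_med <= 1) f_med <- 35
  bias <- onset_probe_bias(rate, spec, f_med, sigma_med)
  onsets <- bm[, 3] - bias
  onsets <- pcg$t0 + round(onsets * rate) / rate
  onsets <- onsets[onsets >= 0]
  onsets <- sort(onsets)
  keep <- c(TRUE, diff(onsets) >= refr * 0.5)
  trigger_train("ACT", unique(onsets[keep]))
}
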