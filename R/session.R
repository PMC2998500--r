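# Scanner monitoring-unit trigger emulation and full-session assembly.

# Rising-edge threshold detector: threshold is 60% of the running peak
# over the trailing `window_s`, with a floor at `floor_frac` of the global
# maximum (the offline analogue of the monitoring unit's training period),
# plus a refractory interval. Returns times in seconds.
cpmu_detect <- function(x, rate, t0 = 0, thresh_frac = 0.6, window_s = 3,
                        refractory_s = 0.3, floor_frac = 0.5) {
  n <- length(x)
  if (!n) return(numeric(0))
  gmax <- max(x)
  if (gmax <= 0) return(numeric(0))
  thr <- pmax(thresh_frac * running_max(x, round(window_s * rate)),
              floor_frac * gmax)
  above <- x >= thr & x > 0
  rising <- which(above & !c(FALSE, above[-n]))
  out <- numeric(0)
  last <- -Inf
  for (i in rising) {
    ti <- t0 + (i - 1) / rate
    if (ti - last < refractory_s) next
    out <- c(out, ti)
    last <- ti
  }
  out
}

#' Emulate the scanner monitoring unit's trigger detection
#'
#' Applies the threshold-crossing detector (60\% of the running peak over
#' the trailing 3 s, 300 ms refractory) to the raw ECG or POX channel, or
#' the full filter + envelope heart-sound chain ([detect_s1_triggers()])
#' to the ACT channel. At isocenter field position the ECG detector fires
#' on magneto-hydrodynamic T-wave bumps whenever they exceed the
#' threshold, producing the characteristic mis-registrations.
#'
#' @param log A [physio_log()] containing the modality's channel.
#' @param modality `"ECG"`, `"POX"` or `"ACT"`.
#' @param config A [simulation_config()] (detector parameters are fixed;
#'   kept for interface symmetry and future extension).
#' @return A [trigger_train()].
#' @export
simulate_cpmu_triggers <- function(log, modality, config = NULL) {
  if (!modality %in% TRIGGER_MODALITIES)
    cg_argument_error(sprintf("unknown modality '%s'", modality))
  ch <- log$channels[[modality]]
  if (is.null(ch))
    cg_argument_error(sprintf("log has no %s channel", modality))
  if (modality == "ACT") {
    tr <- detect_s1_triggers(ch)
    return(trigger_train("ACT", tr$times))
  }
  times <- cpmu_detect(ch$samples, ch$rate, ch$t0)
  if (modality == "ECG" && length(times)) {
    # vector-ECG QRS detection marks the R peak, not the threshold
    # crossing on the upslope; refine and quantize to the sampling grid
    pk <- refine_peak_times(ch$samples, ch$rate, ch$t0, times,
                            search_s = 0.04)
    times <- sort(unique(ch$t0 +
                           round((pk - ch$t0) * ch$rate) / ch$rate))
  }
  trigger_train(modality, times)
}

# Mean-square pressure of `x` restricted to a frequency band (ideal FFT
# mask), evaluated over a set of time windows. Independent of the Hann
# short-time SPL estimator, so generator calibration and measurement do
# not share a code path.
band_power_windows <- function(x, rate, windows, f_lo, f_hi) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(n - n0)))
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)   # two-sided
  X[f < f_lo | f > f_hi] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE) / n)[seq_len(n0)]
  t <- (seq_len(n0) - 1) / rate
  n <- n0
  sel <- rep(FALSE, n)
  for (i in seq_len(nrow(windows)))
    sel <- sel | (t >= windows[i, 1] & t <= windows[i, 2])
  mean(xb[sel]^2)
}

#' Synthesize the microphone channel: heart sounds plus gradient noise
#'
#' Heart-sound bursts (as in [synthesize_pcg()], at the microphone rate)
#' are mixed with calibrated gradient-switching noise
#' ([synthesize_gradient_noise()]). The heart-sound level is set so that
#' the 10-50 Hz band SNR between cardiac-activity windows and noise-only
#' windows equals `config$snr_cardiac_db`.
#'
#' @param schedule A [draw_cycle_schedule()] result.
#' @param config A [simulation_config()].
#' @param duration Duration in seconds (default: covers the schedule).
#' @param noise_gate Optional two-column matrix of (start, end) windows
#'   outside which the gradient noise is silenced (scan windows); `NULL`
#'   keeps the noise running continuously.
#' @return A `MIC` [channel_trace()] in Pa, with attributes
#'   `"cardiac_windows"` and `"noise_windows"`.
#' @export
synthesize_mic_mixture <- function(schedule, config, duration = NULL,
                                   noise_gate = NULL) {
  if (is.null(duration)) duration <- schedule_duration(schedule, config)
  rate <- config$mic_rate
  heart <- synthesize_pcg(schedule, config, duration = duration,
                          rate = rate)$samples
  noise <- synthesize_gradient_noise(config, duration, rate = rate)$samples
  n <- min(length(heart), length(noise))
  heart <- heart[seq_len(n)]; noise <- noise[seq_len(n)]
  if (!is.null(noise_gate) && nrow(noise_gate)) {
    t <- (seq_len(n) - 1) / rate
    gate <- rep(0, n)
    for (i in seq_len(nrow(noise_gate)))
      gate[t >= noise_gate[i, 1] & t <= noise_gate[i, 2]] <- 1
    noise <- noise * gate
  }
  s1 <- schedule$s1_times
  rr_s <- schedule$rr / 1000
  cw <- cbind(s1, s1 + 0.15)
  nw <- cbind(schedule$r_times + 0.45 * rr_s,
              schedule$r_times + 0.75 * rr_s)
  keep <- cw[, 2] < duration & nw[, 2] < duration
  cw <- cw[keep, , drop = FALSE]; nw <- nw[keep, , drop = FALSE]
  if (nrow(cw)) {
    hp <- band_power_windows(heart, rate, cw, 10, 50)
    np <- band_power_windows(noise, rate, cw, 10, 50)
    if (np > 0 && hp > 0)
      heart <- heart * sqrt(np * 10^(config$snr_cardiac_db / 10) / hp)
  }
  out <- channel_trace("MIC", rate = rate, samples = heart + noise,
                       t0 = 0, units = "Pa")
  attr(out, "cardiac_windows") <- cw
  attr(out, "noise_windows") <- nw
  out
}

#' Simulate a complete gated-acquisition session
#'
#' Composes the cycle schedule, all five channels (ECG, POX, ACT, RESP,
#' MIC), the three trigger trains emulated from the monitoring-unit
#' detector, and the session metadata. Identical configurations (same
#' seed) yield bit-identical logs.
#'
#' @param config A [simulation_config()].
#' @param subject Subject identifier stored in the metadata.
#' @return A [physio_log()]; ground truth (cycle schedule, POX peak times
#'   and breath-hold schedule) is attached as attribute `"truth"`.
#' @export
simulate_session <- function(config, subject = "synthetic") {
  schedule <- draw_cycle_schedule(config)
  duration <- schedule_duration(schedule, config)
  ecg <- synthesize_ecg(schedule, config, duration)
  act <- synthesize_pcg(schedule, config, duration)
  pox <- synthesize_pox(schedule, config, duration)
  resp <- synthesize_respiration(config, duration)
  holds <- attr(resp, "holds")
  gate <- if (nrow(holds)) cbind(holds[, 1], holds[, 1] + holds[, 2])
          else NULL
  mic <- synthesize_mic_mixture(schedule, config, duration,
                                noise_gate = gate)
  log <- physio_log(
    channels = list(ecg, pox, act, resp, mic),
    meta = list(field_position = config$field_position,
                tr_s = config$tr_s, te_s = config$te_s,
                subject = subject))
  log$triggers <- list(
    ECG = simulate_cpmu_triggers(log, "ECG", config),
    POX = simulate_cpmu_triggers(log, "POX", config),
    ACT = simulate_cpmu_triggers(log, "ACT", config))
  attr(log, "truth") <- list(schedule = schedule,
                             pox_peaks = attr(pox, "peak_times"),
                             holds = holds)
  log
}

#' Estimate per-cycle POX pulse peak latencies
#'
#' For each R time, the POX pulse peak is located as the maximum of a
#' spline-upsampled excerpt of the POX trace in a window after R, and the
#' latency (peak minus R) is returned in ms.
#'
#' @param pox A `POX` [channel_trace()].
#' @param r_times R-wave times in seconds.
#' @param window Search window after each R, seconds (default
#'   `c(0.1, 0.7)`).
#' @return Numeric vector of latencies in ms (`NA` where no pulse found).
#' @export
estimate_pox_latency <- function(pox, r_times, window = c(0.1, 0.7)) {
  tt <- trace_times(pox)
  x <- pox$samples
  vapply(r_times, function(r) {
    sel <- which(tt >= r + window[1] & tt <= r + window[2])
    if (length(sel) < 4) return(NA_real_)
    fine <- seq(tt[sel[1]], tt[sel[length(sel)]], by = 0.001)
    sp <- stats::spline(tt[sel], x[sel], xout = fine)
    if (max(sp$y) <= 0) return(NA_real_)
    (fine[which.max(sp$y)] - r) * 1000
  }, numeric(1))
}
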