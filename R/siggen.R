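# Synthetic physiological session generator.
#
# Emulates the statistical structure of gated cardiovascular MR sessions
# at ultrahigh field: R-R intervals with subject-level mean/SD, a fixed
# R-to-S1 electromechanical delay (~30 ms), pulse-oximetry pulses arriving
# ~350 ms after R with amplitude/width scatter, magneto-hydrodynamic
# T-wave elevation scaling with static field strength, breath-hold
# schedules, and gradient-switching acoustic noise with sharp lines at
# k/TR and 1/TE.

#' Simulation configuration
#'
#' Defaults encode the reference conditions of the emulated study: R-to-S1
#' delay Normal(29.65, 4.43) ms, POX pulse latency ~350 ms, MHD T-wave gain
#' 1.2 x R amplitude at 7.0 T, CINE FLASH timing TR = 4 ms / TE = 2 ms,
#' gradient noise peaking at 120 dB SPL and a 30 dB cardiac acoustic SNR in
#' the low-frequency band.
#'
#' @param n_cycles Number of cardiac cycles.
#' @param rr_mean,rr_sd R-R interval mean and SD, ms.
#' @param r_to_s1_mean,r_to_s1_sd R-wave to first-heart-tone delay, ms.
#' @param pox_latency_mean,pox_latency_sd POX pulse peak latency after R, ms.
#' @param pox_amp_cv,pox_width_cv Coefficients of variation of the POX pulse
#'   amplitude and width multipliers (fractions in \[0, 1)).
#' @param mhd_gain_at_7T MHD T-wave bump amplitude at isocenter, as a
#'   multiple of the R amplitude.
#' @param mhd_amp_cv Beat-to-beat coefficient of variation of the MHD bump
#'   amplitude (flow-dependent).
#' @param field_position `"home"` (~0.3 T at the sensors), `"front"`
#'   (~1.0 T) or `"isocenter"` (7.0 T).
#' @param tr_s,te_s Sequence repetition and echo time, seconds.
#' @param peak_spl_db Peak third-octave SPL of the gradient noise, dB.
#' @param snr_cardiac_db Cardiac-to-gradient-noise band SNR (10-50 Hz), dB.
#' @param mic_rate Microphone channel sampling rate, samples/s.
#' @param breath_hold_schedule Optional matrix/data.frame with columns
#'   `start`, `duration` (s); `NULL` for an automatic schedule of 15 s
#'   holds separated by 8 s of free breathing.
#' @param seed Integer seed; equal configurations give bit-equal sessions.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_cycles = 200,
                              rr_mean = 900, rr_sd = 50,
                              r_to_s1_mean = 29.65, r_to_s1_sd = 4.43,
                              pox_latency_mean = 350, pox_latency_sd = 8,
                              pox_amp_cv = 0.15, pox_width_cv = 0.15,
                              mhd_gain_at_7T = 1.2, mhd_amp_cv = 0.3,
                              field_position = "home",
                              tr_s = 0.004, te_s = 0.002,
                              peak_spl_db = 120, snr_cardiac_db = 30,
                              mic_rate = 2000,
                              breath_hold_schedule = NULL,
                              seed = 1L) {
  if (n_cycles < 0) cg_argument_error("n_cycles must be >= 0")
  if (rr_mean <= 0) cg_argument_error("rr_mean must be > 0")
  if (rr_sd < 0) cg_argument_error("rr_sd must be >= 0")
  if (pox_amp_cv < 0 || pox_amp_cv >= 1 ||
      pox_width_cv < 0 || pox_width_cv >= 1)
    cg_argument_error("pox cv parameters must lie in [0, 1)")
  if (!(tr_s > te_s && te_s > 0))
    cg_argument_error("need tr_s > te_s > 0")
  if (!field_position %in% FIELD_POSITIONS)
    cg_argument_error("field_position must be home/front/isocenter")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: %d cycles, RR %g+/-%g ms, %s position, seed %d>\n",
    x$n_cycles, x$rr_mean, x$rr_sd, x$field_position, as.integer(x$seed)))
  invisible(x)
}

RR_FLOOR_MS <- 300  # physiological floor preventing non-positive intervals

#' Draw the cardiac cycle schedule
#'
#' Successive R-R intervals are Normal(`rr_mean`, `rr_sd`) truncated at a
#' 300 ms floor; S1 onsets follow each R wave by an independent
#' Normal(`r_to_s1_mean`, `r_to_s1_sd`) delay (truncated > 0).
#'
#' @param config A [simulation_config()].
#' @return An object of class `cycle_schedule` with fields `r_times`,
#'   `s1_times` (s) and `rr` (ms).
#' @export
draw_cycle_schedule <- function(config) {
  n <- config$n_cycles
  if (n < 0) cg_argument_error("n_cycles must be >= 0")
  with_seed(config$seed, {
    rr <- pmax(stats::rnorm(n, config$rr_mean, config$rr_sd), RR_FLOOR_MS)
    delay <- pmax(stats::rnorm(n, config$r_to_s1_mean, config$r_to_s1_sd),
                  1e-3)
  })
  if (n == 0L) {
    r_times <- numeric(0); s1 <- numeric(0); rr <- numeric(0)
  } else {
    r_times <- c(0, cumsum(rr[-n])) / 1000
    s1 <- r_times + delay / 1000
  }
  structure(list(r_times = r_times, s1_times = s1, rr = rr),
            class = "cycle_schedule")
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf("<cycle_schedule: %d cycles, span %.1f s>\n",
              length(x$r_times),
              if (length(x$r_times)) max(x$r_times) else 0))
  invisible(x)
}

schedule_duration <- function(schedule, config) {
  if (!length(schedule$r_times)) return(2)
  max(schedule$r_times) + utils::tail(schedule$rr, 1) / 1000 + 0.5
}

gauss_bump <- function(t, center, sigma, amp, truncate = Inf) {
  u <- (t - center) / sigma
  v <- amp * exp(-0.5 * u^2)
  if (is.finite(truncate)) v[abs(u) > truncate] <- 0
  v
}

# PQRST morphology: five Gaussian bumps per cycle (amplitudes in mV).
ECG_TEMPLATE <- list(
  P = list(dt = -0.180, sigma = 0.025, amp = 0.12),
  Q = list(dt = -0.025, sigma = 0.008, amp = -0.10),
  R = list(dt = 0.000, sigma = 0.008, amp = 1.00),
  S = list(dt = 0.025, sigma = 0.009, amp = -0.15))
T_FRACTION <- 0.40   # T-wave center at 0.40 * RR after R
T_SIGMA <- 0.040
T_AMP <- 0.30
MHD_SIGMA <- 0.050   # MHD bump shares the T-wave window

#' Synthesize the ECG channel
#'
#' Sum-of-Gaussians PQRST template per cycle plus an additive
#' magneto-hydrodynamic bump centered in the T-wave window whose amplitude
#' is `mhd_gain_at_7T * R_amplitude * (B_at_position / 7)` with
#' beat-to-beat scatter `mhd_amp_cv`.
#'
#' @param schedule A [draw_cycle_schedule()] result.
#' @param config A [simulation_config()].
#' @param duration Trace duration in s (default: covers the schedule).
#' @param rate Sampling rate (default 400 Hz, the ECG logging rate).
#' @return A [channel_trace()] labelled `ECG`, in mV.
#' @export
synthesize_ecg <- function(schedule, config, duration = NULL, rate = 400) {
  if (is.null(duration)) duration <- schedule_duration(schedule, config)
  t <- seq(0, duration, by = 1 / rate)
  x <- numeric(length(t))
  n <- length(schedule$r_times)
  B <- FIELD_STRENGTH_T[[config$field_position]]
  mhd_amp0 <- config$mhd_gain_at_7T * 1.0 * (B / 7.0)
  scatter <- with_seed(config$seed + 1L,
                       pmax(stats::rnorm(n, 1, config$mhd_amp_cv), 0.2))
  for (i in seq_len(n)) {
    r <- schedule$r_times[i]
    rr_s <- schedule$rr[i] / 1000
    lo <- max(1L, floor((r - 0.3) * rate))
    hi <- min(length(t), ceiling((r + rr_s) * rate) + 1L)
    idx <- lo:hi
    ti <- t[idx]
    v <- 0
    for (comp in ECG_TEMPLATE)
      v <- v + gauss_bump(ti, r + comp$dt, comp$sigma, comp$amp)
    tc <- r + T_FRACTION * rr_s
    v <- v + gauss_bump(ti, tc, T_SIGMA, T_AMP)
    v <- v + gauss_bump(ti, tc, MHD_SIGMA, mhd_amp0 * scatter[i])
    x[idx] <- x[idx] + v
  }
  channel_trace("ECG", rate = rate, samples = x, t0 = 0)
}

S1_DURATION_S <- 0.080   # total S1 burst duration (6 sigma)
S1_FREQ_HZ <- 35
S2_DURATION_S <- 0.060
S2_FREQ_HZ <- 55
S2_AMP <- 0.4
S2_FRACTION <- 0.35      # S2 onset at 0.35 * RR after R

pcg_burst <- function(t, onset, dur, freq, amp) {
  sigma <- dur / 6
  center <- onset + dur / 2
  u <- (t - center) / sigma
  env <- exp(-0.5 * u^2)
  env[t < onset | t > onset + dur] <- 0
  amp * env * cos(2 * pi * freq * (t - onset))
}

#' Synthesize the phonocardiogram (ACT) channel
#'
#' Each cycle contributes a Gaussian-enveloped first heart tone (center
#' ~35 Hz, 80 ms) starting at its scheduled S1 onset and a smaller second
#' tone at `r_time + 0.35 * RR`. Over 95\% of the S1 spectral energy lies
#' below 100 Hz.
#'
#' @inheritParams synthesize_ecg
#' @param rate Sampling rate (default 200 Hz, the ACT logging rate).
#' @return A [channel_trace()] labelled `ACT`.
#' @export
synthesize_pcg <- function(schedule, config, duration = NULL, rate = 200) {
  if (is.null(duration)) duration <- schedule_duration(schedule, config)
  t <- seq(0, duration, by = 1 / rate)
  x <- numeric(length(t))
  n <- length(schedule$r_times)
  for (i in seq_len(n)) {
    s1 <- schedule$s1_times[i]
    s2 <- schedule$r_times[i] + S2_FRACTION * schedule$rr[i] / 1000
    lo <- max(1L, floor(s1 * rate))
    hi <- min(length(t), ceiling((s2 + S2_DURATION_S) * rate) + 2L)
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] +
      pcg_burst(t[idx], s1, S1_DURATION_S, S1_FREQ_HZ, 1) +
      pcg_burst(t[idx], s2, S2_DURATION_S, S2_FREQ_HZ, S2_AMP)
  }
  channel_trace("ACT", rate = rate, samples = x, t0 = 0)
}

POX_RISE_S <- 0.06    # rise half-Gaussian sigma (scaled by width multiplier)
POX_DECAY_S <- 0.25   # decay half-Gaussian sigma (broad top, slow fall)

# Asymmetric pulse with a smoothly varying width (fast rise, broad top,
# slow decay). The width blend is C-infinity, so the peak has continuous
# curvature and interpolation-based peak pickers are unbiased.
pox_pulse <- function(t, peak, amp, width) {
  d <- t - peak
  sig <- width * (POX_RISE_S +
                    (POX_DECAY_S - POX_RISE_S) * (1 + tanh(d / 0.05)) / 2)
  v <- amp * exp(-(d / sig)^2)
  v[abs(d) > 4 * POX_DECAY_S] <- 0
  v
}

#' Synthesize the pulse-oximetry channel
#'
#' One asymmetric pulse per cycle (fast rise, broad top, slow decay)
#' peaking `Normal(pox_latency_mean, pox_latency_sd)` ms after each R wave,
#' with independent per-pulse amplitude and width multipliers
#' `Normal(1, cv)`.
#'
#' @inheritParams synthesize_ecg
#' @param rate Sampling rate (default 50 Hz, the POX logging rate).
#' @return A [channel_trace()] labelled `POX`.
#' @export
synthesize_pox <- function(schedule, config, duration = NULL, rate = 50) {
  if (is.null(duration)) duration <- schedule_duration(schedule, config)
  t <- seq(0, duration, by = 1 / rate)
  x <- numeric(length(t))
  n <- length(schedule$r_times)
  par <- with_seed(config$seed + 3L, list(
    lat = stats::rnorm(n, config$pox_latency_mean, config$pox_latency_sd),
    amp = pmax(stats::rnorm(n, 1, config$pox_amp_cv), 0.3),
    wid = pmax(stats::rnorm(n, 1, config$pox_width_cv), 0.3)))
  peaks <- schedule$r_times + pmax(par$lat, 50) / 1000
  for (i in seq_len(n)) {
    lo <- max(1L, floor((peaks[i] - 1.2) * rate))
    hi <- min(length(t), ceiling((peaks[i] + 1.2) * rate))
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + pox_pulse(t[idx], peaks[i], par$amp[i], par$wid[i])
  }
  out <- channel_trace("POX", rate = rate, samples = x, t0 = 0)
  attr(out, "peak_times") <- peaks
  out
}

# Frequencies and relative amplitudes of the gradient-switching lines,
# folding components that coincide (e.g. 2/TR with 1/TE when TR = 2 TE).
gradient_lines <- function(tr_s, te_s, nyquist) {
  f <- c((1:3) / tr_s, 1 / te_s)
  f <- f[f < nyquist]
  uf <- sort(unique(round(f, 9)))
  amp <- vapply(uf, function(ff) sum(abs(f - ff) < 1e-9), numeric(1))
  list(freq = uf, amp = amp)
}

third_octave_band <- function(center) c(center / 2^(1 / 6), center * 2^(1 / 6))

# Power (Pa^2) of the line set falling in the loudest standard
# third-octave band, for unit line amplitude scale.
max_third_octave_power <- function(lines) {
  centers <- 1000 * 10^(0.1 * (-20:13))   # 10 Hz .. ~20 kHz
  pw <- vapply(centers, function(fc) {
    b <- third_octave_band(fc)
    sum((lines$amp[lines$freq >= b[1] & lines$freq < b[2]])^2 / 2)
  }, numeric(1))
  max(pw)
}

P_REF <- 20e-6  # SPL reference pressure, Pa

#' Synthesize gradient-switching acoustic noise
#'
#' Sinusoids at 1/TR, 2/TR, 3/TR and 1/TE (coincident components add
#' coherently) plus a broadband Gaussian floor 40 dB below the loudest
#' line, globally scaled so the loudest third-octave band reads
#' `peak_spl_db` dB SPL.
#'
#' @param config A [simulation_config()].
#' @param duration Duration in seconds (>= 0).
#' @param rate Sampling rate (default `config$mic_rate`).
#' @return A [channel_trace()] labelled `MIC`, in Pa.
#' @export
synthesize_gradient_noise <- function(config, duration, rate = NULL) {
  if (duration < 0) cg_argument_error("duration must be >= 0")
  if (is.null(rate)) rate <- config$mic_rate
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  lines <- gradient_lines(config$tr_s, config$te_s, rate / 2)
  x <- numeric(n)
  for (i in seq_along(lines$freq))
    x <- x + lines$amp[i] * sin(2 * pi * lines$freq[i] * t)
  pmax_band <- max_third_octave_power(lines)
  scale <- sqrt(P_REF^2 * 10^(config$peak_spl_db / 10) / pmax_band)
  sigma_floor <- sqrt(pmax_band / 1e4)   # 40 dB below the loudest line
  floor_noise <- with_seed(config$seed + 4L,
                           stats::rnorm(n, 0, sigma_floor))
  channel_trace("MIC", rate = rate, samples = scale * (x + floor_noise),
                t0 = 0, units = "Pa")
}

RESP_FREQ_HZ <- 0.25
RESP_RAMP_S <- 0.4

default_breath_hold_schedule <- function(duration,
                                         hold_s = 15, gap_s = 8,
                                         lead_in_s = 5) {
  starts <- seq(lead_in_s, max(lead_in_s, duration - hold_s - 1),
                by = hold_s + gap_s)
  starts <- starts[starts + hold_s <= duration - 0.5]
  if (!length(starts)) return(cbind(start = numeric(0),
                                    duration = numeric(0)))
  cbind(start = starts, duration = rep(hold_s, length(starts)))
}

resolve_holds <- function(config, duration) {
  sched <- config$breath_hold_schedule
  if (is.null(sched)) sched <- default_breath_hold_schedule(duration)
  sched <- as.matrix(sched)
  if (nrow(sched)) {
    if (any(sched[, 1] < 0) || any(sched[, 1] + sched[, 2] > duration))
      cg_argument_error("breath holds must lie within [0, duration]")
    o <- order(sched[, 1])
    sched <- sched[o, , drop = FALSE]
    if (nrow(sched) > 1 &&
        any(sched[-1, 1] < (sched[-nrow(sched), 1] +
                            sched[-nrow(sched), 2])))
      cg_argument_error("breath-hold intervals overlap")
  }
  sched
}

#' Synthesize the respiration channel
#'
#' Quasi-sinusoidal free breathing (~0.25 Hz) replaced by a near-constant
#' plateau (frozen at the hold-onset value, short cosine ramps) during each
#' scheduled breath-hold.
#'
#' @param config A [simulation_config()].
#' @param duration Duration in seconds.
#' @param rate Sampling rate (default 50 Hz).
#' @return A [channel_trace()] labelled `RESP`. The resolved hold schedule
#'   is attached as attribute `"holds"`.
#' @export
synthesize_respiration <- function(config, duration, rate = 50) {
  if (duration < 0) cg_argument_error("duration must be >= 0")
  sched <- resolve_holds(config, duration)
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  breathing <- sin(2 * pi * RESP_FREQ_HZ * t) +
    0.15 * sin(2 * pi * 2 * RESP_FREQ_HZ * t + 0.7)
  x <- breathing
  for (r in seq_len(nrow(sched))) {
    s <- sched[r, 1]; e <- s + sched[r, 2]
    plateau <- sin(2 * pi * RESP_FREQ_HZ * s) +
      0.15 * sin(2 * pi * 2 * RESP_FREQ_HZ * s + 0.7)
    inside <- t >= s & t < e
    x[inside] <- plateau
    ramp_in <- t >= (s - RESP_RAMP_S) & t < s
    w <- (t[ramp_in] - (s - RESP_RAMP_S)) / RESP_RAMP_S
    x[ramp_in] <- (1 - w) * breathing[ramp_in] + w * plateau
    ramp_out <- t >= e & t < (e + RESP_RAMP_S)
    w <- (t[ramp_out] - e) / RESP_RAMP_S
    x[ramp_out] <- w * breathing[ramp_out] + (1 - w) * plateau
  }
  out <- channel_trace("RESP", rate = rate, samples = x, t0 = 0)
  attr(out, "holds") <- sched
  out
}
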