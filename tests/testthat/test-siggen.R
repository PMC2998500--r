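test_that("cycle schedule: degenerate, empty and statistical behavior", {
  cfg0 <- simulation_config(n_cycles = 0)
  s0 <- draw_cycle_schedule(cfg0)
  expect_length(s0$r_times, 0)
  expect_length(s0$s1_times, 0)

  cfg <- simulation_config(n_cycles = 5, rr_mean = 1000, rr_sd = 0,
                           r_to_s1_mean = 30, r_to_s1_sd = 0)
  s <- draw_cycle_schedule(cfg)
  expect_equal(s$r_times, 0:4)
  expect_equal(s$s1_times, 0:4 + 0.030)

  cfg2 <- simulation_config(n_cycles = 200, rr_mean = 869, rr_sd = 89,
                            seed = 12)
  s2 <- draw_cycle_schedule(cfg2)
  expect_equal(mean(s2$rr), 869, tolerance = 2 * 89 / sqrt(200) / 869)
  expect_true(all(diff(s2$r_times) > 0))
  expect_true(all(s2$s1_times > s2$r_times))
  expect_error(simulation_config(n_cycles = -1),
               class = "cg_argument_error")
})

test_that("ECG synthesis: MHD bump scales with field position", {
  base <- list(n_cycles = 20, rr_sd = 0, seed = 2)
  sch <- draw_cycle_schedule(do.call(simulation_config, base))
  tw_max <- function(fp) {
    cfg <- do.call(simulation_config, c(base, list(field_position = fp)))
    e <- synthesize_ecg(sch, cfg)
    tt <- trace_times(e)
    max(vapply(sch$r_times, function(r)
      max(e$samples[tt > r + 0.25 & tt < r + 0.55]), numeric(1)))
  }
  # home: (0.3/7) * 1.2 ~ 0.05 of R on top of the 0.3 T wave -> undistorted
  expect_lt(tw_max("home"), 0.5)
  # isocenter: T-window amplitude reaches/exceeds the R amplitude
  expect_gte(tw_max("isocenter"), 1)
  # empty schedule -> baseline trace
  e0 <- synthesize_ecg(draw_cycle_schedule(simulation_config(n_cycles = 0)),
                       simulation_config(n_cycles = 0), duration = 2)
  expect_true(all(e0$samples == 0))
  expect_equal(e0$rate, 400)
})

test_that("PCG synthesis: spectral content and envelope peak placement", {
  cfg <- simulation_config(n_cycles = 1, rr_sd = 0, r_to_s1_sd = 0,
                           seed = 1)
  sch <- draw_cycle_schedule(cfg)
  p <- synthesize_pcg(sch, cfg, duration = 1, rate = 2000)
  P <- Mod(stats::fft(p$samples))^2
  f <- (seq_along(P) - 1) * 2000 / length(P)
  half <- f <= 1000
  expect_lt(sum(P[half & f > 105]) / sum(P[half]), 0.05)
  # envelope peak at onset + half the S1 duration, within one sample
  p200 <- synthesize_pcg(sch, cfg, duration = 1)
  env <- cardiogate:::analytic_envelope(p200$samples)
  tt <- trace_times(p200)
  s1_win <- tt >= sch$s1_times[1] - 0.01 & tt <= sch$s1_times[1] + 0.09
  t_peak <- tt[s1_win][which.max(env[s1_win])]
  expect_lt(abs(t_peak - (sch$s1_times[1] + 0.040)), 1 / 200)
  expect_true(all(synthesize_pcg(draw_cycle_schedule(
    simulation_config(n_cycles = 0)), cfg, duration = 1)$samples == 0))
})

test_that("POX synthesis: degenerate latency and mean latency recovery", {
  cfg0 <- simulation_config(n_cycles = 10, rr_sd = 0, pox_latency_sd = 0,
                            pox_amp_cv = 0, pox_width_cv = 0, seed = 1)
  sch0 <- draw_cycle_schedule(cfg0)
  p0 <- synthesize_pox(sch0, cfg0)
  expect_equal(attr(p0, "peak_times"), sch0$r_times + 0.350)
  lat0 <- estimate_pox_latency(p0, sch0$r_times)
  expect_equal(mean(lat0, na.rm = TRUE), 350, tolerance = 5)

  cfg <- simulation_config(n_cycles = 100, seed = 8)
  sch <- draw_cycle_schedule(cfg)
  p <- synthesize_pox(sch, cfg)
  lat <- estimate_pox_latency(p, sch$r_times)
  expect_equal(mean(lat, na.rm = TRUE), 350, tolerance = 10 / 350)
  expect_true(all(attr(p, "peak_times") > sch$r_times))
})

test_that("gradient noise: line placement and calibrated peak SPL", {
  cfg <- simulation_config(seed = 4)
  expect_length(synthesize_gradient_noise(cfg, 0)$samples, 0)
  gn <- synthesize_gradient_noise(cfg, 6)
  # 1/TE coincides with 2/TR at 500 Hz for TR = 4 ms, TE = 2 ms
  mags <- vapply(c(250, 500, 750), function(f)
    goertzel_mag(gn$samples, f, gn$rate), numeric(1))
  expect_equal(mags[2] / mags[1], 2, tolerance = 0.05)
  grid <- compute_spectrogram(gn, window_s = 0.25)
  b <- band_spl(grid, 500 / 2^(1 / 6), 500 * 2^(1 / 6))
  expect_equal(b$spl, 120, tolerance = 0.5)
})

test_that("respiration: holds as low-variance plateaus", {
  cfg <- simulation_config(
    seed = 2,
    breath_hold_schedule = cbind(start = c(10, 40, 70),
                                 duration = c(12, 15, 12)))
  resp <- synthesize_respiration(cfg, 95)
  tt <- trace_times(resp)
  inside <- tt >= 11 & tt <= 21
  outside <- tt >= 25 & tt <= 38
  expect_lt(stats::sd(resp$samples[inside]),
            0.05 * stats::sd(resp$samples[outside]))
  holds <- identify_breath_holds(resp)
  expect_equal(nrow(holds), 3)
  # free breathing only -> no holds detected
  free <- synthesize_respiration(
    simulation_config(breath_hold_schedule = cbind(numeric(0),
                                                   numeric(0))), 60)
  expect_equal(nrow(identify_breath_holds(free)), 0)
  expect_error(synthesize_respiration(
    simulation_config(breath_hold_schedule = cbind(c(5, 10), c(10, 5))),
    60), class = "cg_argument_error")
})

test_that("CPMU emulation: clean ECG one trigger per cycle near R", {
  cfg <- simulation_config(n_cycles = 30, seed = 5)
  sch <- draw_cycle_schedule(cfg)
  log <- physio_log(channels = list(synthesize_ecg(sch, cfg)))
  tr <- simulate_cpmu_triggers(log, "ECG", cfg)
  expect_length(tr$times, 30)
  err <- vapply(tr$times, function(t)
    1000 * abs(t - sch$r_times[which.min(abs(sch$r_times - t))]),
    numeric(1))
  expect_lt(max(err), 10)
  expect_error(simulate_cpmu_triggers(log, "RESP", cfg),
               class = "cg_argument_error")
  expect_error(simulate_cpmu_triggers(log, "POX", cfg),
               class = "cg_argument_error")
})

test_that("isocenter ECG mis-registration emerges and spans up to ~30%", {
  rates <- vapply(1:4, function(seed) {
    cfg <- simulation_config(n_cycles = 80, field_position = "isocenter",
                             seed = seed)
    sch <- draw_cycle_schedule(cfg)
    log <- physio_log(channels = list(synthesize_ecg(sch, cfg)))
    tr <- simulate_cpmu_triggers(log, "ECG", cfg)
    n <- length(sch$r_times)
    off <- vapply(seq_len(n - 1), function(i) {
      inside <- tr$times[tr$times >= sch$r_times[i] - 0.025 &
                         tr$times < sch$r_times[i + 1] - 0.025]
      if (length(inside)) 1000 * (inside[1] - sch$r_times[i]) else NA_real_
    }, numeric(1))
    failure_rate(off)
  }, numeric(1))
  expect_gt(max(rates), 0.08)
  expect_lt(max(rates), 0.45)
})

test_that("simulate_session is bit-reproducible and complete", {
  cfg <- simulation_config(n_cycles = 12, seed = 21)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  attr(a, "truth") <- NULL; attr(b, "truth") <- NULL
  expect_identical(a, b)
  expect_setequal(names(a$channels), c("ECG", "POX", "ACT", "RESP", "MIC"))
  expect_setequal(names(a$triggers), c("ECG", "POX", "ACT"))
  expect_equal(a$meta$field_position, "home")
  # empty session
  e <- simulate_session(simulation_config(n_cycles = 0, seed = 1))
  expect_length(e$triggers$ACT$times, 0)
})

test_that("session-level delay recovery: ACT tickmarks land ~29.65 ms after R", {
  log <- simulate_session(simulation_config(n_cycles = 200, seed = 11))
  truth <- attr(log, "truth")
  r <- truth$schedule$r_times
  d <- vapply(log$triggers$ACT$times, function(t) {
    prev <- r[r <= t]
    if (length(prev)) 1000 * (t - max(prev)) else NA_real_
  }, numeric(1))
  expect_equal(mean(d, na.rm = TRUE), 29.65, tolerance = 1 / 29.65)
})

test_that("parameter recovery within 3 standard errors on 200 cycles", {
  cfg <- simulation_config(n_cycles = 200, rr_mean = 869, rr_sd = 89,
                           seed = 14)
  log <- simulate_session(cfg)
  truth <- attr(log, "truth")
  st <- analyze_triggers(log, r_times = truth$schedule$r_times)
  act <- st[st$modality == "ACT", ]
  n <- act$n_triggers
  expect_equal(act$interval_mean, 869, tolerance = 3 * 89 / sqrt(n) / 869)
  expect_equal(act$interval_sd, 89, tolerance = 3 * 89 / sqrt(n) / 89)
  expect_equal(act$offset_mean, 29.65, tolerance = 3 * 4.43 / sqrt(n) / 29.65)
  lat <- estimate_pox_latency(log$channels$POX, truth$schedule$r_times)
  expect_equal(mean(lat, na.rm = TRUE), 350,
               tolerance = 3 * 8 / sqrt(sum(is.finite(lat))) / 350)
})
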