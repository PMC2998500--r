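test_that("breath-hold identification matches the generated schedule", {
  sched <- cbind(start = c(12, 45, 80), duration = c(14, 12, 16))
  cfg <- simulation_config(seed = 3, breath_hold_schedule = sched)
  resp <- synthesize_respiration(cfg, 110)
  holds <- identify_breath_holds(resp)
  expect_equal(nrow(holds), 3)
  expect_equal(holds$start, sched[, 1], tolerance = 0.5 / 12)
  expect_equal(holds$end, sched[, 1] + sched[, 2], tolerance = 0.5 / 26)
  # single 12 s plateau in a 60 s trace
  cfg1 <- simulation_config(seed = 3,
                            breath_hold_schedule = cbind(20, 12))
  h1 <- identify_breath_holds(synthesize_respiration(cfg1, 60))
  expect_equal(nrow(h1), 1)
  expect_equal(c(h1$start, h1$end), c(20, 32), tolerance = 1 / 26)
  expect_error(identify_breath_holds(channel_trace("RESP", 50, 1:10)),
               class = "cg_argument_error")
})

test_that("segmentation: periodicity, degeneracy, insufficient data", {
  cfg <- simulation_config(n_cycles = 15, rr_mean = 900, rr_sd = 0,
                           seed = 2)
  sch <- draw_cycle_schedule(cfg)
  ecg <- synthesize_ecg(sch, cfg)
  seg <- segment_rr(ecg)
  expect_true(all(seg$shifts == 0))
  expect_equal(seg$reference, seg$cycles[seg$reference_index, ],
               ignore_attr = TRUE)
  expect_true(all(seg$cycles[, 2] > seg$cycles[, 1]))
  expect_error(segment_rr(channel_trace("ECG", 400, numeric(4000))),
               class = "cg_degenerate_correlation")
  one <- synthesize_ecg(draw_cycle_schedule(
    simulation_config(n_cycles = 1, seed = 1)),
    simulation_config(n_cycles = 1, seed = 1), duration = 1.5)
  expect_error(segment_rr(one), class = "cg_insufficient_data")
})

test_that("segmentation shifts equal the exhaustive correlation oracle", {
  n_agree <- 0L
  for (seed in 1:20) {
    cfg <- simulation_config(n_cycles = 10, rr_mean = 850, rr_sd = 60,
                             seed = seed)
    sch <- draw_cycle_schedule(cfg)
    ecg <- synthesize_ecg(sch, cfg)
    # perturb with deterministic noise so shifts are non-trivial
    set.seed(seed + 100)
    ecg$samples <- ecg$samples + stats::rnorm(length(ecg$samples), 0, 0.03)
    seg <- segment_rr(ecg, max_shift_ms = 50)
    L <- min(round((seg$reference[2] - seg$reference[1]) * 400),
             round(0.25 * 400))
    oracle <- brute_force_shifts(ecg$samples, 400, seg$cycles[, 1],
                                 seg$reference[1], L,
                                 round(0.050 * 400))
    expect_equal(seg$shifts, oracle / 400 * 1000)
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 20L)
})

test_that("segmentation mask realigns excerpts and handles constants", {
  cfg <- simulation_config(n_cycles = 20, rr_mean = 880, rr_sd = 40,
                           seed = 6)
  sch <- draw_cycle_schedule(cfg)
  ecg <- synthesize_ecg(sch, cfg)
  seg <- segment_rr(ecg)
  exc <- apply_segmentation_mask(seg, ecg)
  rel <- attr(exc, "rel_times")
  win <- rel <= 0.25
  ref_row <- exc[seg$reference_index, win]
  # realigned correlation >= unshifted correlation over the matched window
  for (i in seq_len(nrow(exc))[-seg$reference_index]) {
    un <- stats::approx(trace_times(ecg), ecg$samples,
                        xout = round(seg$cycles[i, 1] * 400) / 400 +
                          rel[win], rule = 2)$y
    expect_gte(stats::cor(exc[i, win], ref_row) + 1e-9,
               stats::cor(un, ref_row))
  }
  cst <- channel_trace("ECG", 400, rep(2, length(ecg$samples)))
  exc_c <- apply_segmentation_mask(seg, cst)
  expect_true(all(exc_c == 2))
  # ACT excerpts: S1 envelope peaks at a fixed within-cycle phase
  act <- synthesize_pcg(sch, cfg)
  exa <- apply_segmentation_mask(seg, act)
  ph <- apply(exa[, rel <= 0.2, drop = FALSE], 1, function(row)
    rel[which.max(cardiogate:::analytic_envelope(row))])
  expect_lte(diff(range(ph)), 0.015 + 2 * 4.43e-3 * 3)
  late <- channel_trace("ACT", 200, numeric(100),
                        t0 = max(seg$cycles) + 10)
  expect_error(apply_segmentation_mask(seg, late),
               class = "cg_argument_error")
})

test_that("tickmark reassignment matches a containment brute force", {
  cfg <- simulation_config(n_cycles = 15, rr_mean = 900, rr_sd = 40,
                           seed = 9)
  sch <- draw_cycle_schedule(cfg)
  ecg <- synthesize_ecg(sch, cfg)
  seg <- segment_rr(ecg)
  # exact R tickmarks -> all offsets equal the shifts (zero modulo shift)
  off0 <- reassign_tickmarks(seg, trigger_train("ECG", seg$r_times))
  expect_equal(off0, seg$shifts, ignore_attr = TRUE)
  off30 <- reassign_tickmarks(
    seg, trigger_train("ACT", seg$r_times + 0.030))
  expect_equal(off30, 30 + seg$shifts, ignore_attr = TRUE)
  # random tickmarks against an independent containment loop
  set.seed(4)
  ticks <- sort(stats::runif(40, min(seg$cycles), max(seg$cycles)))
  ticks <- ticks[c(TRUE, diff(ticks) > 1e-6)]
  off <- reassign_tickmarks(seg, trigger_train("ACT", ticks))
  g <- 0.025
  for (i in seq_len(nrow(seg$cycles))) {
    inside <- ticks[ticks >= seg$cycles[i, 1] - g &
                    ticks < seg$cycles[i, 2] - g]
    if (!length(inside)) expect_true(is.na(off[i]))
    else expect_equal(off[i],
                      (inside[1] - seg$r_times[i]) * 1000 + seg$shifts[i])
  }
})

test_that("jitter, cycle and offset statistics arithmetic", {
  expect_equal(trigger_jitter(c(10, 40, 82)), 72)
  expect_equal(trigger_jitter(rep(5, 10)), 0)
  expect_error(trigger_jitter(7), class = "cg_insufficient_data")

  cs <- cycle_statistics(c(0, 0.869, 1.738, 2.607))
  expect_equal(cs$interval_mean, 869)
  expect_equal(cs$interval_sd, 0)
  expect_error(cycle_statistics(c(0, 1)), class = "cg_insufficient_data")

  os <- trigger_offset_stats(rep(30, 5))
  expect_equal(os$offset_mean, 30)
  expect_equal(os$offset_sd, 0)
  expect_error(trigger_offset_stats(30), class = "cg_insufficient_data")
})

test_that("failure rate: counting, misses, mode handling", {
  expect_equal(failure_rate(c(20, 21, 22, 24, 25)), 0)
  expect_equal(failure_rate(c(rep(10, 7), rep(410, 3))), 0.3)
  expect_equal(failure_rate(c(10, 12, NA, NA)), 0.5)
  expect_error(failure_rate(numeric(0)), class = "cg_insufficient_data")
})

test_that("ECG failure rate is non-decreasing in MHD gain (seed-averaged)", {
  gains <- c(0, 0.4, 0.8, 1.2, 1.5)
  mean_rates <- vapply(gains, function(g) {
    mean(vapply(1:4, function(seed) {
      cfg <- simulation_config(n_cycles = 60,
                               field_position = "isocenter",
                               mhd_gain_at_7T = g, seed = seed)
      sch <- draw_cycle_schedule(cfg)
      log <- physio_log(channels = list(synthesize_ecg(sch, cfg)))
      tr <- simulate_cpmu_triggers(log, "ECG", cfg)
      n <- length(sch$r_times)
      off <- vapply(seq_len(n - 1), function(i) {
        inside <- tr$times[tr$times >= sch$r_times[i] - 0.025 &
                           tr$times < sch$r_times[i + 1] - 0.025]
        if (length(inside)) 1000 * (inside[1] - sch$r_times[i])
        else NA_real_
      }, numeric(1))
      failure_rate(off)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rates) >= -1e-9))
  expect_equal(mean_rates[1], 0)
  expect_gt(mean_rates[length(gains)], 0.05)
})

test_that("SD-ratio flags reproduce the published counts", {
  t1 <- cg_table1()
  expect_equal(flag_sd_ratio(t1$ecg_interval_sd, t1$act_interval_sd, 1.5),
               4)
  expect_equal(flag_sd_ratio(t1$ecg_interval_sd, t1$act_interval_sd, 0),
               9)
  expect_equal(flag_sd_ratio(t1$ecg_offset_sd, t1$act_offset_sd, 4), 5)
  expect_equal(flag_sd_ratio(t1$ecg_offset_sd, t1$act_offset_sd, 4,
                             strict = TRUE), 4)
  expect_error(flag_sd_ratio(1:3, 1:2, 1), class = "cg_argument_error")
})

test_that("gating to breath-holds never increases the analyzed cycles", {
  log <- simulate_session(simulation_config(n_cycles = 60, seed = 17))
  holds <- identify_breath_holds(log$channels$RESP)
  seg_all <- segment_rr(log$channels$ECG)
  seg_gated <- segment_rr(log$channels$ECG, holds)
  expect_lte(nrow(seg_gated$cycles), nrow(seg_all$cycles))
})

test_that("end-to-end pipeline recovers generator parameters", {
  cfg <- simulation_config(n_cycles = 200, seed = 4)
  log <- simulate_session(cfg)
  st <- analyze_triggers(log)
  act <- st[st$modality == "ACT", ]
  ecg <- st[st$modality == "ECG", ]
  n <- act$n_triggers
  expect_equal(act$interval_mean, 900, tolerance = 3 * 50 / sqrt(n) / 900)
  expect_equal(act$offset_mean, 29.65,
               tolerance = (3 * 4.43 / sqrt(n) + 1) / 29.65)
  expect_lt(abs(ecg$offset_mean), 5)
  expect_equal(ecg$failure_rate, 0)
  # jitter == 0 iff offset SD == 0 (degenerate check)
  expect_true(xor(act$jitter == 0, act$offset_sd > 0))
})
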