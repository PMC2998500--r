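# Trigger-fidelity post-processing pipeline: breath-hold gating,
# cross-correlation R-R segmentation/realignment, tickmark reassignment
# and the per-modality interval/offset statistics.

#' Identify breath-hold periods from the respiratory trace
#'
#' Maximal intervals where the rolling standard deviation (2 s window)
#' falls below `quiet_fraction` times the whole-trace SD, dilated by half
#' the rolling window to recover the true hold boundaries, each at least
#' `min_duration_s` long.
#'
#' @param resp The `RESP` [channel_trace()].
#' @param min_duration_s Minimum hold duration, seconds.
#' @param quiet_fraction Rolling-SD threshold as a fraction of the
#'   whole-trace SD.
#' @param window_s Rolling window length, seconds.
#' @return data.frame with columns `start`, `end` (seconds).
#' @export
identify_breath_holds <- function(resp, min_duration_s = 5,
                                  quiet_fraction = 0.1, window_s = 2) {
  x <- resp$samples
  rate <- resp$rate
  w <- round(window_s * rate)
  n <- length(x)
  if (n < w) cg_argument_error("trace shorter than the rolling window")
  half <- w %/% 2L
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  m <- hi - lo + 1L
  mu <- (cs[hi + 1L] - cs[lo]) / m
  v <- pmax((cs2[hi + 1L] - cs2[lo]) / m - mu^2, 0)
  rsd <- sqrt(v)
  quiet <- rsd < quiet_fraction * stats::sd(x)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs))
    return(data.frame(start = numeric(0), end = numeric(0)))
  # dilate by the half-window blur, merge, then apply the duration floor
  t_start <- resp$t0 + pmax(runs[, 1] - 1L - half, 0) / rate
  t_end <- resp$t0 + pmin(runs[, 2] - 1L + half, n - 1L) / rate
  merged <- list()
  cs_ <- t_start[1]; ce_ <- t_end[1]
  for (i in seq_len(nrow(runs))[-1]) {
    if (t_start[i] <= ce_) ce_ <- max(ce_, t_end[i])
    else { merged[[length(merged) + 1L]] <- c(cs_, ce_)
           cs_ <- t_start[i]; ce_ <- t_end[i] }
  }
  merged[[length(merged) + 1L]] <- c(cs_, ce_)
  mm <- do.call(rbind, merged)
  keep <- (mm[, 2] - mm[, 1]) >= min_duration_s
  data.frame(start = mm[keep, 1], end = mm[keep, 2])
}

refine_peak_times <- function(x, rate, t0, cross_times,
                              search_s = 0.06) {
  vapply(cross_times, function(tc) {
    i0 <- round((tc - t0) * rate) + 1L
    lo <- max(1L, i0)
    hi <- min(length(x), i0 + round(search_s * rate))
    ip <- lo + which.max(x[lo:hi]) - 1L
    dp <- if (ip > 1L && ip < length(x))
      parabolic_peak(x[ip - 1L], x[ip], x[ip + 1L]) else 0
    t0 + (ip - 1L + dp) / rate
  }, numeric(1))
}

in_holds <- function(times, holds) {
  if (is.null(holds)) return(rep(TRUE, length(times)))
  h <- as_window_matrix(holds)
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(h)))
    out <- out | (times >= h[i, 1] & times <= h[i, 2])
  out
}

#' Segment an ECG trace into realigned R-R intervals
#'
#' R waves are located with the monitoring-unit-style threshold detector
#' and refined to their peaks. The first complete R-R interval inside the
#' first breath-hold is the reference; every other candidate interval is
#' assigned the integer-sample shift (within `max_shift_ms`) maximizing
#' the normalized cross-correlation with the reference. Ties prefer the
#' smallest absolute shift.
#'
#' @param ecg The `ECG` [channel_trace()].
#' @param holds Optional breath-hold intervals (data.frame/matrix with
#'   start, end columns); `NULL` analyses the whole trace.
#' @param max_shift_ms Half-width of the admissible shift range, ms.
#' @param corr_window_s Length of the leading, QRS-anchored portion of
#'   each interval used for the correlation (capped at the reference
#'   length). Realignment corrects trigger-detection bias at the cycle
#'   onset; correlating the full interval would let natural R-R
#'   variability (the position of the following R wave) drag the shifts.
#' @return An object of class `cycle_segmentation`: `reference`
#'   (start, end), `reference_index`, `cycles` (matrix of start/end
#'   times), `r_times` (refined per-cycle R peak times), `shifts` (ms)
#'   and `rate`.
#' @export
segment_rr <- function(ecg, holds = NULL, max_shift_ms = 150,
                       corr_window_s = 0.25) {
  x <- ecg$samples
  rate <- ecg$rate
  if (length(x) < 2 || stats::sd(x) == 0 || max(x) <= 0)
    cg_stop("ECG trace is constant; correlation undefined",
            "cg_degenerate_correlation")
  cross <- cpmu_detect(x, rate, ecg$t0)
  r_times <- refine_peak_times(x, rate, ecg$t0, cross)
  ok <- in_holds(r_times, holds)
  # complete cycles: consecutive detected R pairs, both inside a hold
  idx <- which(ok[-length(ok)] & ok[-1])
  if (length(r_times) < 2 || length(idx) < 2)
    cg_insufficient_data("fewer than two cardiac cycles available")
  starts <- r_times[idx]
  ends <- r_times[idx + 1L]
  ref_i <- 1L
  Ls_full <- round((ends[ref_i] - starts[ref_i]) * rate)
  Ls <- min(Ls_full, round(corr_window_s * rate))
  # anchor the reference window at its refined R peak (sub-sample), so
  # the reference's own sampling-grid phase does not bias every shift
  ref_seg <- stats::approx(trace_times(ecg), x,
                           xout = starts[ref_i] + (seq_len(Ls) - 1) / rate,
                           rule = 2)$y
  if (stats::sd(ref_seg) == 0)
    cg_stop("reference interval is constant", "cg_degenerate_correlation")
  smax <- round(max_shift_ms / 1000 * rate)
  shifts_grid <- seq(-smax, smax)
  n <- length(x)
  shifts <- numeric(length(idx))
  for (k in seq_along(idx)) {
    if (k == ref_i) { shifts[k] <- 0; next }
    base <- round((starts[k] - ecg$t0) * rate) + 1L
    valid <- shifts_grid[base + shifts_grid >= 1L &
                         base + shifts_grid + Ls - 1L <= n]
    if (!length(valid)) { shifts[k] <- 0; next }
    M <- vapply(valid, function(s) x[(base + s):(base + s + Ls - 1L)],
                numeric(Ls))
    cc <- suppressWarnings(as.numeric(stats::cor(ref_seg, M)))
    cc[!is.finite(cc)] <- -Inf
    best <- max(cc)
    cand <- valid[cc >= best - 1e-12]
    cand <- cand[order(abs(cand), cand)]
    shifts[k] <- cand[1]
  }
  structure(list(
    reference = c(starts[ref_i], ends[ref_i]),
    reference_index = ref_i,
    cycles = cbind(start = starts, end = ends),
    r_times = starts,
    shifts = shifts / rate * 1000,
    rate = rate),
    class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cycle_segmentation: %d cycles, reference [%0.3f, %0.3f] s, shift SD %.1f ms>\n",
    nrow(x$cycles), x$reference[1], x$reference[2], stats::sd(x$shifts)))
  invisible(x)
}

#' Cut realigned per-cycle excerpts from a simultaneous trace
#'
#' Each cycle's time window, displaced by its realignment shift, is cut
#' from `other` and linearly resampled onto a common 400 samples/s
#' timebase of the reference interval's length.
#'
#' @param seg A [segment_rr()] result.
#' @param other Any [channel_trace()] overlapping the segmentation span.
#' @param out_rate Common overlay rate, samples/s.
#' @return Matrix with one row per cycle; attribute `"rel_times"` holds
#'   the within-cycle time axis in seconds.
#' @export
apply_segmentation_mask <- function(seg, other, out_rate = 400) {
  t_other <- trace_times(other)
  if (!length(t_other) ||
      max(t_other) < min(seg$cycles[, 1]) ||
      min(t_other) > max(seg$cycles[, 2]))
    cg_argument_error("trace does not overlap the segmentation span")
  L <- seg$reference[2] - seg$reference[1]
  rel <- seq(0, L, by = 1 / out_rate)
  out <- matrix(NA_real_, nrow = nrow(seg$cycles), ncol = length(rel))
  for (i in seq_len(nrow(seg$cycles))) {
    # reference row is R-anchored (sub-sample); candidate rows sit on the
    # correlation grid plus their integer-sample shift, mirroring the
    # alignment actually optimized
    t_start <- if (i == seg$reference_index) seg$cycles[i, 1] else
      round(seg$cycles[i, 1] * seg$rate) / seg$rate + seg$shifts[i] / 1000
    out[i, ] <- stats::approx(t_other, other$samples, xout = t_start + rel,
                              rule = 2)$y
  }
  attr(out, "rel_times") <- rel
  out
}

#' Reassign trigger tickmarks to realigned cycles
#'
#' Each tickmark is assigned to the cycle containing it; the per-cycle
#' offset is `tickmark - cycle R time + cycle shift` in ms. At most one
#' offset per cycle is retained (earliest tickmark); extra tickmarks are
#' counted as doubles; cycles without tickmarks are `NA` (missed).
#'
#' @param seg A [segment_rr()] result.
#' @param triggers A [trigger_train()].
#' @param r_times Per-cycle R times, seconds (default: the segmentation's
#'   refined R peaks).
#' @param guard_ms Lead guard subtracted from both cycle boundaries, ms: a
#'   tickmark marking the R wave itself stays in its own cycle even when
#'   sampling-grid quantization places it just before the refined R peak.
#' @return Numeric vector of per-cycle offsets in ms with `NA` for missed
#'   cycles; attribute `"doubles"` counts surplus tickmarks.
#' @export
reassign_tickmarks <- function(seg, triggers, r_times = NULL,
                               guard_ms = 25) {
  if (is.null(r_times)) r_times <- seg$r_times
  times <- if (inherits(triggers, "trigger_train")) triggers$times
           else as.numeric(triggers)
  g <- guard_ms / 1000
  nc <- nrow(seg$cycles)
  offsets <- rep(NA_real_, nc)
  doubles <- 0L
  for (i in seq_len(nc)) {
    inside <- times[times >= seg$cycles[i, 1] - g &
                    times < seg$cycles[i, 2] - g]
    if (!length(inside)) next
    offsets[i] <- (inside[1] - r_times[i]) * 1000 + seg$shifts[i]
    doubles <- doubles + length(inside) - 1L
  }
  attr(offsets, "doubles") <- doubles
  offsets
}

#' Peak-to-peak trigger jitter
#'
#' Defined as the range (max minus min) of the per-cycle trigger offsets,
#' the spread quoted "across the cardiac cycle".
#'
#' @param offsets Per-cycle offsets in ms (`NA` = missed cycle, ignored).
#' @return Jitter in ms.
#' @export
trigger_jitter <- function(offsets) {
  o <- offsets[is.finite(offsets)]
  if (length(o) < 2)
    cg_insufficient_data("need at least two offsets for jitter")
  max(o) - min(o)
}

#' Mean and SD of the cardiac cycle length from a trigger train
#'
#' @param triggers A [trigger_train()] or numeric times in seconds
#'   (>= 3 triggers).
#' @return List with `interval_mean` and `interval_sd` in ms (sample SD,
#'   n-1 denominator).
#' @export
cycle_statistics <- function(triggers) {
  times <- if (inherits(triggers, "trigger_train")) triggers$times
           else as.numeric(triggers)
  if (length(times) < 3)
    cg_insufficient_data("need >= 3 triggers (>= 2 intervals)")
  d <- diff(times) * 1000
  list(interval_mean = mean(d), interval_sd = stats::sd(d))
}

#' Mean and SD of per-cycle trigger offsets
#'
#' @param offsets Per-cycle offsets in ms (`NA` ignored; >= 2 required).
#' @return List with `offset_mean` and `offset_sd` in ms.
#' @export
trigger_offset_stats <- function(offsets) {
  o <- offsets[is.finite(offsets)]
  if (length(o) < 2)
    cg_insufficient_data("need at least two offsets")
  list(offset_mean = mean(o), offset_sd = stats::sd(o))
}

#' Trigger mis-registration rate
#'
#' Fraction of cycles whose trigger offset lies more than `tolerance_ms`
#' from the modal offset (mode of a 20 ms-binned histogram); missed
#' cycles (`NA` offsets) count as failures.
#'
#' @param offsets Per-cycle offsets in ms, `NA` for missed cycles.
#' @param tolerance_ms Allowed distance from the modal offset, ms.
#' @return Failure rate in \[0, 1\].
#' @export
failure_rate <- function(offsets, tolerance_ms = 100) {
  if (!length(offsets))
    cg_insufficient_data("need at least one cycle")
  o <- offsets[is.finite(offsets)]
  n_missed <- sum(!is.finite(offsets))
  if (!length(o)) return(1)
  bins <- floor(o / 20)
  tab <- table(bins)
  modal_bin <- as.numeric(names(tab)[which.max(tab)])
  modal <- modal_bin * 20 + 10
  (sum(abs(o - modal) > tolerance_ms) + n_missed) / length(offsets)
}

#' Count subjects whose ECG variability exceeds a multiple of ACT's
#'
#' @param sd_ecg,sd_act Per-subject standard deviations (same length).
#' @param ratio Multiplicative factor.
#' @param strict If `FALSE` (default) the comparison is
#'   `sd_ecg >= ratio * sd_act`; if `TRUE`, strictly greater.
#' @return Integer count of qualifying subjects.
#' @export
flag_sd_ratio <- function(sd_ecg, sd_act, ratio, strict = FALSE) {
  if (length(sd_ecg) != length(sd_act))
    cg_argument_error("sd vectors must have equal length")
  if (!length(sd_ecg)) cg_argument_error("need at least one subject")
  if (ratio < 0) cg_argument_error("ratio must be >= 0")
  if (strict) sum(sd_ecg > ratio * sd_act)
  else sum(sd_ecg >= ratio * sd_act)
}

#' Full trigger-fidelity analysis of a session
#'
#' Runs the post-processing pipeline: breath-hold identification,
#' cross-correlation R-R segmentation of the ECG, tickmark reassignment
#' for every logged modality, and the interval/offset statistics.
#'
#' @param log A [physio_log()] with ECG and RESP channels and trigger
#'   trains.
#' @param r_times Optional ground-truth R times overriding the
#'   segmentation's R estimates for offset computation.
#' @return data.frame with one row per modality: interval mean/SD, offset
#'   mean/SD, jitter, failure rate and cycle counts.
#' @export
analyze_triggers <- function(log, r_times = NULL) {
  resp <- log$channels$RESP
  holds <- if (!is.null(resp)) identify_breath_holds(resp) else NULL
  if (!is.null(holds) && !nrow(holds)) holds <- NULL
  ecg <- log$channels$ECG
  if (is.null(ecg)) cg_argument_error("log has no ECG channel")
  seg <- segment_rr(ecg, holds)
  rt <- if (is.null(r_times)) seg$r_times else {
    vapply(seg$r_times, function(t)
      r_times[which.min(abs(r_times - t))], numeric(1))
  }
  # successive trigger intervals, never spanning a gap between holds
  gated_intervals <- function(times) {
    if (is.null(holds)) return(diff(times) * 1000)
    h <- as_window_matrix(holds)
    unlist(lapply(seq_len(nrow(h)), function(i)
      diff(times[times >= h[i, 1] & times <= h[i, 2]]) * 1000))
  }
  rows <- lapply(names(log$triggers), function(mod) {
    tr <- log$triggers[[mod]]
    gated <- tr$times[in_holds(tr$times, holds)]
    iv <- gated_intervals(gated)
    cyc <- if (length(iv) >= 2)
      list(interval_mean = mean(iv), interval_sd = stats::sd(iv))
    else list(interval_mean = NA_real_, interval_sd = NA_real_)
    off <- reassign_tickmarks(seg, tr, rt)
    os <- if (sum(is.finite(off)) >= 2) trigger_offset_stats(off)
          else list(offset_mean = NA_real_, offset_sd = NA_real_)
    jit <- if (sum(is.finite(off)) >= 2) trigger_jitter(off) else NA_real_
    data.frame(modality = mod,
               n_cycles = nrow(seg$cycles),
               n_triggers = length(gated),
               interval_mean = cyc$interval_mean,
               interval_sd = cyc$interval_sd,
               offset_mean = os$offset_mean,
               offset_sd = os$offset_sd,
               jitter = jit,
               failure_rate = failure_rate(off))
  })
  do.call(rbind, rows)
}
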