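# Shared fixture builders; everything is generated in code.

make_small_log <- function() {
  physio_log(
    channels = list(
      channel_trace("ECG", 400, sin(2 * pi * 1.2 * (0:3999) / 400)),
      channel_trace("ACT", 200, cos(2 * pi * 0.8 * (0:1999) / 200)),
      channel_trace("POX", 50, rep(c(0, 1, 0.5, 0.2), 50))),
    triggers = list(
      trigger_train("ECG", c(0.102, 0.961, 1.803)),
      trigger_train("ACT", c(0.131, 0.990))),
    meta = list(field_position = "home", tr_s = 0.004, te_s = 0.002,
                subject = "s1"))
}

# Exhaustive cross-correlation shift search, written independently of
# segment_rr (explicit loops, textbook Pearson formula, hand-rolled
# linear interpolation for the R-anchored reference window).
brute_force_shifts <- function(x, rate, starts, ref_start, L, smax,
                               ref_index = 1L) {
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    den <- sqrt(sum(am^2) * sum(bm^2))
    if (den == 0) return(-Inf)
    sum(am * bm) / den
  }
  lerp <- function(tq) {
    i <- floor(tq * rate) + 1
    w <- tq * rate - (i - 1)
    x[i] * (1 - w) + x[pmin(i + 1, length(x))] * w
  }
  ref <- vapply(ref_start + (seq_len(L) - 1) / rate, lerp, numeric(1))
  out <- vapply(starts, function(st) {
    base <- round(st * rate) + 1L
    best_c <- -Inf; best_s <- 0L
    for (s in seq(-smax, smax)) {
      lo <- base + s
      if (lo < 1L || lo + L - 1L > length(x)) next
      cc <- pearson(ref, x[lo:(lo + L - 1L)])
      better <- cc > best_c + 1e-12 ||
        (cc >= best_c - 1e-12 &&
           (abs(s) < abs(best_s) || (abs(s) == abs(best_s) && s < best_s)))
      if (better) { best_c <- max(cc, best_c); best_s <- s }
    }
    best_s
  }, integer(1))
  out[ref_index] <- 0L   # the reference is one of the cycles, shift 0
  out
}

# Full 2^n enumeration of the signed-rank statistic (independent oracle
# for the dynamic-programming exact Wilcoxon).
enumerate_wilcoxon_p <- function(d) {
  d <- d[abs(d) > 1e-12]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

goertzel_mag <- function(x, f, fs) {
  k <- seq_along(x) - 1
  abs(sum(x * exp(-2i * pi * f * k / fs)))
}
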