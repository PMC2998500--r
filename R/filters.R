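# Digital IIR design and filtering primitives.
#
# The heart-sound low-pass is an inverse Chebyshev (Chebyshev type II)
# design: maximally monotone passband, equiripple stopband whose ripple
# maxima sit exactly at the specified attenuation. The analog prototype is
# realized at the stopband edge, frequency-scaled with bilinear pre-warping
# and mapped to the z-domain. Zero-phase application (forward-backward)
# follows the scipy filtfilt scheme with companion-matrix initial
# conditions so that trigger timing is not skewed by group delay.

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef) * ri
  coef
}

# Analog Chebyshev type II prototype with stopband edge at 1 rad/s.
cheb2ap <- function(n, rs) {
  de <- 1 / sqrt(10^(0.1 * rs) - 1)
  mu <- asinh(1 / de) / n
  m <- if (n %% 2) c(seq(-n + 1, -1, 2), seq(2, n - 1, 2)) else
    seq(-n + 1, n - 1, 2)
  z <- -Conj(1i / sin(m * pi / (2 * n)))
  mp <- seq(-n + 1, n - 1, 2)
  p <- -exp(1i * pi * mp / (2 * n))
  p <- complex(real = sinh(mu) * Re(p), imaginary = cosh(mu) * Im(p))
  p <- 1 / p
  k <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = k)
}

# Low-pass to low-pass scaling followed by bilinear transform.
zpk_bilinear_lowpass <- function(zpk, wo, fs) {
  z <- zpk$z * wo
  p <- zpk$p * wo
  k <- zpk$k * wo^(length(p) - length(z))
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Design the heart-sound low-pass filter
#'
#' Third-order inverse Chebyshev low-pass. `cutoff` is interpreted as the
#' stopband-edge frequency: the first frequency at which the attenuation
#' reaches `stopband_db`, beyond which the equiripple stopband keeps the
#' magnitude at or below `-stopband_db`.
#'
#' @param rate Sampling rate of the signal to be filtered, samples/s.
#' @param cutoff Stopband-edge frequency in Hz (must be < `rate/2`).
#' @param order Filter order (default 3).
#' @param stopband_db Minimum stopband attenuation in dB (default 30).
#' @return An object of class `filter_spec` with realized coefficients
#'   `b`, `a` for the given rate.
#' @export
design_heart_sound_filter <- function(rate, cutoff = 105, order = 3,
                                      stopband_db = 30) {
  if (order < 1) cg_argument_error("order must be >= 1")
  if (cutoff <= 0 || stopband_db <= 0)
    cg_argument_error("cutoff and stopband_db must be > 0")
  if (cutoff >= rate / 2)
    cg_argument_error("cutoff must be below the Nyquist frequency")
  warped <- 2 * rate * tan(pi * cutoff / rate)
  ba <- zpk_bilinear_lowpass(cheb2ap(order, stopband_db), warped, rate)
  structure(list(family = "inverse Chebyshev low-pass", order = order,
                 cutoff = cutoff, stopband_db = stopband_db, rate = rate,
                 b = ba$b, a = ba$a),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec: order-%d %s, stopband edge %g Hz @ -%g dB, fs=%g>\n",
              x$order, x$family, x$cutoff, x$stopband_db, x$rate))
  invisible(x)
}

#' Frequency response of a realized filter
#'
#' @param spec A `filter_spec`.
#' @param freqs Frequencies in Hz at which to evaluate the response.
#' @return Complex response H(f).
#' @export
filter_response <- function(spec, freqs) {
  w <- 2 * pi * freqs / spec$rate
  ez <- exp(-1i * outer(w, seq_along(spec$b) - 1))
  num <- drop(ez %*% spec$b)
  ez <- exp(-1i * outer(w, seq_along(spec$a) - 1))
  den <- drop(ez %*% spec$a)
  num / den
}

# Direct-form II transposed IIR filter with optional initial conditions.
lfilter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- length(x)
  y <- numeric(n)
  z <- if (is.null(zi)) numeric(nfilt - 1) else zi
  if (nfilt == 1L) return(list(y = b[1] * x, zf = numeric(0)))
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nfilt > 2L) {
      z[seq_len(nfilt - 2L)] <-
        b[2:(nfilt - 1L)] * xi + z[2:(nfilt - 1L)] - a[2:(nfilt - 1L)] * yi
    }
    z[nfilt - 1L] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  list(y = y, zf = z)
}

# Steady-state initial conditions for a unit step (scipy lfilter_zi).
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  if (nfilt == 1L) return(numeric(0))
  comp <- rbind(-a[-1], cbind(diag(1, nfilt - 2L), 0))
  if (nfilt == 2L) comp <- matrix(-a[2], 1, 1)
  IminusA <- diag(nfilt - 1L) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

#' Apply a filter to a numeric signal
#'
#' @param spec A `filter_spec`.
#' @param x Numeric signal sampled at `spec$rate`.
#' @param zero_phase If `TRUE` (default) use forward-backward filtering
#'   (no group delay, squared magnitude response); otherwise single-pass
#'   causal filtering.
#' @return Filtered signal, same length as `x`.
#' @export
apply_filter <- function(spec, x, zero_phase = TRUE) {
  b <- spec$b; a <- spec$a
  if (!zero_phase) return(lfilter(b, a, x)$y)
  nfilt <- max(length(a), length(b))
  pad <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= pad)
    cg_argument_error("signal too short for zero-phase filtering")
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi = zi * ext[1])$y
  y <- rev(lfilter(b, a, rev(y), zi = zi * y[length(y)])$y)
  y[(pad + 1L):(pad + n)]
}

# O(n) sliding maximum over the trailing `w` samples (current included),
# via the block prefix/suffix-max trick; fully vectorized.
running_max <- function(x, w) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  nb <- ceiling(n / w)
  xp <- c(x, rep(-Inf, nb * w - n))
  m <- matrix(xp, nrow = w)
  pref <- apply(m, 2, cummax)
  suff <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  i <- seq_len(n)
  j <- i - w + 1L
  out <- pref[((i - 1L) %% w) + 1L + (((i - 1L) %/% w)) * w]
  jj <- pmax(j, 1L)
  out2 <- suff[((jj - 1L) %% w) + 1L + (((jj - 1L) %/% w)) * w]
  pmax(out, out2)
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (n == 0L || k == 1L) return(x)
  half <- k %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Magnitude of the analytic signal (FFT Hilbert transform). The input is
# zero-padded to a 2-3-5-smooth length so the FFT stays O(n log n).
analytic_envelope <- function(x) {
  n0 <- length(x)
  if (n0 == 0L) return(numeric(0))
  n <- stats::nextn(n0, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(n - n0)))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}
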