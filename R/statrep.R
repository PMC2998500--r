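# Agreement and comparison statistics: Bland-Altman, exact Wilcoxon
# matched-pairs with midranks, paired t, and score-table summaries.

#' Bland-Altman agreement analysis
#'
#' @param a,b Paired measurements (equal length >= 2).
#' @param loa_factor Limits-of-agreement multiplier (1.96 by convention).
#' @return An object of class `bland_altman`: `bias` (mean of `a - b`),
#'   `sd_diff`, `loa_low`, `loa_high`, and per-pair `(mean, diff)` pairs.
#' @export
bland_altman <- function(a, b, loa_factor = 1.96) {
  if (length(a) != length(b))
    cg_argument_error("paired vectors must have equal length")
  if (length(a) < 2) cg_argument_error("need at least two pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - loa_factor * s,
                 loa_high = bias + loa_factor * s,
                 pairs = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman: bias %.3f, limits [%.3f, %.3f], n=%d>\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$pairs)))
  invisible(x)
}

# Exact null distribution of W+ for (possibly tied) ranks, by dynamic
# programming over the 2^n sign assignments. Ranks are doubled so that
# midranks (k + 0.5) become integers.
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)  # counts[w + 1] = #assignments with W+ = w/1
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original treatment); tied
#' absolute differences receive midranks. For `n <= exact_max` effective
#' pairs the two-sided p-value is exact, computed over all `2^n` sign
#' assignments of the (tied) rank multiset; above that a normal
#' approximation with tie correction is used.
#'
#' @param x,y Paired scores (equal length >= 2).
#' @param exact_max Largest n for which the exact distribution is used.
#' @return An object of class `paired_test`: `test`, `statistic` (W+),
#'   `w_minus`, `p_two_sided`, `n_effective`, `exact`.
#' @export
wilcoxon_matched_pairs <- function(x, y, exact_max = 15) {
  if (length(x) != length(y))
    cg_argument_error("paired vectors must have equal length")
  if (length(x) < 2) cg_argument_error("need at least two pairs")
  d <- x - y
  d <- d[abs(d) > 1e-12]
  n <- length(d)
  if (n == 0)
    return(structure(list(test = "wilcoxon_matched_pairs",
                          statistic = 0, w_minus = 0, p_two_sided = 1,
                          n_effective = 0, exact = TRUE),
                     class = "paired_test"))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_distribution(ranks2)
    w2 <- as.integer(round(2 * w_plus))
    cdf_lo <- sum(counts[seq_len(w2 + 1)]) / 2^n
    cdf_hi <- sum(counts[(w2 + 1):length(counts)]) / 2^n
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(test = "wilcoxon_matched_pairs", statistic = w_plus,
                 w_minus = w_minus, p_two_sided = p, n_effective = n,
                 exact = exact),
            class = "paired_test")
}

#' Paired t-test
#'
#' @param x,y Paired measurements (equal length >= 2) whose differences
#'   have nonzero variance.
#' @return An object of class `paired_test` with the t statistic and the
#'   two-sided p-value on `n - 1` degrees of freedom.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y))
    cg_argument_error("paired vectors must have equal length")
  n <- length(x)
  if (n < 2) cg_argument_error("need at least two pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0)
    cg_stop("differences have zero variance", "cg_degenerate_variance")
  t_stat <- mean(d) / (s / sqrt(n))
  structure(list(test = "paired_t", statistic = t_stat,
                 p_two_sided = 2 * stats::pt(-abs(t_stat), n - 1),
                 n_effective = n, df = n - 1),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("<%s: statistic %.3f, p = %.2f (n=%d)>\n",
              x$test, x$statistic, x$p_two_sided, x$n_effective))
  invisible(x)
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Summarize consensus image-quality scores
#'
#' Per (modality, phase) arithmetic mean and sample SD of the consensus
#' scores, rounded half-up to one decimal (the print precision of the
#' source tables).
#'
#' @param table data.frame with a `subject` column and score columns named
#'   `<modality>_<phase>` (e.g. `act_ed`, `ecg_es`), scores in \[0, 3\].
#' @return data.frame with columns `modality`, `phase`, `mean`, `sd`.
#' @export
summarize_scores <- function(table) {
  cols <- setdiff(names(table), "subject")
  if (!nrow(table) || !length(cols))
    cg_argument_error("empty score table")
  sc <- as.matrix(table[, cols, drop = FALSE])
  if (any(sc < 0 | sc > 3))
    cg_validation_error("scores must lie in [0, 3]")
  parts <- strsplit(cols, "_", fixed = TRUE)
  data.frame(
    modality = toupper(vapply(parts, `[`, character(1), 1)),
    phase = vapply(parts, `[`, character(1), 2),
    mean = round_half_up(colMeans(sc), 1),
    sd = round_half_up(apply(sc, 2, stats::sd), 1),
    row.names = NULL)
}

#' Duration of one cine cardiac phase
#'
#' `(60000 / heart_rate_bpm) / n_phases`, rounded to the nearest ms: the
#' temporal resolution of a retrospectively binned cine acquisition.
#'
#' @param n_phases Number of reconstructed cardiac phases (>= 1).
#' @param heart_rate_bpm Heart rate in beats per minute (> 0).
#' @return Phase duration in integer ms.
#' @export
cine_phase_duration <- function(n_phases, heart_rate_bpm) {
  if (n_phases < 1 || heart_rate_bpm <= 0)
    cg_argument_error("need n_phases >= 1 and heart_rate_bpm > 0")
  round((60000 / heart_rate_bpm) / n_phases)
}
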