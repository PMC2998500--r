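# Containers and text I/O for multi-rate physiological recordings.
#
# A session is stored as a plain-text log: "#"-prefixed key=value headers
# introduce meta fields, channel blocks (one sample per line) and trigger
# blocks (one time in seconds per line). The decimal separator is always
# ".", independent of locale.

CHANNEL_LABELS <- c("ECG", "POX", "ACT", "RESP", "MIC")
TRIGGER_MODALITIES <- c("ECG", "POX", "ACT")
FIELD_POSITIONS <- c("home", "front", "isocenter")

# Static field strength (T) at the sensor position for each table position.
FIELD_STRENGTH_T <- c(home = 0.3, front = 1.0, isocenter = 7.0)

default_units <- function(label) {
  switch(label, ECG = "mV", MIC = "Pa", "a.u.")
}

#' Single-channel physiological trace
#'
#' @param label One of `"ECG"`, `"POX"`, `"ACT"`, `"RESP"`, `"MIC"`.
#' @param rate Sampling rate in samples/s (> 0).
#' @param samples Numeric vector of sample amplitudes (ECG in mV, MIC in Pa,
#'   others in arbitrary units).
#' @param t0 Time of the first sample on the shared session clock, seconds.
#' @param units Unit string; defaults to the conventional unit for the label.
#' @return An object of class `channel_trace`.
#' @export
channel_trace <- function(label, rate, samples, t0 = 0, units = NULL) {
  label <- as.character(label)
  if (!label %in% CHANNEL_LABELS)
    cg_format_error(sprintf("unknown channel label '%s'", label))
  rate <- as.numeric(rate)
  if (!is.finite(rate) || rate <= 0)
    cg_validation_error("channel rate must be > 0")
  t0 <- as.numeric(t0)
  if (!is.finite(t0) || t0 < 0)
    cg_validation_error("channel t0 must be >= 0")
  samples <- as.numeric(samples)
  structure(
    list(label = label, rate = rate, t0 = t0, samples = samples,
         units = if (is.null(units)) default_units(label) else units),
    class = "channel_trace")
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace %s: %d samples @ %g Hz, t0=%g s [%s]>\n",
              x$label, length(x$samples), x$rate, x$t0, x$units))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace A [channel_trace()].
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

#' Sample times of a trace on the session clock
#' @param trace A [channel_trace()].
#' @export
trace_times <- function(trace) {
  n <- length(trace$samples)
  if (n == 0L) return(numeric(0))
  trace$t0 + (seq_len(n) - 1) / trace$rate
}

#' Per-modality train of trigger tickmarks
#'
#' @param modality One of `"ECG"`, `"POX"`, `"ACT"`.
#' @param times Strictly increasing trigger instants in seconds (>= 0).
#' @return An object of class `trigger_train`.
#' @export
trigger_train <- function(modality, times = numeric(0)) {
  modality <- as.character(modality)
  if (!modality %in% TRIGGER_MODALITIES)
    cg_argument_error(sprintf("unknown trigger modality '%s'", modality))
  times <- as.numeric(times)
  if (length(times) && any(times < 0))
    cg_validation_error("trigger times must be >= 0")
  if (length(times) > 1 && any(diff(times) <= 0))
    cg_validation_error("trigger times must be strictly increasing")
  structure(list(modality = modality, times = times), class = "trigger_train")
}

#' @export
print.trigger_train <- function(x, ...) {
  cat(sprintf("<trigger_train %s: %d tickmarks>\n", x$modality,
              length(x$times)))
  invisible(x)
}

#' Multi-channel physiological recording session
#'
#' @param channels List of [channel_trace()] objects, at most one per label.
#' @param triggers List of [trigger_train()] objects, at most one per modality.
#' @param meta Named list of session metadata: `field_position` (one of
#'   `"home"`, `"front"`, `"isocenter"`), `tr_s`, `te_s`, `subject`.
#' @return An object of class `physio_log`.
#' @export
physio_log <- function(channels = list(), triggers = list(), meta = list()) {
  labs <- vapply(channels, function(ch) ch$label, character(1))
  if (anyDuplicated(labs))
    cg_validation_error("duplicate channel label in log")
  names(channels) <- labs
  mods <- vapply(triggers, function(tr) tr$modality, character(1))
  if (anyDuplicated(mods))
    cg_validation_error("duplicate trigger modality in log")
  names(triggers) <- mods
  if (!is.null(meta$field_position) &&
      !meta$field_position %in% FIELD_POSITIONS)
    cg_validation_error("meta field_position must be home/front/isocenter")
  structure(list(channels = channels, triggers = triggers, meta = meta),
            class = "physio_log")
}

#' @export
print.physio_log <- function(x, ...) {
  cat(sprintf("<physio_log: %d channels (%s), %d trigger trains (%s)>\n",
              length(x$channels), paste(names(x$channels), collapse = ","),
              length(x$triggers), paste(names(x$triggers), collapse = ",")))
  invisible(x)
}

fmt_num <- function(x) {
  # locale-proof, round-trip safe at 9 significant digits
  sprintf("%.9g", x)
}

#' Write a physiological log to a text file
#'
#' Deterministic layout: meta block first, then channel blocks in canonical
#' label order (ECG, POX, ACT, RESP, MIC), then trigger blocks in modality
#' order. Trigger times are written with millisecond precision, samples with
#' nine significant digits.
#'
#' @param log A [physio_log()].
#' @param path Output file path.
#' @export
write_physio_log <- function(log, path) {
  if (!inherits(log, "physio_log")) cg_argument_error("log must be physio_log")
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    cg_io_error(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  out <- character(0)
  for (key in c("field_position", "tr_s", "te_s", "subject")) {
    v <- log$meta[[key]]
    if (!is.null(v)) {
      vs <- if (is.numeric(v)) fmt_num(v) else as.character(v)
      out <- c(out, sprintf("# meta %s=%s", key, vs))
    }
  }
  for (lab in CHANNEL_LABELS) {
    ch <- log$channels[[lab]]
    if (is.null(ch)) next
    out <- c(out, sprintf("# channel=%s rate_hz=%s t0_s=%s units=%s",
                          ch$label, fmt_num(ch$rate), fmt_num(ch$t0),
                          ch$units),
             fmt_num(ch$samples))
  }
  for (mod in TRIGGER_MODALITIES) {
    tr <- log$triggers[[mod]]
    if (is.null(tr)) next
    out <- c(out, sprintf("# triggers=%s", mod), sprintf("%.3f", tr$times))
  }
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

parse_kv <- function(tokens) {
  kv <- regmatches(tokens, regexpr("=", tokens), invert = TRUE)
  vals <- vapply(kv, function(p) p[2], character(1))
  names(vals) <- vapply(kv, function(p) p[1], character(1))
  vals
}

#' Read a physiological log from a text file
#'
#' @param path Path to a file written in the format of [write_physio_log()].
#' @return A [physio_log()].
#' @export
read_physio_log <- function(path) {
  if (!file.exists(path)) cg_io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- grep("^#", lines)
  channels <- list()
  triggers <- list()
  meta <- list()
  n <- length(lines)
  block_end <- function(i) {
    nxt <- hdr_idx[hdr_idx > i]
    if (length(nxt)) nxt[1] - 1L else n
  }
  as_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) cg_format_error(sprintf("malformed numeric in %s", what))
    v
  }
  for (i in hdr_idx) {
    body <- sub("^#\\s*", "", lines[i])
    tokens <- strsplit(trimws(body), "\\s+")[[1]]
    if (!length(tokens)) cg_format_error("empty header line")
    if (tokens[1] == "meta") {
      kv <- parse_kv(tokens[-1])
      for (key in names(kv)) {
        meta[[key]] <- if (key %in% c("tr_s", "te_s"))
          as_num(kv[[key]], "meta") else kv[[key]]
      }
    } else if (startsWith(tokens[1], "channel=")) {
      kv <- parse_kv(tokens)
      lab <- kv[["channel"]]
      if (!lab %in% CHANNEL_LABELS)
        cg_format_error(sprintf("unknown channel label '%s'", lab))
      if (lab %in% names(channels))
        cg_format_error(sprintf("duplicate channel header '%s'", lab))
      j <- block_end(i)
      samp <- if (j >= i + 1L)
        as_num(lines[seq(i + 1L, j)], paste("channel", lab)) else numeric(0)
      channels[[lab]] <- channel_trace(
        lab, rate = as_num(kv[["rate_hz"]], "rate"),
        samples = samp, t0 = as_num(kv[["t0_s"]], "t0"),
        units = kv[["units"]])
    } else if (startsWith(tokens[1], "triggers=")) {
      kv <- parse_kv(tokens)
      mod <- kv[["triggers"]]
      if (!mod %in% TRIGGER_MODALITIES)
        cg_format_error(sprintf("unknown trigger modality '%s'", mod))
      if (mod %in% names(triggers))
        cg_format_error(sprintf("duplicate trigger header '%s'", mod))
      j <- block_end(i)
      times <- if (j >= i + 1L)
        as_num(lines[seq(i + 1L, j)], paste("triggers", mod)) else numeric(0)
      triggers[[mod]] <- trigger_train(mod, times)
    } else {
      cg_format_error(sprintf("unrecognized header: '%s'", lines[i]))
    }
  }
  physio_log(channels = unname(channels), triggers = unname(triggers),
             meta = meta)
}

#' Read a CSV score/measurement table
#'
#' Thin wrapper around [utils::read.csv()] enforcing "." decimals.
#' @param path CSV path with a header row.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) cg_io_error(sprintf("no such file: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled trigger-variance summary table (per-subject interval/offset SDs)
#' @return data.frame with one row per subject.
#' @export
cg_table1 <- function() {
  read_score_table(system.file("extdata", "table1.csv",
                               package = "cardiogate", mustWork = TRUE))
}

#' Bundled consensus image-quality score table
#' @return data.frame with one row per subject.
#' @export
cg_table2 <- function() {
  read_score_table(system.file("extdata", "table2.csv",
                               package = "cardiogate", mustWork = TRUE))
}
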