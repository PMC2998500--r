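# Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32,
# mono). No audio package ships with the analysis environment, so the few
# chunk layouts we need are parsed directly.

#' Read a single-channel WAV file as a calibrated microphone trace
#'
#' Samples are normalized to full scale \[-1, 1\] and multiplied by
#' `calibration` (Pa per full-scale unit), yielding a `MIC` trace in Pa.
#' The sampling rate is taken from the WAV header.
#'
#' @param path WAV file path (PCM 16/24-bit or float32, mono).
#' @param calibration Pa per full-scale count (see [calibrate_spl()]).
#' @param t0 Session-clock time of the first sample, seconds.
#' @return A [channel_trace()] labelled `MIC`.
#' @export
read_mic_wav <- function(path, calibration = 1, t0 = 0) {
  if (!file.exists(path)) cg_io_error(sprintf("no such file: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) cg_format_error("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) cg_format_error("not a WAVE file")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (id == "data") {
      if (is.null(fmt)) cg_format_error("data chunk before fmt chunk")
      if (fmt$channels != 1L)
        cg_stop("only single-channel WAV is supported",
                "cg_unsupported_format")
      nbytes <- fmt$bits %/% 8L
      nsamp <- sz %/% nbytes
      if (fmt$format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", nsamp, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$format == 1L && fmt$bits == 24L) {
        raw <- readBin(con, "raw", sz)
        m <- matrix(as.integer(raw[seq_len(nsamp * 3L)]), nrow = 3L)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        x <- v / 2^23
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "numeric", nsamp, size = 4, endian = "little")
      } else {
        cg_stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                        fmt$format, fmt$bits), "cg_unsupported_format")
      }
      samples <- x
      if (sz %% 2L == 1L) readBin(con, "raw", 1)  # chunk padding
    } else {
      readBin(con, "raw", sz + sz %% 2L)          # skip unknown chunk
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) cg_format_error("no data chunk found")
  channel_trace("MIC", rate = fmt$rate, samples = samples * calibration,
                t0 = t0, units = "Pa")
}

#' Write a microphone trace to a WAV file
#'
#' The inverse of [read_mic_wav()]: samples are divided by `calibration`
#' and clipped to full scale.
#'
#' @param trace A [channel_trace()] (any label; samples interpreted as Pa).
#' @param path Output path.
#' @param calibration Pa per full-scale count.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_mic_wav <- function(trace, path, calibration = 1, bits = 16) {
  x <- trace$samples / calibration
  rate <- as.integer(round(trace$rate))
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    cg_io_error(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  if (bits == 16) {
    fmt_code <- 1L; nbytes <- 2L
    pcm <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  } else if (bits == 32) {
    fmt_code <- 3L; nbytes <- 4L
  } else cg_argument_error("bits must be 16 or 32")
  data_sz <- length(x) * nbytes
  wr_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                 endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                 endian = "little")
  writeChar("RIFF", con, eos = NULL); wr_u32(36L + data_sz)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr_u32(16L)
  wr_u16(fmt_code); wr_u16(1L); wr_u32(rate)
  wr_u32(rate * nbytes); wr_u16(nbytes); wr_u16(8L * nbytes)
  writeChar("data", con, eos = NULL); wr_u32(data_sz)
  if (bits == 16) {
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(NULL)
}
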