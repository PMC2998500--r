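# Classed conditions so callers (and tests) can distinguish failure modes.

cg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cg_error"), call = call))
}

cg_format_error     <- function(msg) cg_stop(msg, "cg_format_error")
cg_validation_error <- function(msg) cg_stop(msg, "cg_validation_error")
cg_argument_error   <- function(msg) cg_stop(msg, "cg_argument_error")
cg_io_error         <- function(msg) cg_stop(msg, "cg_io_error")
cg_insufficient_data <- function(msg) cg_stop(msg, "cg_insufficient_data")

#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
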