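#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Commercial rounding: round half away from zero, as score points and
## percentage tables are conventionally reported (base round() is banker's).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log a pipeline message to stderr
#'
#' Minimal leveled logger used by the reading/derivation steps so that data
#' cleaning actions (out-of-range coercions, dropped records) leave a trace.
#'
#' @param ... message parts, pasted together.
#' @param level one of "INFO", "WARN", "ERROR".
#' @return invisibly, the formatted message.
#' @export
nr_log <- function(..., level = c("INFO", "WARN", "ERROR")) {
  level <- match.arg(level)
  msg <- sprintf("[neorisk %s] %s", level, paste0(...))
  message(msg)
  invisible(msg)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
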