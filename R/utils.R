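#' @keywords internal
#' @useDynLib etibdiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a timestamped log message
#'
#' Messages go to `stderr` via [message()]; suppress with
#' `suppressMessages()` or `options(etibdiv.quiet = TRUE)`.
#' @param ... pieces pasted into the message.
#' @keywords internal
ed_log <- function(...) {
  if (isTRUE(getOption("etibdiv.quiet", FALSE))) return(invisible(NULL))
  message("[etibdiv] ", ...)
  invisible(NULL)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# deterministic child seed derived from a user seed; kept below 2^31
# (double arithmetic: products of two < 2^31 factors overflow integers but
# stay exact in doubles)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(k) * 7919) %% 2147483647)
}
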