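#' Package logging
#'
#' Minimal levelled logger used by all pipeline stages. The active level is
#' controlled by `options(ehtmarkers.log_level = ...)`; messages below the
#' active level are suppressed. Levels, in increasing severity: "debug",
#' "info", "warn".
#'
#' @param level one of "debug", "info", "warn"
#' @param ... parts of the message, pasted together
#' @return invisibly, the formatted message (emitted via [message()])
#' @export
eht_log <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  active <- getOption("ehtmarkers.log_level", "info")
  msg <- sprintf("[%s] %s", toupper(level), paste0(..., collapse = ""))
  if (ranks[[level]] >= ranks[[active]]) message(msg)
  invisible(msg)
}

#' Derive a named sub-stream seed from a top-level seed
#'
#' All randomness in the package flows from one user-supplied seed, fanned
#' out into named sub-streams so that adding a stream never perturbs the
#' draws of another. The mapping is a fixed deterministic hash of the stream
#' name folded into the seed, reduced modulo 2^31 - 1 so the result is a
#' valid R integer seed.
#'
#' @param seed integer top-level seed
#' @param name character stream name
#' @return an integer seed for the named stream
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(seed) + h * 2654435) %% 2147483647)
}

# Run code under a named sub-stream of `seed`, restoring RNG state after.
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}
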