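#' @keywords internal
"_PACKAGE"

## numerically stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible integer seed for a named random stream
#'
#' Combines a master seed with a character label through a polynomial string
#' hash so that every (stage, index, arm, ...) stream gets its own stable
#' sub-seed. Adding new streams never perturbs existing ones, and the result
#' always fits in a signed 32-bit integer.
#'
#' @param seed master integer seed.
#' @param ... character/numeric labels identifying the stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "mc", "gEUD", "IC_OFF")
stream_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  mod <- 2147483647 # 2^31 - 1, prime
  h <- 7
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% mod
  as.integer((abs(as.numeric(seed)) %% mod + h) %% (mod - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## shared argument checks
stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

## deterministic hash of an R object (configs in run logs); not cryptographic
object_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "\n")
  mod <- 2147483647
  h <- 7
  for (code in utf8ToInt(txt)) h <- (h * 131 + code) %% mod
  sprintf("%08x", h)
}
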