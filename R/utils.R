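#' Run code with a temporary RNG state
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never clobbers a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Streams for different (condition, replicate, channel) combinations must be
#' independent yet fully determined by the master seed. A small polynomial
#' string hash (base 31, mod 2^31 - 1) keeps the result inside R's 32-bit
#' integer range with no external dependency.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return integer sub-seed in [1, 2^31 - 2].
#' @export
sub_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Percentage with 1-decimal rounding
#'
#' The reporting convention used throughout the association tables:
#' `100 * x / n` rounded to one decimal place.
#'
#' @param x numerator count.
#' @param n denominator count.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
#' @examples
#' percent_of(21430, 50531)  # 42.4
percent_of <- function(x, n, digits = 1) {
  stopifnot(n > 0, x >= 0)
  round(100 * x / n, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
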