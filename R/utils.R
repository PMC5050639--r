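#' Derive a reproducible sub-stream seed
#'
#' Expands one master seed into independent, named seeds for the different
#' stochastic stages of a simulation (masking, QTL choice, residual draws,
#' forest fitting, ...), so that any single stage of a large experiment can be
#' re-run in isolation with exactly the RNG state it saw inside the full run.
#'
#' The labels are folded into the master seed with a 31-bit multiplicative
#' string hash; the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... further labels (character or numeric) naming the sub-stream,
#'   e.g. `substream_seed(42, "mask", iter)`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "mask", 3)
substream_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  tokens <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "/")
  s <- abs(as.numeric(master)) %% 2147483647
  for (k in utf8ToInt(tokens)) s <- (s * 31 + k) %% 2147483647
  as.integer(s)
}

## clip numeric values into [lo, hi]
clip <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

## stop() with sprintf formatting, no call in message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
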