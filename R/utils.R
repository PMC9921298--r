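# internal helpers: error formatting and reproducible local RNG

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' random-number state afterwards, so seeded package functions never disturb
#' the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a named substream seed from a root seed. Keeps every derived seed in
# [1, 2^31 - 2] so it is a valid R integer seed. The hash only has to decouple
# the streams, not be cryptographic.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65521
  v <- as.double(seed) %% 2147483647
  v <- (v * 48271) %% 2147483647
  v <- (v * 31 + h * 9973) %% 2147483646
  as.integer(v) + 1L
}

# format a numeric for CSV so that reading it back agrees to >= 12 significant
# digits (integers round-trip exactly under %.15g)
fmt_num <- function(x) formatC(x, digits = 15, format = "g", width = 1)
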