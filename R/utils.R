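# RNG stream handling. Every stochastic routine draws from a stream seeded
# by a stable hash of (master seed, labels...), so that adding or reordering
# unrelated draws cannot perturb an existing cohort.

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary set of string labels
#' (e.g. exam id, sequence, purpose) into an integer below 2^31 - 1.
#' The hash is plain FNV-style arithmetic on UTF-8 bytes, so it is identical
#' on every platform and R version.
#'
#' @param seed Master integer seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return A single integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  key <- paste(c(format(as.integer(seed)), vapply(list(...), as.character,
                                                  character(1))),
               collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

# Evaluate `expr` under a private RNG stream, restoring the caller's
# RNG state afterwards.
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample a signed percent deviation whose median equals `median_target`.
# The majority sign (the sign of the target) occurs with probability
# p_major; magnitudes are log-normal. The log-normal median of the majority
# branch is solved so that the median of the signed mixture lands exactly
# on the target; minority-sign magnitudes are smaller (factor 0.6).
sample_signed_pct <- function(median_target, sigma, p_major) {
  stopifnot(p_major > 0.5, p_major <= 1)
  m <- abs(median_target) / exp(sigma * qnorm(1 - 0.5 / p_major))
  major <- p_major >= 1 || runif(1) < p_major
  mag <- m * exp(sigma * rnorm(1)) * if (major) 1 else 0.6
  s <- sign(median_target)
  if (s == 0) s <- 1
  if (major) s * mag else -s * mag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the length-1 surprise
sample_safe <- function(x, size = length(x)) x[sample.int(length(x), size)]
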