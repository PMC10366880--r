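# Inter-sequence outlier screening: the 10 percent pairwise percent
# difference threshold, flagged pairs, and the reference TKV as the mean of
# error-free sequences.

#' Screening configuration
#'
#' @param threshold_pct Percent-difference threshold above which a sequence
#'   pair is flagged (default 10).
#' @param exclude_unexplained When screening flags an exam but no geometric
#'   detector fires, exclude the sequence with maximum absolute deviation
#'   from the exam median as an UNEXPLAINED_OUTLIER (default `TRUE`).
#' @param strict_exclusion Exclude every flagged sequence from the reference
#'   even when a correction restored it (default `FALSE`: corrected
#'   composing/breath-hold sequences re-enter the reference).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(threshold_pct = 10, exclude_unexplained = TRUE,
                             strict_exclusion = FALSE) {
  stopifnot(threshold_pct > 0)
  structure(list(threshold_pct = threshold_pct,
                 exclude_unexplained = exclude_unexplained,
                 strict_exclusion = strict_exclusion),
            class = "screening_config")
}

#' Pairwise percent difference of two volumes
#'
#' `100 * |a - b| / ((a + b) / 2)`: symmetric in its arguments, denominator
#' the mean of the pair.
#'
#' @param a,b Positive volumes (vectorized).
#' @return Percent difference.
#' @export
pairwise_pct_diff <- function(a, b) {
  if (any(a <= 0 | b <= 0)) stop("volumes must be positive")
  100 * abs(a - b) / ((a + b) / 2)
}

#' Signed percent deviation from a reference volume
#'
#' `100 * (tkv - reference) / reference`.
#'
#' @param tkv Measured volume.
#' @param reference Positive reference volume.
#' @return Signed percent deviation.
#' @export
signed_deviation <- function(tkv, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (tkv - reference) / reference
}

#' Screen one exam's per-sequence TKVs for outlier pairs
#'
#' Computes the full symmetric pairwise percent-difference matrix and flags
#' every unordered pair exceeding the threshold. An exam with any flagged
#' pair is marked for acquisition-error review.
#'
#' @param tkvs Named numeric vector of per-sequence TKVs (>= 2 sequences).
#' @param config A [screening_config()].
#' @return List with `matrix` (symmetric, zero diagonal), `flagged_pairs`
#'   (data frame seq_a, seq_b, pct_diff) and `review` (logical).
#' @export
screen_exam <- function(tkvs, config = screening_config()) {
  if (length(tkvs) < 2) stop("need at least two sequences to screen")
  if (is.null(names(tkvs))) names(tkvs) <- paste0("seq", seq_along(tkvs))
  n <- length(tkvs)
  m <- matrix(0, n, n, dimnames = list(names(tkvs), names(tkvs)))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pairwise_pct_diff(tkvs[i], tkvs[j])
      m[i, j] <- m[j, i] <- d
      if (d > config$threshold_pct)
        pairs[[length(pairs) + 1L]] <- data.frame(
          seq_a = names(tkvs)[i], seq_b = names(tkvs)[j], pct_diff = d,
          stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  flagged <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(seq_a = character(0), seq_b = character(0),
               pct_diff = numeric(0))
  list(matrix = m, flagged_pairs = flagged, review = nrow(flagged) > 0)
}

#' Reference TKV from error-free sequences
#'
#' Arithmetic mean of the TKVs of unflagged sequences; when no sequence is
#' flagged, the mean of all. When every sequence is flagged the reference is
#' undefined and the exam needs manual review.
#'
#' @param tkvs Named numeric vector of per-sequence TKVs.
#' @param flagged_sequences Character vector of sequences excluded as
#'   erroneous.
#' @return List with `reference_ml` (`NA` when undefined), `included`
#'   (character) and `status` (`"OK"` or `"MANUAL_REVIEW"`).
#' @export
reference_tkv <- function(tkvs, flagged_sequences = character(0)) {
  included <- setdiff(names(tkvs), flagged_sequences)
  if (length(included) == 0) {
    return(list(reference_ml = NA_real_, included = character(0),
                status = "MANUAL_REVIEW"))
  }
  list(reference_ml = mean(tkvs[included]), included = included,
       status = "OK")
}
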