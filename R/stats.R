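# Agreement and bias statistics: coefficient of variation, observer
# agreement, per-sequence bias relative to the reference, mean pairwise
# percent-difference matrices before and after exclusion, and Bland-Altman
# limits of agreement. Sample (n-1) standard deviations throughout.

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#'
#' @param values Numeric vector of at least two positive values.
#' @return CV in percent; `NA` when fewer than two values.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  100 * stats::sd(values) / mean(values)
}

#' Inter-observer agreement for one sequence of one exam
#'
#' @param tkvs Numeric vector of per-observer TKVs (>= 2 observers).
#' @return List with `mean_ml`, `cv_pct` and `max_pct_diff` (maximum over
#'   observer pairs of the pairwise percent difference).
#' @export
observer_agreement <- function(tkvs) {
  if (length(tkvs) < 2) stop("need at least two observers")
  n <- length(tkvs)
  mx <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      mx <- max(mx, pairwise_pct_diff(tkvs[i], tkvs[j]))
  list(mean_ml = mean(tkvs), cv_pct = coefficient_of_variation(tkvs),
       max_pct_diff = mx)
}

#' Per-sequence bias across a cohort
#'
#' Mean signed deviation from the exam reference per sequence, computed over
#' exams where the sequence was free of (or corrected for) acquisition
#' errors, plus fixed 1-percent-point histogram bins over [-10, 10] for each
#' sequence's deviation distribution.
#'
#' @param deviations Data frame with columns `exam_id`, `sequence`,
#'   `deviation_pct`, `included` (logical).
#' @return List with `bias` (named mean deviation per sequence, `NA` where a
#'   sequence was never included), `n` (contributing exams) and `histogram`
#'   (data frame sequence, bin_lo, bin_hi, count).
#' @export
sequence_bias <- function(deviations) {
  seqs <- intersect(SEQUENCES, unique(deviations$sequence))
  if (length(seqs) == 0) seqs <- unique(deviations$sequence)
  bias <- setNames(rep(NA_real_, length(seqs)), seqs)
  n <- setNames(integer(length(seqs)), seqs)
  breaks <- seq(-10, 10, by = 1)
  hist_rows <- list()
  for (sq in seqs) {
    d <- deviations$deviation_pct[deviations$sequence == sq &
                                    deviations$included]
    d <- d[!is.na(d)]
    n[sq] <- length(d)
    if (length(d) > 0) bias[sq] <- mean(d)
    cnt <- table(cut(d[d >= -10 & d <= 10], breaks, right = FALSE))
    hist_rows[[sq]] <- data.frame(sequence = sq, bin_lo = breaks[-length(breaks)],
                                  bin_hi = breaks[-1], count = as.integer(cnt))
  }
  list(bias = bias, n = n, histogram = do.call(rbind, hist_rows))
}

#' Mean pairwise percent-difference matrices, pre and post exclusion
#'
#' Entry (i, j) is the mean over exams of the pairwise percent difference
#' between sequences i and j. The post matrix uses post-correction TKVs and
#' drops, exam-wise, pairs in which either sequence was excluded.
#'
#' @param tkv_pre,tkv_post Numeric matrices `[exam x sequence]` of
#'   observer-mean TKVs.
#' @param included Logical matrix `[exam x sequence]`.
#' @return List of two symmetric matrices `pre` and `post` (entries `NA`
#'   where no exam contributes).
#' @export
pairwise_matrix <- function(tkv_pre, tkv_post = tkv_pre,
                            included = NULL) {
  seqs <- colnames(tkv_pre)
  if (is.null(included))
    included <- matrix(TRUE, nrow(tkv_pre), ncol(tkv_pre),
                       dimnames = dimnames(tkv_pre))
  mk <- function(tkv, inc) {
    m <- matrix(NA_real_, length(seqs), length(seqs),
                dimnames = list(seqs, seqs))
    diag(m) <- 0
    for (i in seq_along(seqs)[-length(seqs)]) {
      for (j in (i + 1):length(seqs)) {
        ok <- inc[, i] & inc[, j] & !is.na(tkv[, i]) & !is.na(tkv[, j])
        if (any(ok)) {
          d <- pairwise_pct_diff(tkv[ok, i], tkv[ok, j])
          m[i, j] <- m[j, i] <- mean(d)
        }
      }
    }
    m
  }
  list(pre = mk(tkv_pre, included | TRUE), post = mk(tkv_post, included))
}

#' Bland-Altman summary of paired measurements
#'
#' @param a Either the differences themselves, or the first member of each
#'   pair when `b` is given.
#' @param b Optional second member of each pair.
#' @return List with `mean_diff`, `loa` (`mean +- 1.96 sd`, sample SD) and
#'   `sd_diff`.
#' @export
bland_altman <- function(a, b = NULL) {
  d <- if (is.null(b)) a else a - b
  if (length(d) < 2) stop("need at least two pairs")
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa = c(lower = m - 1.96 * s,
                                           upper = m + 1.96 * s))
}

#' Cohort-level agreement and bias statistics
#'
#' Aggregates per-exam QC results into: per-exam inter-sequence CV pre and
#' post exclusion (with mean, median and IQR), the pre/post mean pairwise
#' percent-difference matrices, per-sequence bias with histogram data,
#' per-sequence inter-observer agreement (median CV and median max percent
#' difference across exams), and Bland-Altman summaries for each sequence
#' pair (on pre-correction signed percent differences). A Shapiro-Wilk
#' normality screen on the per-exam CVs chooses whether the headline
#' location summary is reported as mean +- SD or median [IQR]; both are
#' always present.
#'
#' @param results List of per-exam QC results from [analyze_exam()].
#' @return An object of class `tkv_cohort_stats`.
#' @export
cohort_stats <- function(results) {
  seqs <- SEQUENCES
  n <- length(results)
  tkv_pre <- tkv_post <- included <-
    matrix(NA, n, length(seqs), dimnames = list(NULL, seqs))
  cv_pre <- cv_post <- rep(NA_real_, n)
  dev_rows <- list()
  obs_rows <- list()
  for (e in seq_len(n)) {
    r <- results[[e]]
    tkv_pre[e, ] <- r$tkv_pre_seq[seqs]
    tkv_post[e, ] <- r$tkv_post_seq[seqs]
    included[e, ] <- seqs %in% r$included
    cv_pre[e] <- coefficient_of_variation(r$tkv_pre_seq)
    if (length(r$included) >= 2)
      cv_post[e] <- coefficient_of_variation(r$tkv_post_seq[r$included])
    dev_rows[[e]] <- data.frame(
      exam_id = r$exam_id, sequence = seqs,
      deviation_pct = unname(r$deviations_pct[seqs]),
      included = seqs %in% r$included, stringsAsFactors = FALSE)
    if (!is.null(r$observer_agreement))
      obs_rows[[e]] <- cbind(exam_id = r$exam_id, r$observer_agreement)
  }
  included <- matrix(as.logical(included), n, length(seqs),
                     dimnames = list(NULL, seqs))
  deviations <- do.call(rbind, dev_rows)
  bias <- sequence_bias(deviations)
  matrices <- pairwise_matrix(tkv_pre, tkv_post, included)

  obs_agree <- NULL
  if (length(obs_rows) > 0) {
    oa <- do.call(rbind, obs_rows)
    agg <- function(v) c(median = stats::median(v, na.rm = TRUE),
                         q1 = unname(quantile(v, 0.25, na.rm = TRUE)),
                         q3 = unname(quantile(v, 0.75, na.rm = TRUE)))
    obs_agree <- do.call(rbind, lapply(split(oa, oa$sequence), function(d)
      data.frame(sequence = d$sequence[1],
                 median_cv_pct = agg(d$cv_pct)[1],
                 cv_q1 = agg(d$cv_pct)[2], cv_q3 = agg(d$cv_pct)[3],
                 median_max_pct_diff = agg(d$max_pct_diff)[1],
                 row.names = NULL)))
    all_row <- data.frame(sequence = "ALL",
                          median_cv_pct = stats::median(oa$cv_pct, na.rm = TRUE),
                          cv_q1 = unname(quantile(oa$cv_pct, 0.25, na.rm = TRUE)),
                          cv_q3 = unname(quantile(oa$cv_pct, 0.75, na.rm = TRUE)),
                          median_max_pct_diff =
                            stats::median(oa$max_pct_diff, na.rm = TRUE))
    obs_agree <- rbind(obs_agree, all_row)
  }

  ba <- list()
  for (i in seq_along(seqs)[-length(seqs)]) {
    for (j in (i + 1):length(seqs)) {
      ok <- !is.na(tkv_pre[, i]) & !is.na(tkv_pre[, j])
      if (sum(ok) >= 2) {
        d <- 100 * (tkv_pre[ok, i] - tkv_pre[ok, j]) /
          ((tkv_pre[ok, i] + tkv_pre[ok, j]) / 2)
        ba[[paste(seqs[i], seqs[j], sep = "-")]] <- bland_altman(d)
      }
    }
  }

  normal <- if (sum(!is.na(cv_pre)) >= 3 &&
                length(unique(stats::na.omit(cv_pre))) > 1)
    tryCatch(stats::shapiro.test(stats::na.omit(cv_pre))$p.value > 0.05,
             error = function(e) FALSE) else FALSE
  structure(list(
    n_exams = n,
    cv_pre = cv_pre, cv_post = cv_post,
    mean_cv_pre = mean(cv_pre, na.rm = TRUE),
    mean_cv_post = mean(cv_post, na.rm = TRUE),
    median_cv_pre = stats::median(cv_pre, na.rm = TRUE),
    median_cv_post = stats::median(cv_post, na.rm = TRUE),
    cv_summary_style = if (normal) "mean_sd" else "median_iqr",
    pairwise = matrices,
    sequence_bias = bias$bias, bias_n = bias$n,
    bias_histogram = bias$histogram,
    observer_agreement = obs_agree,
    bland_altman = ba,
    deviations = deviations,
    sd_definition = "sample (n-1)"
  ), class = "tkv_cohort_stats")
}

#' @export
print.tkv_cohort_stats <- function(x, ...) {
  cat(sprintf("TKV cohort statistics over %d exams\n", x$n_exams))
  cat(sprintf("  inter-sequence CV: mean %.2f%% pre, %.2f%% post exclusion\n",
              x$mean_cv_pre, x$mean_cv_post))
  cat(sprintf("                     median %.2f%% pre, %.2f%% post\n",
              x$median_cv_pre, x$median_cv_post))
  cat("  per-sequence bias (mean % deviation from reference):\n")
  for (sq in names(x$sequence_bias))
    cat(sprintf("    %-9s %+6.2f%%  (n = %d)\n", sq, x$sequence_bias[[sq]],
                x$bias_n[[sq]]))
  if (!is.null(x$observer_agreement)) {
    all_row <- x$observer_agreement[x$observer_agreement$sequence == "ALL", ]
    cat(sprintf("  inter-observer CV (median [IQR]): %.2f%% [%.2f-%.2f]\n",
                all_row$median_cv_pct, all_row$cv_q1, all_row$cv_q3))
  }
  invisible(x)
}

#' Histogram of per-sequence deviations from the reference
#'
#' Base-graphics rendering of the per-sequence deviation histograms
#' (1-percent-point bins over [-10, 10]).
#'
#' @param x A `tkv_cohort_stats` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.tkv_cohort_stats <- function(x, ...) {
  h <- x$bias_histogram
  seqs <- unique(h$sequence)
  old <- graphics::par(mfrow = c(length(seqs), 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (sq in seqs) {
    d <- h[h$sequence == sq, ]
    graphics::barplot(d$count, names.arg = sprintf("%d", d$bin_lo),
                      main = sq, ylab = "exams", ...)
  }
  invisible(x)
}
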