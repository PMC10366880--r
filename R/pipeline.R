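# Orchestration: volumes -> screening -> detection -> correction ->
# reference and deviations, per exam; then cohort aggregation. Exams are
# processed one at a time so cohort size does not grow memory.

#' Pipeline configuration
#'
#' @param simulation A [synthetic_config()] to generate the cohort, or
#'   `NULL` when reading stacks from `input_dir`.
#' @param input_dir Directory of NIfTI stacks written by [simulate_cohort()]
#'   (used when `simulation` is `NULL`).
#' @param screening A [screening_config()].
#' @param detection A [detection_config()].
#' @param detect_scope `"all"` (audit mode: every sequence of every exam is
#'   reviewed by the geometric detectors; the default, since the detectors
#'   are cheap and sub-threshold errors still bias the reference) or
#'   `"flagged"` (only exams flagged by the 10 percent screen are reviewed,
#'   mirroring a manual-review workload).
#' @param output_dir Optional directory for the artifact bundle (CSV/JSON).
#' @param seed Master seed (forwarded to the simulation config when one is
#'   given without a seed of its own).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL,
                            screening = screening_config(),
                            detection = detection_config(),
                            detect_scope = c("all", "flagged"),
                            output_dir = NULL, seed = 1L) {
  detect_scope <- match.arg(detect_scope)
  if (is.null(simulation) && is.null(input_dir))
    stop("either a simulation config or an input directory is required")
  structure(list(simulation = simulation, input_dir = input_dir,
                 screening = screening, detection = detection,
                 detect_scope = detect_scope, output_dir = output_dir,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Analyze one exam: volumes, screening, detection, correction, reference
#'
#' @param stacks Nested list `[[observer]][[sequence]]` of binary
#'   [slice_stack()]s (a plain named list is treated as one observer).
#' @param exam_id Identifier used in outputs.
#' @param screening A [screening_config()].
#' @param detection A [detection_config()].
#' @param detect_scope `"all"` or `"flagged"` (see [pipeline_config()]).
#' @return An exam QC result: per-sequence pre/post TKVs (observer means),
#'   the pairwise percent-difference matrix, flagged pairs, classified
#'   flags, correction records, excluded/included sequences, the reference
#'   TKV (mean over observers of the per-observer mean of included
#'   sequences), per-sequence signed deviations from the reference, and an
#'   exam status.
#' @export
analyze_exam <- function(stacks, exam_id = "exam",
                         screening = screening_config(),
                         detection = detection_config(),
                         detect_scope = c("all", "flagged")) {
  detect_scope <- match.arg(detect_scope)
  if (inherits(stacks[[1]], "slice_stack")) stacks <- list(stacks)
  n_obs <- length(stacks)
  seqs <- names(stacks[[1]])

  vol_rows <- list()
  tkv_pre <- matrix(NA_real_, n_obs, length(seqs),
                    dimnames = list(NULL, seqs))
  labeled1 <- list()   # observer-1 labeled stacks, shared with detection
  for (obs in seq_len(n_obs)) {
    for (sq in seqs) {
      if (obs == 1L) {
        lab <- suppressWarnings(split_left_right(stacks[[1]][[sq]]))
        labeled1[[sq]] <- lab
        v <- compute_volumes(lab)
      } else {
        v <- tkv(stacks[[obs]][[sq]])
      }
      tkv_pre[obs, sq] <- v$total_ml
      vol_rows[[length(vol_rows) + 1L]] <- data.frame(
        exam_id = exam_id, observer = obs, sequence = sq,
        right_ml = v$right_ml, left_ml = v$left_ml, total_ml = v$total_ml,
        stringsAsFactors = FALSE)
    }
  }
  tkv_pre_seq <- colMeans(tkv_pre)

  scr <- screen_exam(tkv_pre_seq, screening)
  review_seqs <- if (detect_scope == "all") seqs else
    unique(c(scr$flagged_pairs$seq_a, scr$flagged_pairs$seq_b))
  det <- classify_exam_errors(labeled1, detection, sequences = review_seqs)
  flags <- det$flags

  corr <- apply_corrections(stacks, flags, detection)
  tkv_post <- tkv_pre
  if (nrow(corr$records) > 0) {
    for (r in seq_len(nrow(corr$records))) {
      rec <- corr$records[r, ]
      if (rec$action != "NONE")
        tkv_post[rec$observer, rec$sequence] <- rec$tkv_after_ml
    }
  }
  tkv_post_seq <- colMeans(tkv_post)

  excluded <- corr$excluded
  # a corrected sequence is still excluded when an uncorrectable error
  # type fired on it as well (kept in the flag's evidence)
  for (fl in flags) {
    if (any(c("BREATHING_MOTION", "INCOMPLETE_KIDNEY") %in%
              fl$evidence$also_detected))
      excluded <- unique(c(excluded, fl$sequence))
  }
  if (screening$strict_exclusion)
    excluded <- unique(c(excluded, vapply(flags, `[[`, "", "sequence")))

  # screening flagged the exam but no detector explains it: call the most
  # deviant sequence an unexplained outlier
  if (scr$review && length(flags) == 0 && screening$exclude_unexplained) {
    dev_med <- abs(tkv_pre_seq - stats::median(tkv_pre_seq))
    worst <- names(which.max(dev_med))
    flags <- c(flags, list(qc_flag(
      "UNEXPLAINED_OUTLIER", worst,
      evidence = list(abs_dev_from_median_ml = unname(dev_med[worst])),
      affected_slices = integer(0), correctable = FALSE)))
    excluded <- unique(c(excluded, worst))
  }

  included <- setdiff(seqs, excluded)
  if (length(included) > 0) {
    ref_by_obs <- vapply(seq_len(n_obs), function(o)
      mean(tkv_post[o, included]), numeric(1))
    reference_ml <- mean(ref_by_obs)
    status <- if (length(excluded) > 0) "EXCLUSIONS"
      else if (any(vapply(flags, `[[`, TRUE, "correctable"))) "CORRECTED"
      else "OK"
  } else {
    reference_ml <- NA_real_
    status <- "MANUAL_REVIEW"
  }
  deviations <- if (is.na(reference_ml))
    setNames(rep(NA_real_, length(seqs)), seqs) else
    signed_deviation(tkv_post_seq, reference_ml)

  obs_agree <- NULL
  if (n_obs >= 2) {
    obs_agree <- do.call(rbind, lapply(seqs, function(sq) {
      a <- observer_agreement(tkv_pre[, sq])
      data.frame(sequence = sq, mean_ml = a$mean_ml, cv_pct = a$cv_pct,
                 max_pct_diff = a$max_pct_diff, stringsAsFactors = FALSE)
    }))
  }

  list(exam_id = exam_id,
       volumes = do.call(rbind, vol_rows),
       tkv_pre = tkv_pre, tkv_post = tkv_post,
       tkv_pre_seq = tkv_pre_seq, tkv_post_seq = tkv_post_seq,
       pairwise_matrix = scr$matrix,
       flagged_pairs = scr$flagged_pairs,
       flags = flags,
       corrections = corr$records,
       not_evaluable = det$not_evaluable,
       excluded = excluded, included = included,
       reference_ml = reference_ml,
       deviations_pct = deviations,
       observer_agreement = obs_agree,
       status = status)
}

flags_to_df <- function(exam_id, flags) {
  if (length(flags) == 0)
    return(data.frame(exam_id = character(0), sequence = character(0),
                      error_type = character(0), correctable = logical(0),
                      affected_slices = character(0)))
  do.call(rbind, lapply(flags, function(f) data.frame(
    exam_id = exam_id, sequence = f$sequence, error_type = f$error_type,
    correctable = f$correctable,
    affected_slices = paste(f$affected_slices, collapse = ";"),
    stringsAsFactors = FALSE)))
}

#' Run the full QC pipeline over a cohort
#'
#' Simulates (or reads) each exam, computes per-sequence volumes, screens
#' for inter-sequence outliers, detects and corrects acquisition errors,
#' derives the reference TKV and deviations, and aggregates cohort
#' statistics. With `output_dir` set in the config, writes `volumes.csv`,
#' `flags.json`, `flags.csv`, `corrections.csv`, `qc_summary.csv`,
#' `error_summary.csv`, `stats.json` and the resolved configuration as
#' `config.yaml`; outputs are byte-identical for identical inputs, config
#' and seed.
#'
#' @param config A [pipeline_config()].
#' @return List with `results` (per-exam QC results), `stats`
#'   ([cohort_stats()]), `volumes`, `flags`, `corrections`,
#'   `error_summary` data frames, `truths` (simulation only) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list(); truths <- list()
  vol <- list(); fl <- list(); co <- list()

  failed <- list()
  process <- function(stacks, exam_id) {
    r <- tryCatch(
      analyze_exam(stacks, exam_id, config$screening, config$detection,
                   config$detect_scope),
      error = function(e) e)
    if (inherits(r, "error")) {
      # one broken exam must not take the cohort down
      warning("exam ", exam_id, " failed: ", conditionMessage(r),
              call. = FALSE)
      failed[[length(failed) + 1L]] <<- data.frame(
        exam_id = exam_id, message = conditionMessage(r))
      return(invisible(NULL))
    }
    results[[length(results) + 1L]] <<- r
    vol[[length(vol) + 1L]] <<- r$volumes
    fl[[length(fl) + 1L]] <<- flags_to_df(exam_id, r$flags)
    if (nrow(r$corrections) > 0)
      co[[length(co) + 1L]] <<- cbind(exam_id = exam_id, r$corrections)
  }

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    for (i in seq_len(sim$n_exams)) {
      exam <- generate_exam(sim, i)
      truths[[length(truths) + 1L]] <- exam$truth
      process(exam$stacks, exam$exam_id)
    }
  } else {
    files <- list.files(config$input_dir, pattern = "\\.nii(\\.gz)?$")
    exam_ids <- sort(unique(sub("_(AX|COR)_.*$", "", files)))
    for (id in exam_ids)
      process(read_exam_nifti(config$input_dir, id), id)
  }

  stats <- cohort_stats(results)
  flags_df <- do.call(rbind, fl)
  bundle <- list(
    results = results, stats = stats,
    volumes = do.call(rbind, vol),
    flags = flags_df,
    corrections = if (length(co)) do.call(rbind, co) else NULL,
    error_summary = summarize_flags(flags_df, length(results)),
    failed_exams = if (length(failed)) do.call(rbind, failed) else NULL,
    truths = if (length(truths)) truths else NULL,
    config = config)
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

#' Error-summary table: counts and percentages by type and sequence
#'
#' One row per error type plus a total row; columns count flags over all
#' sequences (with the percentage of all sequence measurements), the number
#' of affected exams (percentage of exams), and per-sequence counts.
#'
#' @param flags_df Flag data frame from [run_pipeline()].
#' @param n_exams Number of exams reviewed.
#' @param sequences Sequence set (default the five standard sequences).
#' @return A data frame.
#' @export
summarize_flags <- function(flags_df, n_exams,
                            sequences = tkv_sequences()) {
  types <- c(ERROR_TYPES, "UNEXPLAINED_OUTLIER")
  n_seq_total <- n_exams * length(sequences)
  rows <- list()
  for (ty in c(types, "TOTAL")) {
    d <- if (ty == "TOTAL") flags_df else
      flags_df[flags_df$error_type == ty, , drop = FALSE]
    row <- data.frame(error_type = ty,
                      n_sequences = nrow(d),
                      pct_sequences = if (n_seq_total > 0)
                        100 * nrow(d) / n_seq_total else NA_real_,
                      n_exams = length(unique(d$exam_id)),
                      pct_exams = if (n_exams > 0)
                        100 * length(unique(d$exam_id)) / n_exams else NA_real_)
    for (sq in sequences) row[[sq]] <- sum(d$sequence == sq)
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$volumes, file.path(dir, "volumes.csv"), row.names = FALSE)
  write.csv(bundle$flags, file.path(dir, "flags.csv"), row.names = FALSE)
  if (!is.null(bundle$corrections))
    write.csv(bundle$corrections, file.path(dir, "corrections.csv"),
              row.names = FALSE)
  write.csv(bundle$error_summary, file.path(dir, "error_summary.csv"),
            row.names = FALSE)
  qc <- do.call(rbind, lapply(bundle$results, function(r) data.frame(
    exam_id = r$exam_id, status = r$status,
    reference_ml = r$reference_ml,
    n_flags = length(r$flags),
    excluded = paste(r$excluded, collapse = ";"),
    cv_pre_pct = coefficient_of_variation(r$tkv_pre_seq),
    cv_post_pct = if (length(r$included) >= 2)
      coefficient_of_variation(r$tkv_post_seq[r$included]) else NA_real_,
    stringsAsFactors = FALSE)))
  write.csv(qc, file.path(dir, "qc_summary.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$stats$pairwise$pre),
            file.path(dir, "pairwise_pct_diff_pre.csv"))
  write.csv(as.data.frame(bundle$stats$pairwise$post),
            file.path(dir, "pairwise_pct_diff_post.csv"))
  write.csv(bundle$stats$bias_histogram,
            file.path(dir, "deviation_histogram.csv"), row.names = FALSE)
  if (!is.null(bundle$stats$observer_agreement))
    write.csv(bundle$stats$observer_agreement,
              file.path(dir, "observer_agreement.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(bundle$results, function(r) list(
      exam_id = r$exam_id, status = r$status,
      reference_ml = r$reference_ml,
      excluded = r$excluded,
      deviations_pct = as.list(r$deviations_pct),
      flags = lapply(r$flags, unclass))),
    file.path(dir, "flags.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  s <- bundle$stats
  jsonlite::write_json(list(
    n_exams = s$n_exams,
    mean_cv_pre_pct = s$mean_cv_pre, mean_cv_post_pct = s$mean_cv_post,
    median_cv_pre_pct = s$median_cv_pre,
    median_cv_post_pct = s$median_cv_post,
    cv_summary_style = s$cv_summary_style,
    sequence_bias_pct = as.list(s$sequence_bias),
    pairwise_pre = s$pairwise$pre, pairwise_post = s$pairwise$post,
    sd_definition = s$sd_definition,
    thresholds = unclass(bundle$config$detection),
    screening = unclass(bundle$config$screening)),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- bundle$config
  yaml::write_yaml(list(
    detect_scope = cfg$detect_scope,
    screening = unclass(cfg$screening),
    detection = unclass(cfg$detection),
    simulation = if (!is.null(cfg$simulation)) unclass(cfg$simulation),
    input_dir = cfg$input_dir, seed = cfg$seed),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
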