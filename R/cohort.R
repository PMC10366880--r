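# Exam-level synthesis: anatomy shared across sequences and observers,
# per-sequence bias, per-(observer, sequence, kidney) multiplicative noise,
# and one acquisition-error realization per sequence applied identically to
# every observer variant (the error is a property of the acquisition, not of
# the reader).

#' Generate one synthetic multi-sequence exam
#'
#' @param config A [synthetic_config()].
#' @param exam_index Integer exam index within the cohort.
#' @param sequences Sequences to rasterize (default all five).
#' @param observers Number of observer variants (default from config).
#' @param inject Inject acquisition errors at the configured rates
#'   (default `TRUE`; set `FALSE` for a clean exam).
#' @return List with `exam_id`, `stacks` (nested list `[[observer]][[sequence]]`
#'   of [slice_stack()]s) and `truth`, the ground-truth ledger entry: true
#'   per-kidney volumes, applied biases, observer noise multipliers, clean
#'   digitized TKVs, and one record per injected error with its exactly
#'   bookkept expected TKV perturbation.
#' @export
generate_exam <- function(config, exam_index, sequences = SEQUENCES,
                          observers = config$n_observers, inject = TRUE) {
  anatomy <- sample_anatomy(config, exam_index)
  check_fit(anatomy, config, exam_index)
  exam_id <- sprintf("exam%04d", exam_index)
  sdlog <- sqrt(log(1 + config$observer_cv^2))

  # error realizations per sequence (independent of observer count)
  injected <- list()
  if (inject) {
    for (sq in sequences) {
      for (ty in ERROR_TYPES) {
        rate <- config$error_rates[ty, sq]
        if (rate <= 0) next
        hit <- with_stream(derive_seed(config$seed, "exam", exam_index,
                                       "draw", sq, ty),
                           runif(1) < rate)
        if (hit) injected[[length(injected) + 1L]] <- list(sequence = sq,
                                                           type = ty)
      }
    }
  }

  stacks <- vector("list", observers)
  clean_tkv <- matrix(NA_real_, observers, length(sequences),
                      dimnames = list(NULL, sequences))
  noise_mult <- matrix(NA_real_, observers, length(sequences),
                       dimnames = list(NULL, sequences))
  plans <- list()

  for (obs in seq_len(observers)) {
    stacks[[obs]] <- list()
    for (sq in sequences) {
      b <- config$sequence_biases[[sq]]
      noise <- with_stream(
        derive_seed(config$seed, "exam", exam_index, "obsnoise", obs, sq),
        exp(rnorm(2, -sdlog^2 / 2, sdlog)))   # volume-scale, per kidney
      extra <- c(right = ((1 + b) * noise[1])^(1 / 3),
                 left = ((1 + b) * noise[2])^(1 / 3))
      jit <- with_stream(
        derive_seed(config$seed, "exam", exam_index, "raster", obs, sq),
        runif(3))
      st <- rasterize_stack(anatomy, sq, config, extra, jit)
      clean_tkv[obs, sq] <- sum(st$mask > 0) *
        prod(st$pixel_spacing_mm) * st$nominal_spacing_mm / 1000
      noise_mult[obs, sq] <- mean(noise)
      for (inj in injected) {
        if (inj$sequence != sq) next
        key <- paste(sq, inj$type, sep = ":")
        if (is.null(plans[[key]])) {
          # plan drawn once, from the first observer's stack geometry
          mag <- config$error_magnitudes[[inj$type]]
          plans[[key]] <- with_stream(
            derive_seed(config$seed, "exam", exam_index, "plan", sq, inj$type),
            plan_error(st, inj$type, mag))
        }
        st <- apply_error_plan(st, plans[[key]])
      }
      stacks[[obs]][[sq]] <- st
    }
  }

  truth <- list(
    exam_id = exam_id,
    true_tkv_ml = anatomy$tkv_true_ml,
    true_kidney_ml = anatomy$kidney_true_ml,
    sequence_biases = config$sequence_biases[sequences],
    observer_noise = noise_mult,
    clean_tkv_ml = clean_tkv,
    errors = unname(plans)
  )
  for (i in seq_along(truth$errors))
    truth$errors[[i]]$sequence <- strsplit(names(plans)[i], ":")[[1]][1]
  list(exam_id = exam_id, stacks = stacks, truth = truth)
}

#' Simulate a cohort of synthetic exams
#'
#' Exams are generated one at a time. With `out_dir` set, mask stacks are
#' written as NIfTI files (one per exam x sequence x observer, with a JSON
#' geometry sidecar) together with a truth ledger (`truth.csv`, `truth.json`)
#' and the generator configuration (`config.yaml`). With a `callback`, each
#' exam is passed to the callback and discarded, which keeps memory flat for
#' large cohorts. Otherwise the full list of exams is returned (sensible
#' only for small cohorts).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @param callback Optional `function(exam)` applied to each exam.
#' @return Invisibly, the list of truth ledger entries (plus exams when
#'   neither `out_dir` nor `callback` is given).
#' @export
simulate_cohort <- function(config, out_dir = NULL, callback = NULL) {
  truths <- vector("list", config$n_exams)
  exams <- if (is.null(out_dir) && is.null(callback))
    vector("list", config$n_exams) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  for (i in seq_len(config$n_exams)) {
    exam <- generate_exam(config, i)
    truths[[i]] <- exam$truth
    if (!is.null(out_dir)) write_exam_nifti(exam, out_dir)
    if (!is.null(callback)) callback(exam)
    if (!is.null(exams)) exams[[i]] <- exam
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(truth_ledger(truths), file.path(out_dir, "truth.csv"),
              row.names = FALSE)
  }
  if (!is.null(exams)) {
    invisible(structure(list(exams = exams, truths = truths),
                        class = "tkv_cohort"))
  } else {
    invisible(truths)
  }
}

#' Flatten truth ledger entries into a data frame
#'
#' One row per exam x injected error (exams without errors get one row with
#' empty error fields).
#'
#' @param truths List of truth entries from [simulate_cohort()] /
#'   [generate_exam()].
#' @return A data frame.
#' @export
truth_ledger <- function(truths) {
  rows <- list()
  for (tr in truths) {
    base <- data.frame(exam_id = tr$exam_id, true_tkv_ml = tr$true_tkv_ml,
                       true_right_ml = tr$true_kidney_ml[["right"]],
                       true_left_ml = tr$true_kidney_ml[["left"]],
                       stringsAsFactors = FALSE)
    if (length(tr$errors) == 0) {
      base$error_type <- NA_character_; base$sequence <- NA_character_
      base$target_pct <- NA_real_; base$expected_dv_ml <- NA_real_
      rows[[length(rows) + 1L]] <- base
    } else {
      for (e in tr$errors) {
        r <- base
        r$error_type <- e$type; r$sequence <- e$sequence
        r$target_pct <- e$target_pct; r$expected_dv_ml <- e$expected_dv_ml
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  do.call(rbind, rows)
}
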