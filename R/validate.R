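# Labeled-simulation validation of the detectors: inject each error type
# into independently generated single-sequence stacks, classify, and count
# the confusion between injected and detected types. Clean stacks measure
# specificity.

#' Validate detectors on labeled synthetic stacks
#'
#' For each error type, generates `n_per_type` single-sequence phantom
#' stacks (sequence drawn according to the type's configured per-sequence
#' rates), injects the error at configured magnitudes, and classifies the
#' result with [classify_exam_errors()]; `n_clean` clean stacks (sequences
#' cycled) measure the false-positive rate. Sensitivity counts a detection
#' of the *injected* type; specificity is the fraction of clean stacks with
#' no flag at all.
#'
#' @param n_per_type Injections per error type.
#' @param n_clean Clean stacks for specificity.
#' @param seed Master seed.
#' @param config A [synthetic_config()] (biases/noise are irrelevant here;
#'   geometry and magnitudes are used).
#' @param detection A [detection_config()].
#' @return List with `confusion` (data frame injected x detected counts),
#'   `raw` (one row per stack with the injected signed TKV perturbation in
#'   percent, for magnitude calibration), `sensitivity` (named per type),
#'   `specificity`, and `false_positive_rate`.
#' @export
validate_detectors <- function(n_per_type = 200, n_clean = 200, seed = 1L,
                               config = NULL,
                               detection = detection_config()) {
  if (is.null(config)) config <- synthetic_config(seed = seed)
  rates <- config$error_rates
  rows <- list()
  idx <- 0L
  for (ty in ERROR_TYPES) {
    elig <- colnames(rates)[rates[ty, ] > 0]
    probs <- rates[ty, elig] / sum(rates[ty, elig])
    for (i in seq_len(n_per_type)) {
      idx <- idx + 1L
      sq <- with_stream(derive_seed(seed, "valseq", ty, i),
                        elig[sample.int(length(elig), 1, prob = probs)])
      exam <- generate_exam(config, 100000L + idx, sequences = sq,
                            observers = 1L, inject = FALSE)
      st <- exam$stacks[[1]][[sq]]
      clean_ml <- sum(st$mask > 0) * prod(st$pixel_spacing_mm) *
        st$nominal_spacing_mm / 1000
      inj <- inject_error(st, ty,
                          magnitude = config$error_magnitudes[[ty]],
                          seed = derive_seed(seed, "valinj", ty, i))
      cls <- classify_exam_errors(setNames(list(inj$stack), sq), detection)
      detected <- if (length(cls$flags) > 0)
        cls$flags[[1]]$error_type else "NONE"
      rows[[length(rows) + 1L]] <- data.frame(
        injected = ty, sequence = sq, detected = detected,
        injected_pct = 100 * inj$record$expected_dv_ml / clean_ml,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_clean)) {
    idx <- idx + 1L
    sq <- SEQUENCES[(i - 1L) %% length(SEQUENCES) + 1L]
    exam <- generate_exam(config, 100000L + idx, sequences = sq,
                          observers = 1L, inject = FALSE)
    cls <- classify_exam_errors(setNames(list(exam$stacks[[1]][[sq]]), sq),
                                detection)
    detected <- if (length(cls$flags) > 0)
      cls$flags[[1]]$error_type else "NONE"
    rows[[length(rows) + 1L]] <- data.frame(
      injected = "NONE", sequence = sq, detected = detected,
      injected_pct = 0, stringsAsFactors = FALSE)
  }
  conf <- do.call(rbind, rows)
  sens <- vapply(ERROR_TYPES, function(ty) {
    d <- conf[conf$injected == ty, ]
    mean(d$detected == ty)
  }, numeric(1))
  clean <- conf[conf$injected == "NONE", ]
  spec <- mean(clean$detected == "NONE")
  list(confusion = as.data.frame(table(injected = conf$injected,
                                       detected = conf$detected)),
       raw = conf,
       sensitivity = sens, specificity = spec,
       false_positive_rate = 1 - spec)
}
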