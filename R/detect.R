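# Geometric detection of the four acquisition-error types from slice
# geometry and mask morphology. The study this replaces found these errors
# by visual review of orthogonal reformations; here the same signatures are
# quantified: boundary discontinuities between adjacent slices (Dice overlap
# and normalized centroid displacement), exact near-duplicate slice content,
# non-monotone or duplicated recorded slice positions, and kidney masks
# touching the stack or image boundary. All detectors are deterministic and
# never mutate their input.

#' Detection thresholds
#'
#' All thresholds are artifact-defined (the visual review they replace had
#' no quantitative criteria) and are echoed into output metadata.
#'
#' @param discontinuity_threshold Junction score above which a boundary
#'   discontinuity is counted (default 0.35).
#' @param duplicate_dice Minimum Dice for near-duplicate slice content
#'   (default 0.999; injected re-acquisitions are exact copies).
#' @param area_floor Junctions are only scored where both slices hold at
#'   least this fraction of the kidney's peak slice area (default 0.3);
#'   below it, normal apex/base taper mimics discontinuity.
#' @param dominance_factor A single junction is "dominant" (breath-hold
#'   signature) when its score exceeds this multiple of every other score
#'   (default 2).
#' @param position_dup_tol Fraction of the median slice spacing below which
#'   two recorded positions count as duplicates (default 0.25).
#' @param border_contact_min Minimum in-plane border contact (voxels) for an
#'   incomplete-field-of-view flag (default 10).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(discontinuity_threshold = 0.35,
                             duplicate_dice = 0.999,
                             area_floor = 0.3,
                             dominance_factor = 2,
                             position_dup_tol = 0.25,
                             border_contact_min = 10) {
  structure(as.list(environment()), class = "detection_config")
}

qc_flag <- function(error_type, sequence, evidence, affected_slices,
                    correctable) {
  structure(list(error_type = error_type, sequence = sequence,
                 evidence = evidence, affected_slices = affected_slices,
                 correctable = correctable), class = "qc_flag")
}

#' @export
print.qc_flag <- function(x, ...) {
  cat(sprintf("<qc_flag %s on %s (%scorrectable), slices %s>\n",
              x$error_type, x$sequence, if (x$correctable) "" else "not ",
              paste(range(x$affected_slices), collapse = "-")))
  invisible(x)
}

dice_coef <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

#' Per-junction discontinuity profile of a stack
#'
#' For every pair of adjacent slices within each kidney's span (both slices
#' holding at least `area_floor` of that kidney's peak slice area), computes
#' the Dice overlap of the kidney masks and the in-plane centroid
#' displacement normalized by the kidney's equivalent radius. The junction
#' score is the maximum of `1 - Dice` and the normalized displacement;
#' per-junction results are the maximum over the two kidneys.
#'
#' @param stack A binary [slice_stack()].
#' @param config A [detection_config()].
#' @return Data frame with columns `junction` (index i for the pair i, i+1),
#'   `kidney`, `dice`, `displacement`, `score`; zero rows when no kidney.
#' @export
slice_discontinuity_profile <- function(stack, config = detection_config()) {
  lab <- if (isTRUE(attr(stack, "labeled"))) stack else
    suppressWarnings(split_left_right(stack))
  if (isTRUE(attr(lab, "empty")))
    return(data.frame(junction = integer(0), kidney = character(0),
                      dice = numeric(0), displacement = numeric(0),
                      score = numeric(0)))
  out <- list()
  sp <- stack$pixel_spacing_mm
  d3 <- dim(lab$mask)
  for (L in c(1L, 2L)) {
    side <- c("right", "left")[L]
    vox <- which(lab$mask == L) - 1L
    if (length(vox) == 0) next
    vr <- vox %% d3[1]
    vc <- (vox %/% d3[1]) %% d3[2]
    vs <- vox %/% (d3[1] * d3[2])
    counts <- tabulate(vs + 1L, nbins = d3[3])
    # centroids per slice from index arithmetic (no per-slice array scans)
    cents <- matrix(NA_real_, d3[3], 2)
    sums_r <- rowsum(as.numeric(vr), vs)
    sums_c <- rowsum(as.numeric(vc), vs)
    slices_present <- as.integer(rownames(sums_r)) + 1L
    cents[slices_present, 1] <- sums_r[, 1] / counts[slices_present] * sp[1]
    cents[slices_present, 2] <- sums_c[, 1] / counts[slices_present] * sp[2]
    # crop to the kidney's bounding box: Dice is unaffected and the
    # per-junction matrix work shrinks several-fold
    m <- lab$mask[(min(vr):max(vr)) + 1L, (min(vc):max(vc)) + 1L, ,
                  drop = FALSE] == L
    floor_n <- config$area_floor * max(counts)
    for (i in seq_len(length(counts) - 1)) {
      if (counts[i] < floor_n || counts[i + 1] < floor_n) next
      d <- 2 * sum(m[, , i] & m[, , i + 1]) / (counts[i] + counts[i + 1])
      r_eq <- sqrt(max(counts[i], counts[i + 1]) * prod(sp) / pi)
      disp <- sqrt(sum((cents[i, ] - cents[i + 1, ])^2)) / r_eq
      out[[length(out) + 1L]] <- data.frame(
        junction = i, kidney = side, dice = d,
        displacement = disp, score = max(1 - d, min(disp, 1)))
    }
  }
  if (length(out) == 0)
    return(data.frame(junction = integer(0), kidney = character(0),
                      dice = numeric(0), displacement = numeric(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

# Collapse a profile to one score per junction (max over kidneys).
junction_scores <- function(profile) {
  if (nrow(profile) == 0) return(numeric(0))
  tapply(profile$score, profile$junction, max)
}

# Adjacent slice pairs with exactly duplicated kidney content, skipping
# pairs whose recorded positions are themselves (near-)duplicated --
# those belong to composing overlap, not breathing.
near_duplicate_junctions <- function(stack, config) {
  counts <- slice_counts(stack)
  n <- length(counts)
  if (n < 2) return(integer(0))
  med_sp <- effective_spacing(stack)
  hits <- integer(0)
  for (i in seq_len(n - 1)) {
    if (counts[i] == 0 || counts[i] != counts[i + 1]) next
    if (!is.null(stack$positions_mm) &&
        abs(stack$positions_mm[i + 1] - stack$positions_mm[i]) <
          0.5 * med_sp) next
    d <- dice_coef(stack$mask[, , i] > 0, stack$mask[, , i + 1] > 0)
    if (!is.na(d) && d >= config$duplicate_dice) hits <- c(hits, i)
  }
  hits
}

#' Detect breathing-motion slice misregistration
#'
#' Fires when at least two separated junctions exceed the discontinuity
#' threshold (slice subsets acquired at different breathing positions), or
#' when exactly duplicated adjacent slice content appears at non-composed
#' positions. Duplicate junctions are only counted when isolated (their
#' neighbors are not also duplicates): a re-acquired slice duplicates one
#' neighbor, whereas a run of equal slices is the signature of anatomy
#' sampled coarsely across a flat extremum. Never fires on axial T1: a 3D
#' acquisition excites all slices together, so within-stack breathing
#' misregistration cannot occur.
#'
#' @param stack A binary [slice_stack()].
#' @param config A [detection_config()].
#' @param profile Optional precomputed [slice_discontinuity_profile()].
#' @return A `qc_flag` or `NULL`.
#' @export
detect_breathing <- function(stack, config = detection_config(),
                             profile = NULL) {
  if (SEQUENCE_MODE[[stack$sequence]] == "3D") return(NULL)
  if (is.null(profile)) profile <- slice_discontinuity_profile(stack, config)
  js <- junction_scores(profile)
  above <- as.integer(names(js)[js > config$discontinuity_threshold])
  scattered <- length(above) >= 2 && diff(range(above)) >= 2
  dups <- near_duplicate_junctions(stack, config)
  dups <- dups[!((dups - 1L) %in% dups | (dups + 1L) %in% dups)]
  if (!scattered && length(dups) == 0) return(NULL)
  qc_flag("BREATHING_MOTION", stack$sequence,
          evidence = list(junctions = above,
                          junction_scores = unname(js[as.character(above)]),
                          duplicate_junctions = dups,
                          threshold = config$discontinuity_threshold),
          affected_slices = sort(unique(c(above, above + 1L, dups, dups + 1L))),
          correctable = FALSE)
}

#' Detect a breath-hold position mismatch
#'
#' Fires when exactly one interior junction carries a dominant discontinuity
#' (above threshold and more than `dominance_factor` times every other
#' junction score): two internally coherent halves acquired at different
#' breath-hold positions. When the second half's slice areas exactly repeat
#' the areas just before the junction, the duplicated slices are identified
#' and the flag is correctable by deleting them; otherwise content is
#' missing and the flag is exclude-only. Only axial sequences are acquired
#' in multiple breath holds.
#'
#' @inheritParams detect_breathing
#' @return A `qc_flag` or `NULL`.
#' @export
detect_breath_hold_mismatch <- function(stack, config = detection_config(),
                                        profile = NULL) {
  if (SEQUENCE_ORIENTATION[[stack$sequence]] != "axial") return(NULL)
  if (is.null(profile)) profile <- slice_discontinuity_profile(stack, config)
  js <- junction_scores(profile)
  if (length(js) == 0) return(NULL)
  above <- names(js)[js > config$discontinuity_threshold]
  if (length(above) != 1) return(NULL)
  top <- js[[above]]
  others <- js[setdiff(names(js), above)]
  if (length(others) > 0 && top <= config$dominance_factor * max(others))
    return(NULL)
  jn <- as.integer(above)
  q <- jn + 1L                       # second half starts here
  counts <- slice_counts(stack)
  dup_k <- 0L
  for (k in 1:8) {
    if (q - k < 1 || q + k - 1 > length(counts)) break
    m <- 0:(k - 1)
    if (all(counts[q + m] == counts[q - k + m]) && any(counts[q + m] > 0))
      dup_k <- k
  }
  if (dup_k > 0) {
    qc_flag("BREATH_HOLD_MISMATCH", stack$sequence,
            evidence = list(junction = jn, score = top,
                            duplicated_count = dup_k, variant = "duplicate"),
            affected_slices = q:(q + dup_k - 1L), correctable = TRUE)
  } else {
    qc_flag("BREATH_HOLD_MISMATCH", stack$sequence,
            evidence = list(junction = jn, score = top, variant = "missing"),
            affected_slices = c(jn, q), correctable = FALSE)
  }
}

#' Detect composing overlap from recorded slice positions
#'
#' Two overlapping acquisitions composed into one stack leave non-monotone
#' or (near-)duplicated recorded positions; in the overlap the organ volume
#' is double-counted. Pure bookkeeping: no mask content is inspected.
#'
#' @inheritParams detect_breathing
#' @return A `qc_flag`, `NULL`, or the string `"NOT_EVALUABLE"` when the
#'   stack carries no per-slice positions.
#' @export
detect_composing_overlap <- function(stack, config = detection_config()) {
  p <- stack$positions_mm
  if (is.null(p) || length(p) < 2) return("NOT_EVALUABLE")
  dif <- diff(p)
  med <- stats::median(abs(dif))
  bad <- which(dif <= 0 | abs(dif) < config$position_dup_tol * med)
  if (length(bad) == 0) return(NULL)
  involved <- sort(unique(c(bad, bad + 1L)))
  overlap <- range(p[involved])
  qc_flag("COMPOSING_OVERLAP", stack$sequence,
          evidence = list(overlap_range_mm = overlap,
                          first_violation = bad[1],
                          n_violations = length(bad),
                          median_spacing_mm = med),
          affected_slices = involved, correctable = TRUE)
}

#' Detect kidneys not entirely within the field of view
#'
#' Fires when kidney mask is present on the first or last slice of the
#' stack, or touches the in-plane image border with a contact area above
#' `border_contact_min` voxels.
#'
#' @inheritParams detect_breathing
#' @return A `qc_flag` or `NULL`.
#' @export
detect_incomplete_fov <- function(stack, config = detection_config()) {
  counts <- slice_counts(stack)
  n <- length(counts)
  ends <- c(if (counts[1] > 0) 1L, if (counts[n] > 0) n)
  d <- dim(stack$mask)
  border <- sum(stack$mask[1, , ] > 0) + sum(stack$mask[d[1], , ] > 0) +
    sum(stack$mask[, 1, ] > 0) + sum(stack$mask[, d[2], ] > 0)
  if (length(ends) == 0 && border <= config$border_contact_min) return(NULL)
  qc_flag("INCOMPLETE_KIDNEY", stack$sequence,
          evidence = list(truncated_ends = ends,
                          end_slice_areas_mm2 =
                            counts[ends] * prod(stack$pixel_spacing_mm),
                          border_contact_voxels = border),
          affected_slices = if (length(ends)) ends else integer(0),
          correctable = FALSE)
}

#' Run all detectors on every sequence of an exam
#'
#' Applies the four detectors to each stack. When several fire on one
#' sequence, the flag type follows the precedence composing > incomplete >
#' breath-hold > breathing (the bookkeeping signals outrank the
#' morphological ones), with the other firing types retained in the
#' evidence. Multiple sequences of one exam can carry distinct flags.
#'
#' @param stacks Named list of one observer's [slice_stack()]s (one per
#'   sequence).
#' @param config A [detection_config()].
#' @param sequences Sequences to review (default: all present; pass the
#'   sequences of screening-flagged pairs to restrict review to them).
#' @return List with `flags` (list of `qc_flag`) and `not_evaluable`
#'   (data frame sequence x detector of abstentions).
#' @export
classify_exam_errors <- function(stacks, config = detection_config(),
                                 sequences = names(stacks)) {
  flags <- list()
  ne <- list()
  for (sq in sequences) {
    st <- stacks[[sq]]
    if (is.null(st)) next
    profile <- slice_discontinuity_profile(st, config)
    res <- list(
      COMPOSING_OVERLAP = detect_composing_overlap(st, config),
      INCOMPLETE_KIDNEY = detect_incomplete_fov(st, config),
      BREATH_HOLD_MISMATCH = detect_breath_hold_mismatch(st, config, profile),
      BREATHING_MOTION = detect_breathing(st, config, profile)
    )
    for (d in names(res)) {
      if (identical(res[[d]], "NOT_EVALUABLE")) {
        ne[[length(ne) + 1L]] <- data.frame(sequence = sq, detector = d)
        res[[d]] <- NULL
      }
    }
    fired <- Filter(Negate(is.null), res)
    if (length(fired) == 0) next
    primary <- fired[[1]]
    if (length(fired) > 1)
      primary$evidence$also_detected <- names(fired)[-1]
    flags[[length(flags) + 1L]] <- primary
  }
  list(flags = flags,
       not_evaluable = if (length(ne)) do.call(rbind, ne) else
         data.frame(sequence = character(0), detector = character(0)))
}
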