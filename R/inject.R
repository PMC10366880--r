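# Injection of the four acquisition-error types into clean stacks.
#
# Each injection is split into a *plan* (drawn from an RNG stream using the
# clean stack's slice-area profile, with an exactly bookkept expected TKV
# perturbation) and a deterministic *application*, so the same acquisition
# error can be imposed on every observer variant of a sequence.
#
# Signed magnitudes are sampled so that the median perturbation per type
# matches the observed medians; the achieved perturbation is then realized
# by choosing slices whose summed area x spacing best approximates the
# sampled target (granularity is one flank slice, well under 1 percent of
# TKV at default resolution).

error_eligible <- function(error_type, sequence) {
  switch(error_type,
    BREATHING_MOTION = SEQUENCE_MODE[[sequence]] == "2D",
    BREATH_HOLD_MISMATCH = SEQUENCE_ORIENTATION[[sequence]] == "axial",
    COMPOSING_OVERLAP = SEQUENCE_ORIENTATION[[sequence]] == "axial",
    INCOMPLETE_KIDNEY = sequence == "AX_T1",
    stop("unknown error type: ", error_type))
}

# Allowed row-shift range so shifted content never leaves the grid.
row_shift_bounds <- function(stack) {
  any_fg <- apply(stack$mask > 0, 1, any)
  rows <- which(any_fg)
  if (length(rows) == 0) return(c(0L, 0L))
  c(-(min(rows) - 1L), nrow(stack$mask[, , 1]) - max(rows))
}

# Equivalent pixel radius of the larger kidney at peak area, along rows.
equiv_radius_px <- function(stack) {
  lab <- suppressWarnings(split_left_right(stack))
  a_max <- max(slice_counts(lab, 1L), slice_counts(lab, 2L), 1L)
  sqrt(a_max * prod(stack$pixel_spacing_mm) / pi) / stack$pixel_spacing_mm[1]
}

# Draw a junction shift (integer rows) in [0.5, 0.75] local radii,
# clipped to the available margin.
draw_shift <- function(r_px, lo_margin, hi_margin) {
  mag <- round(runif(1, 0.5, 0.75) * r_px)
  dir <- sample(c(-1L, 1L), 1)
  s <- dir * mag
  # stay 5 px clear of the image border: a shift that parks the kidney on
  # the edge would mimic an incomplete field of view
  lo <- min(lo_margin + 5L, 0L)
  hi <- max(hi_margin - 5L, 0L)
  max(min(s, hi), lo)
}

target_median <- function(params, sequence) {
  mp <- params$median_pct
  if (length(mp) > 1 || !is.null(names(mp))) {
    if (!sequence %in% names(mp))
      stop("no magnitude median configured for sequence ", sequence)
    mp <- mp[[sequence]]
  }
  mp
}

# ---- plans -----------------------------------------------------------------

plan_breathing <- function(stack, params) {
  t <- stack$nominal_spacing_mm
  areas <- slice_areas(stack)
  v_ml <- sum(areas) * t / 1000
  d <- sample_signed_pct(target_median(params, stack$sequence),
                         params$sigma, params$p_major)
  dv <- abs(d) / 100 * v_ml
  a_max <- max(areas)
  pickable <- which(areas >= 0.05 * a_max)
  pickable <- pickable[pickable > 1 & pickable < length(areas)]
  # random picks until one more slice would close the gap, then take the
  # unpicked slice whose area best matches the remaining deficit
  sel <- integer(0); cum <- 0
  for (i in sample_safe(pickable)) {
    gap <- dv - cum
    if (gap <= max(areas[setdiff(pickable, sel)]) * t / 1000) break
    sel <- c(sel, i); cum <- cum + areas[i] * t / 1000
  }
  rest <- setdiff(pickable, sel)
  if (length(rest) > 0 && dv - cum > 0) {
    best <- rest[which.min(abs(areas[rest] * t / 1000 - (dv - cum)))]
    if (abs(areas[best] * t / 1000 - (dv - cum)) < dv - cum) {
      sel <- c(sel, best); cum <- cum + areas[best] * t / 1000
    }
  }
  if (length(sel) == 0) {   # tiny target: closest single slice
    best <- pickable[which.min(abs(areas[pickable] * t / 1000 - dv))]
    sel <- best; cum <- areas[best] * t / 1000
  }
  sel <- sort(sel)
  # in-plane shift segments: 3 scattered junctions -> 4 segments
  core <- which(areas >= 0.35 * a_max)
  core <- core[core > 2 & core < length(areas) - 1]
  jn <- integer(0)
  cand <- core
  while (length(jn) < 3 && length(cand) > 0) {
    j <- sample_safe(cand, 1)
    jn <- sort(c(jn, j))
    cand <- cand[abs(cand - j) >= 3]   # keep junctions separated
  }
  r_px <- equiv_radius_px(stack)
  bounds <- row_shift_bounds(stack)
  shifts <- c(0L)
  for (q in seq_along(jn)) {
    prev <- shifts[length(shifts)]
    dlt <- draw_shift(r_px, bounds[1] - min(0, prev), bounds[2] - max(0, prev))
    # alternate away from the previous shift so consecutive segments differ
    shifts <- c(shifts, prev + if (q %% 2 == 1) dlt else -dlt)
  }
  shifts <- pmin(pmax(shifts, min(bounds[1] + 5L, 0L)),
                 max(bounds[2] - 5L, 0L))
  list(type = "BREATHING_MOTION",
       action = if (d >= 0) "duplicate" else "remove",
       slices = sel,
       junctions = jn, segment_shifts = shifts,
       target_pct = d,
       expected_dv_ml = if (d >= 0) cum else -cum)
}

plan_breath_hold <- function(stack, params) {
  t <- stack$nominal_spacing_mm
  areas <- slice_areas(stack)
  counts <- slice_counts(stack)
  v_ml <- sum(areas) * t / 1000
  d <- sample_signed_pct(target_median(params, stack$sequence),
                         params$sigma, params$p_major)
  dv <- abs(d) / 100 * v_ml
  a_max <- max(areas)
  core <- which(areas >= 0.35 * a_max)
  n <- length(areas)
  best <- NULL; best_err <- Inf
  for (k in 1:6) {
    for (q in core) {
      # both faces of the junction must stay in the kidney core after the
      # shift, or the discontinuity falls into the apex/base taper
      if (!((q - 1) %in% core)) next
      if (d >= 0) {
        if (q - k < 2 || !((q - k) %in% core)) next
        ach <- sum(areas[(q - k):(q - 1)]) * t / 1000
      } else {
        if (q + k > n - 1 || !((q + k) %in% core)) next
        ach <- sum(areas[q:(q + k - 1)]) * t / 1000
      }
      if (abs(ach - dv) < best_err) {
        best_err <- abs(ach - dv)
        best <- list(q = q, k = k, ach = ach)
      }
    }
  }
  if (is.null(best)) stop("no feasible breath-hold junction in stack")
  r_px <- equiv_radius_px(stack)
  bounds <- row_shift_bounds(stack)
  dlt <- draw_shift(r_px, bounds[1], bounds[2])
  list(type = "BREATH_HOLD_MISMATCH",
       action = if (d >= 0) "duplicate" else "missing",
       second_half_start = best$q, k = best$k,
       row_shift = dlt, col_shift = sample(c(-2L, -1L, 1L, 2L), 1),
       target_pct = d,
       expected_dv_ml = if (d >= 0) best$ach else -best$ach)
}

plan_composing <- function(stack, params) {
  t <- stack$nominal_spacing_mm
  areas <- slice_areas(stack)
  v_ml <- sum(areas) * t / 1000
  d <- abs(sample_signed_pct(target_median(params, stack$sequence),
                             params$sigma, params$p_major))
  dv <- d / 100 * v_ml
  a_max <- max(areas)
  core <- which(areas >= 0.35 * a_max)
  best <- NULL; best_err <- Inf
  for (k in 1:8) {
    for (m in core) {
      if (m - k + 1 < 2 || m >= length(areas)) next
      ach <- sum(areas[(m - k + 1):m]) * t / 1000
      if (abs(ach - dv) < best_err) {
        best_err <- abs(ach - dv)
        best <- list(m = m, k = k, ach = ach)
      }
    }
  }
  if (is.null(best)) stop("no feasible composing seam in stack")
  list(type = "COMPOSING_OVERLAP",
       seam = best$m, k = best$k,
       col_shift = sample(c(-2L, -1L, 1L, 2L), 1),
       target_pct = d, expected_dv_ml = best$ach)
}

plan_incomplete <- function(stack, params) {
  t <- stack$nominal_spacing_mm
  areas <- slice_areas(stack)
  v_ml <- sum(areas) * t / 1000
  d <- -abs(sample_signed_pct(target_median(params, stack$sequence),
                              params$sigma, params$p_major))
  dv <- abs(d) / 100 * v_ml
  n <- length(areas)
  end <- sample(c("first", "last"), 1)
  a <- if (end == "last") rev(areas) else areas
  cum <- cumsum(a) * t / 1000
  k <- which(cum >= dv)[1]
  if (is.na(k)) k <- n - 1L
  if (k > 1 && abs(cum[k - 1] - dv) < abs(cum[k] - dv)) k <- k - 1L
  span <- kidney_span(stack)
  empty_end <- if (end == "last") n - max(span) else min(span) - 1L
  # crop at least one kidney-bearing slice, but never the whole kidney
  k <- min(max(k, empty_end + 1L), empty_end + length(span) - 3L)
  crop <- if (end == "last") (n - k + 1L):n else 1L:k
  ach <- sum(areas[crop]) * t / 1000
  list(type = "INCOMPLETE_KIDNEY", end = end, crop = crop,
       target_pct = d, expected_dv_ml = -ach)
}

plan_error <- function(stack, error_type, params) {
  switch(error_type,
    BREATHING_MOTION = plan_breathing(stack, params),
    BREATH_HOLD_MISMATCH = plan_breath_hold(stack, params),
    COMPOSING_OVERLAP = plan_composing(stack, params),
    INCOMPLETE_KIDNEY = plan_incomplete(stack, params),
    stop("unknown error type: ", error_type))
}

# ---- application -----------------------------------------------------------

apply_segment_shifts <- function(mask, junctions, shifts) {
  n <- dim(mask)[3]
  bounds <- c(0L, junctions, n)
  for (s in seq_along(shifts)) {
    if (shifts[s] == 0L) next
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    for (i in idx) mask[, , i] <- shift_slice(mask[, , i], d_row = shifts[s])
  }
  mask
}

apply_breathing <- function(stack, plan) {
  mask <- apply_segment_shifts(stack$mask, plan$junctions, plan$segment_shifts)
  n <- dim(mask)[3]
  if (plan$action == "duplicate") {
    order_idx <- sort(c(seq_len(n), plan$slices))
  } else {
    order_idx <- setdiff(seq_len(n), plan$slices)
  }
  out <- replace_mask(stack, mask[, , order_idx, drop = FALSE])
  reindex_positions(out)
}

apply_breath_hold <- function(stack, plan) {
  n <- n_slices(stack)
  q <- plan$second_half_start; k <- plan$k
  src <- if (plan$action == "duplicate") {
    c(seq_len(q - 1L), pmax(1L, seq(q, n) - k))
  } else {
    c(seq_len(q - 1L), pmin(n, seq(q, n) + k))
  }
  mask <- stack$mask[, , src, drop = FALSE]
  if (plan$action == "missing") {
    # slices sampled beyond the grid are empty (kidney has end margin)
    beyond <- which(seq(q, n) + k > n) + q - 1L
    if (length(beyond)) mask[, , beyond] <- 0L
  }
  # second breath-hold at a different position: shift its content in-plane
  for (i in q:n)
    mask[, , i] <- shift_slice(mask[, , i], d_row = plan$row_shift,
                               d_col = plan$col_shift)
  replace_mask(stack, mask)
}

apply_composing <- function(stack, plan) {
  n <- n_slices(stack)
  m <- plan$seam; k <- plan$k
  dup <- (m - k + 1L):m
  pos <- stack$positions_mm %||% ((seq_len(n) - 1) * stack$nominal_spacing_mm)
  copies <- stack$mask[, , dup, drop = FALSE]
  for (j in seq_len(k))
    copies[, , j] <- shift_slice(copies[, , j], d_col = plan$col_shift)
  new_mask <- array(0L, dim(stack$mask) + c(0, 0, k))
  new_mask[, , seq_len(m)] <- stack$mask[, , seq_len(m)]
  new_mask[, , m + seq_len(k)] <- copies
  if (m < n) new_mask[, , (m + k + 1L):(n + k)] <- stack$mask[, , (m + 1L):n]
  new_pos <- c(pos[seq_len(m)], pos[dup], if (m < n) pos[(m + 1L):n])
  replace_mask(stack, new_mask, positions_mm = new_pos)
}

apply_incomplete <- function(stack, plan) {
  keep <- setdiff(seq_len(n_slices(stack)), plan$crop)
  out <- subset_slices(stack, keep)
  reindex_positions(out)
}

apply_error_plan <- function(stack, plan) {
  switch(plan$type,
    BREATHING_MOTION = apply_breathing(stack, plan),
    BREATH_HOLD_MISMATCH = apply_breath_hold(stack, plan),
    COMPOSING_OVERLAP = apply_composing(stack, plan),
    INCOMPLETE_KIDNEY = apply_incomplete(stack, plan))
}

#' Inject an acquisition error into a slice stack
#'
#' Perturbs a clean stack with one of the four geometric acquisition-error
#' types: breathing-motion slice misregistration (duplicated or removed
#' interior slices plus in-plane shifts of slice subsets), breath-hold
#' position mismatch (the stack split at one interior junction with the
#' second half's anatomy shifted along the normal, duplicating or skipping
#' anatomical content), composing overlap (a contiguous position range
#' re-acquired and appended so recorded positions overlap), or incomplete
#' field of view (kidney-bearing slices cropped from one end).
#'
#' @param stack A clean binary [slice_stack()].
#' @param error_type One of [tkv_error_types()].
#' @param magnitude Magnitude distribution parameters (list with
#'   `median_pct`, `sigma`, `p_major`); defaults per
#'   [default_error_magnitudes()]. Use `magnitude = 0` for an explicit
#'   no-op (returns the stack unchanged, flagged as such).
#' @param seed Integer seed for the injection stream.
#' @param check_eligibility Refuse error types that cannot occur in this
#'   stack's sequence (default `TRUE`).
#' @return List with `stack` (the perturbed stack) and `record`: the truth
#'   entry (type, action, affected slices, target and exactly-bookkept
#'   expected signed TKV perturbation in mL).
#' @export
inject_error <- function(stack, error_type, magnitude = NULL, seed = 1L,
                         check_eligibility = TRUE) {
  error_type <- match.arg(error_type, ERROR_TYPES)
  if (check_eligibility && !error_eligible(error_type, stack$sequence))
    stop(sprintf("%s is not eligible for sequence %s", error_type,
                 stack$sequence))
  if (!is.null(magnitude) && identical(magnitude, 0)) {
    return(list(stack = stack,
                record = list(type = error_type, action = "noop",
                              target_pct = 0, expected_dv_ml = 0)))
  }
  if (is.null(magnitude))
    magnitude <- default_error_magnitudes()[[error_type]]
  plan <- with_stream(derive_seed(seed, "inject", error_type, stack$sequence),
                      plan_error(stack, error_type, magnitude))
  list(stack = apply_error_plan(stack, plan), record = plan)
}
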