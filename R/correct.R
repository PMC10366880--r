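# Repairs for correctable acquisition errors. Two operations exist:
# deleting duplicated slices (breath-hold re-acquisitions) and recomposing
# an overlapping composed stack by position sorting and duplicate-position
# collapse. Breathing misregistration and truncated kidneys cannot be
# repaired from masks alone; those sequences are excluded from the
# reference instead. Corrected volumes are always recomputed through the
# volumetry path, never adjusted arithmetically.

#' Percent change of a corrected volume relative to pre-correction
#'
#' `100 * (before - after) / before`.
#'
#' @param before_ml,after_ml Volumes in mL.
#' @return Percent change.
#' @export
correction_pct_change <- function(before_ml, after_ml) {
  100 * (before_ml - after_ml) / before_ml
}

#' Delete duplicated slices from a stack
#'
#' Removes the given duplicate slices (the later re-acquisition; the first
#' occurrence of the content is retained), re-indexes positions to a regular
#' grid, and leaves volume recomputation to [compute_volumes()]. Refuses to
#' act when deletion would remove every kidney-bearing slice.
#'
#' @param stack A [slice_stack()].
#' @param duplicate_indices Integer slice indices identified as duplicated
#'   content (e.g. from [detect_breath_hold_mismatch()] evidence).
#' @return The corrected stack.
#' @export
delete_duplicate_slices <- function(stack, duplicate_indices) {
  if (length(duplicate_indices) == 0) return(stack)
  keep <- setdiff(seq_len(n_slices(stack)), duplicate_indices)
  if (length(keep) == 0 || !any(slice_counts(subset_slices(stack, keep)) > 0))
    stop("deleting these slices would empty the kidney span; exclude instead")
  reindex_positions(subset_slices(stack, keep))
}

#' Recompose a stack with overlapping acquisitions
#'
#' Sorts slices by recorded position, collapses groups of near-duplicate
#' positions (within `position_dup_tol` x median spacing) keeping the
#' earlier acquisition's slice (the middle one, with a warning, when three
#' positions coincide), and keeps the surviving recorded positions so the
#' effective spacing used by [compute_volumes()] is re-derived from actually
#' recorded positions.
#'
#' @param stack A [slice_stack()] with per-slice positions.
#' @param config A [detection_config()] (for the duplicate tolerance).
#' @return The corrected stack.
#' @export
recompose_stack <- function(stack, config = detection_config()) {
  p <- stack$positions_mm
  if (is.null(p)) stop("recompose requires per-slice positions")
  ord <- order(p)                       # stable: acquisition order kept
  p_s <- p[ord]
  df <- diff(p_s)
  # spacing from the distinct positions: with heavy duplication the plain
  # median of differences degenerates to zero
  pos_df <- df[df > 1e-9]
  if (length(pos_df) == 0) stop("all slice positions coincide")
  tol <- config$position_dup_tol * stats::median(pos_df)
  groups <- cumsum(c(TRUE, df >= tol))
  keep <- integer(0)
  for (g in unique(groups)) {
    members <- ord[groups == g]
    if (length(members) >= 3) {
      warning("three or more slices within position tolerance; keeping the middle one")
      members_sorted <- sort(members)
      keep <- c(keep, members_sorted[ceiling(length(members) / 2)])
    } else {
      keep <- c(keep, min(members))     # earlier acquisition wins
    }
  }
  keep <- keep[order(p[keep])]
  subset_slices(stack, keep)
}

#' Apply corrections for classified flags to an exam
#'
#' Policy: composing overlap is recomposed; a breath-hold mismatch with
#' identified duplicate slices has them deleted; breathing motion,
#' incomplete kidneys, missing-content breath-holds and unexplained
#' outliers are not corrected and their sequences are excluded from the
#' reference. Volumes before/after are recomputed through [tkv()].
#'
#' @param stacks Either one observer's named list of [slice_stack()]s or a
#'   nested list `[[observer]][[sequence]]`.
#' @param flags List of `qc_flag` objects from [classify_exam_errors()].
#' @param config A [detection_config()].
#' @return List with `stacks` (same shape, corrected), `records` (data
#'   frame: one row per flag x observer with action, slices removed,
#'   spacing and TKV before/after, percent change) and `excluded`
#'   (sequences left uncorrectable).
#' @export
apply_corrections <- function(stacks, flags, config = detection_config()) {
  nested <- !inherits(stacks[[1]], "slice_stack")
  if (!nested) stacks <- list(stacks)
  records <- list()
  excluded <- character(0)
  for (fl in flags) {
    sq <- fl$sequence
    action <- if (fl$error_type == "COMPOSING_OVERLAP") "RECOMPOSE"
      else if (fl$error_type == "BREATH_HOLD_MISMATCH" && fl$correctable)
        "DELETE_DUPLICATES"
      else "NONE"
    if (action == "NONE") excluded <- c(excluded, sq)
    for (obs in seq_along(stacks)) {
      st <- stacks[[obs]][[sq]]
      if (is.null(st)) next
      before <- tkv(st)
      st_new <- switch(action,
        RECOMPOSE = recompose_stack(st, config),
        DELETE_DUPLICATES = delete_duplicate_slices(st, fl$affected_slices),
        NONE = st)
      after <- tkv(st_new)
      records[[length(records) + 1L]] <- data.frame(
        sequence = sq, observer = obs, error_type = fl$error_type,
        action = action,
        n_slices_removed = n_slices(st) - n_slices(st_new),
        spacing_before_mm = effective_spacing(st),
        spacing_after_mm = effective_spacing(st_new),
        tkv_before_ml = before$total_ml, tkv_after_ml = after$total_ml,
        pct_change = correction_pct_change(before$total_ml, after$total_ml),
        stringsAsFactors = FALSE)
      stacks[[obs]][[sq]] <- st_new
    }
  }
  records <- if (length(records)) do.call(rbind, records) else data.frame(
    sequence = character(0), observer = integer(0), error_type = character(0),
    action = character(0), n_slices_removed = integer(0),
    spacing_before_mm = numeric(0), spacing_after_mm = numeric(0),
    tkv_before_ml = numeric(0), tkv_after_ml = numeric(0),
    pct_change = numeric(0))
  list(stacks = if (nested) stacks else stacks[[1]],
       records = records, excluded = unique(excluded))
}
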