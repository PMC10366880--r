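# Volumetry: connected-component cleanup, right/left assignment, and the
# voxel-count x in-plane-area x slice-spacing volume rule.

# Label 3D connected components (26-connectivity). Returns an integer array
# of component ids plus sizes, in deterministic raster-scan order.
label_components <- function(mask) {
  d <- dim(mask)
  storage.mode(mask) <- "integer"
  lab <- label_components_cpp(mask, as.integer(d))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = d)
  sizes <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(labels = lab, sizes = sizes, n = n)
}

# mm coordinate along the left-right axis of every voxel of a component.
component_lr_centroid <- function(stack, labels, id) {
  idx <- which(labels == id) - 1L
  d <- dim(labels)
  ax <- if (stack$lr_axis == "col") 2L else 1L
  coord <- if (ax == 1L) idx %% d[1] else (idx %/% d[1]) %% d[2]
  sp <- stack$pixel_spacing_mm[ax]
  org <- stack$origin_mm[ax]
  mean(org + coord * sp) * stack$lr_sign
}

#' Separate right and left kidney in a binary mask stack
#'
#' Computes 3D connected components (26-connectivity), keeps the two largest,
#' discards everything else as stray labeling, and assigns the kept
#' components to the right/left kidney by the centroid coordinate along the
#' patient left-right axis. When only one component exists (e.g. fused or
#' touching kidneys) the stack is split at the image mid-plane along the
#' left-right axis, with mid-plane voxels assigned to the side of their
#' row-wise centroid.
#'
#' @param stack A binary [slice_stack()].
#' @return The stack with `mask` relabeled 0 = background, 1 = right kidney,
#'   2 = left kidney, and attribute `"n_stray_voxels"` counting removed
#'   voxels. An empty mask is returned unchanged with attribute
#'   `"empty" = TRUE` and a warning.
#' @export
split_left_right <- function(stack) {
  cc <- label_components(stack$mask)
  if (cc$n == 0L) {
    warning("empty mask: no kidney voxels found")
    out <- replace_mask(stack, array(0L, dim(stack$mask)))
    attr(out, "empty") <- TRUE
    attr(out, "n_stray_voxels") <- 0L
    return(out)
  }
  new <- array(0L, dim(stack$mask))
  if (cc$n == 1L) {
    # Single component: mid-plane split (legacy rule for fused kidneys).
    ax <- if (stack$lr_axis == "col") 2L else 1L
    mid <- (dim(stack$mask)[ax] + 1) / 2
    idx <- which(cc$labels == 1L, arr.ind = TRUE)
    coord <- idx[, ax]
    side <- ifelse(coord < mid, 1L, ifelse(coord > mid, 2L, NA_integer_))
    if (anyNA(side)) {
      # voxels exactly on the mid-plane follow their row-wise centroid
      other <- if (ax == 2L) 1L else 2L
      key <- interaction(idx[, other], idx[, 3], drop = TRUE)
      cent <- tapply(coord, key, mean)
      side[is.na(side)] <- ifelse(cent[as.character(key[is.na(side)])] < mid,
                                  1L, 2L)
    }
    if (stack$lr_sign < 0) side <- 3L - side
    new[idx] <- side
    stray <- 0L
  } else {
    # Two largest components; ties broken by lower component id, i.e. by
    # raster-scan discovery order, which is deterministic.
    ord <- order(-cc$sizes, seq_along(cc$sizes))
    keep <- ord[1:2]
    cents <- vapply(keep, function(id)
      component_lr_centroid(stack, cc$labels, id), numeric(1))
    right_id <- keep[which.min(cents)]  # patient-right = smaller L-R coord
    left_id <- setdiff(keep, right_id)
    new[cc$labels == right_id] <- 1L
    new[cc$labels == left_id] <- 2L
    stray <- sum(cc$sizes) - sum(cc$sizes[keep])
  }
  out <- replace_mask(stack, new)
  attr(out, "n_stray_voxels") <- as.integer(stray)
  attr(out, "labeled") <- TRUE
  out
}

#' Compute kidney volumes from a labeled stack
#'
#' Volume of each kidney is the product of its voxel count, the in-plane
#' pixel area and the slice spacing, divided by 1000 to give millilitres.
#' Slice spacing is the stack's [effective_spacing()]: the median consecutive
#' position difference when per-slice positions are recorded, else the
#' nominal spacing.
#'
#' @param stack A [slice_stack()] with labels in `{0, 1 (right), 2 (left)}`;
#'   a plain binary stack is passed through [split_left_right()] first.
#' @return An object of class `kidney_volumes`: list with `right_ml`,
#'   `left_ml`, `total_ml`, `voxel_counts`, `effective_spacing_mm`, and
#'   `empty` flag.
#' @export
compute_volumes <- function(stack) {
  sp <- effective_spacing(stack)
  if (!is.finite(sp) || sp <= 0) stop("non-positive slice spacing")
  if (any(stack$mask > 2L)) stop("labels must be in {0, 1, 2}")
  px_area <- prod(stack$pixel_spacing_mm)
  cnt <- tabulate(stack$mask, nbins = 2L)
  n_right <- cnt[1]
  n_left <- cnt[2]
  empty <- (n_right + n_left) == 0L
  if (empty) warning("empty mask: volumes are zero")
  right <- n_right * px_area * sp / 1000
  left <- n_left * px_area * sp / 1000
  structure(list(
    right_ml = right, left_ml = left, total_ml = right + left,
    voxel_counts = c(right = n_right, left = n_left),
    effective_spacing_mm = sp, empty = empty
  ), class = "kidney_volumes")
}

#' @export
print.kidney_volumes <- function(x, ...) {
  cat(sprintf("<kidney_volumes right %.1f mL, left %.1f mL, total %.1f mL (spacing %.3g mm)>\n",
              x$right_ml, x$left_ml, x$total_ml, x$effective_spacing_mm))
  invisible(x)
}

#' Total kidney volume of a binary stack
#'
#' Convenience wrapper: [split_left_right()] then [compute_volumes()].
#'
#' @param stack A binary [slice_stack()].
#' @return A `kidney_volumes` object.
#' @export
tkv <- function(stack) {
  compute_volumes(split_left_right(stack))
}

#' Height-adjusted total kidney volume
#'
#' @param total_ml Total kidney volume in mL.
#' @param height_m Patient height in meters.
#' @return ht-TKV in mL/m; `NA` (not zero) when height is missing.
#' @export
ht_tkv <- function(total_ml, height_m) {
  if (is.null(height_m) || length(height_m) == 0 || is.na(height_m))
    return(NA_real_)
  if (height_m <= 0) stop("height must be positive")
  total_ml / height_m
}
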