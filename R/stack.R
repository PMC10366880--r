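#' Construct a slice stack
#'
#' The unit of data every detector and corrector operates on: an ordered set
#' of 2D binary (or right/left-labeled) mask slices plus the geometry needed
#' to turn voxel counts into millilitres. Array axes are `[row, col, slice]`.
#' For axial stacks rows run anterior-posterior, columns left-right and
#' slices inferior-superior; for coronal stacks rows run inferior-superior,
#' columns left-right and slices anterior-posterior. In both cases the
#' patient left-right axis is the column axis, with patient-left at larger
#' column coordinate.
#'
#' @param mask 3D integer or logical array `[row, col, slice]`; 0 background,
#'   1 foreground (or 1 = right kidney, 2 = left kidney after labeling).
#' @param positions_mm Numeric vector of per-slice coordinates along the
#'   stack normal (mm), one per slice, or `NULL` when unknown.
#' @param pixel_spacing_mm Length-2 numeric, in-plane (row, col) spacing in mm.
#' @param nominal_spacing_mm Recorded slice spacing in mm.
#' @param orientation `"axial"` or `"coronal"`.
#' @param sequence One of [tkv_sequences()].
#' @param origin_mm Length-2 numeric, mm coordinate of the first row/col
#'   voxel center (used for centroids in patient coordinates).
#' @param lr_axis In-plane axis corresponding to patient left-right
#'   (`"col"` by convention here).
#' @param lr_sign +1 if patient-left lies at increasing coordinate.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(mask, positions_mm = NULL, pixel_spacing_mm,
                        nominal_spacing_mm, orientation, sequence,
                        origin_mm = c(0, 0), lr_axis = "col", lr_sign = 1) {
  stopifnot(length(dim(mask)) == 3L)
  if (is.logical(mask)) mask <- array(as.integer(mask), dim = dim(mask))
  storage.mode(mask) <- "integer"
  if (!is.null(positions_mm) && length(positions_mm) != dim(mask)[3])
    stop("positions_mm must have one entry per slice")
  stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0),
            nominal_spacing_mm > 0)
  orientation <- match.arg(orientation, c("axial", "coronal"))
  sequence <- match.arg(sequence, SEQUENCES)
  lr_axis <- match.arg(lr_axis, c("row", "col"))
  structure(list(
    mask = mask,
    positions_mm = positions_mm,
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    nominal_spacing_mm = as.numeric(nominal_spacing_mm),
    orientation = orientation,
    sequence = sequence,
    origin_mm = as.numeric(origin_mm),
    lr_axis = lr_axis,
    lr_sign = lr_sign
  ), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<slice_stack %s (%s), %d x %d x %d, px %.3g x %.3g mm, slice %.3g mm, %d fg voxels>\n",
    x$sequence, x$orientation, d[1], d[2], d[3],
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    effective_spacing(x), sum(x$mask > 0)))
  invisible(x)
}

n_slices <- function(stack) dim(stack$mask)[3]

#' Effective slice spacing of a stack
#'
#' Median absolute difference of consecutive recorded slice positions when
#' positions are available, else the recorded nominal spacing. The median is
#' robust to the position jumps left by composing overlaps, which is what
#' re-deriving the thickness from actually recorded positions is for.
#'
#' @param stack A [slice_stack()].
#' @return Spacing in mm.
#' @export
effective_spacing <- function(stack) {
  p <- stack$positions_mm
  if (!is.null(p) && length(p) >= 2) {
    s <- stats::median(abs(diff(p)))
    if (is.finite(s) && s > 0) return(s)
  }
  stack$nominal_spacing_mm
}

# Per-slice foreground voxel counts (all labels pooled or a single label).
slice_counts <- function(stack, label = NULL) {
  m <- stack$mask
  if (is.null(label)) {
    as.integer(colSums(m > 0L, dims = 2L))
  } else {
    as.integer(colSums(m == label, dims = 2L))
  }
}

# Per-slice foreground area in mm^2.
slice_areas <- function(stack, label = NULL) {
  slice_counts(stack, label) * prod(stack$pixel_spacing_mm)
}

# Indices of slices containing any foreground.
kidney_span <- function(stack) which(slice_counts(stack) > 0)

# Translate slice content by integer pixels along rows/cols, zero-filling.
shift_slice <- function(sl, d_row = 0L, d_col = 0L) {
  nr <- nrow(sl); nc <- ncol(sl)
  out <- matrix(0L, nr, nc)
  src_r <- seq_len(nr) - d_row
  src_c <- seq_len(nc) - d_col
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- sl[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Replace the mask of a stack, keeping geometry; optionally new positions.
replace_mask <- function(stack, mask, positions_mm = stack$positions_mm) {
  storage.mode(mask) <- "integer"
  stack$mask <- mask
  stack$positions_mm <- positions_mm
  stack
}

# Subset slices of a stack (keeps recorded positions of the kept slices).
subset_slices <- function(stack, idx) {
  stack$mask <- stack$mask[, , idx, drop = FALSE]
  if (!is.null(stack$positions_mm))
    stack$positions_mm <- stack$positions_mm[idx]
  stack
}

# Uniformly re-indexed positions after slice insertion/removal: the scanner
# is assumed to have recorded a regular grid of the new length.
reindex_positions <- function(stack) {
  n <- n_slices(stack)
  t <- stack$nominal_spacing_mm
  p0 <- if (!is.null(stack$positions_mm)) stack$positions_mm[1] else 0
  stack$positions_mm <- p0 + (seq_len(n) - 1) * t
  stack
}
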