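# NIfTI input/output. Masks are written as uint8 NIfTI volumes with the
# voxel spacing in pixdim; geometry that NIfTI cannot carry faithfully for
# irregular stacks (per-slice positions along the normal, sequence label,
# orientation, left-right axis convention) goes into a JSON sidecar next to
# each volume.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a slice stack as NIfTI plus JSON sidecar
#'
#' @param stack A [slice_stack()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_stack_nifti <- function(stack, path) {
  img <- RNifti::asNifti(stack$mask)
  RNifti::pixdim(img) <- c(stack$pixel_spacing_mm, effective_spacing(stack))
  RNifti::writeNifti(img, path, datatype = "uint8")
  meta <- list(
    sequence = stack$sequence,
    orientation = stack$orientation,
    positions_mm = stack$positions_mm,
    pixel_spacing_mm = stack$pixel_spacing_mm,
    nominal_spacing_mm = stack$nominal_spacing_mm,
    origin_mm = stack$origin_mm,
    lr_axis = stack$lr_axis,
    lr_sign = stack$lr_sign
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a slice stack from NIfTI (with optional JSON sidecar)
#'
#' Without a sidecar, spacing is taken from pixdim, positions are assumed
#' regular, and `sequence`/`orientation` must be supplied.
#'
#' @param path NIfTI path.
#' @param sequence,orientation Used when no sidecar is present.
#' @return A [slice_stack()].
#' @export
read_stack_nifti <- function(path, sequence = NULL, orientation = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(img > 0), dim = dim(img))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    slice_stack(arr, positions_mm = meta$positions_mm,
                pixel_spacing_mm = meta$pixel_spacing_mm,
                nominal_spacing_mm = meta$nominal_spacing_mm,
                orientation = meta$orientation, sequence = meta$sequence,
                origin_mm = meta$origin_mm %||% c(0, 0),
                lr_axis = meta$lr_axis %||% "col",
                lr_sign = meta$lr_sign %||% 1)
  } else {
    pd <- RNifti::pixdim(img)
    if (is.null(sequence)) stop("no sidecar: sequence must be given")
    if (is.null(orientation))
      orientation <- SEQUENCE_ORIENTATION[[sequence]]
    slice_stack(arr, positions_mm = (seq_len(dim(arr)[3]) - 1) * pd[3],
                pixel_spacing_mm = pd[1:2], nominal_spacing_mm = pd[3],
                orientation = orientation, sequence = sequence)
  }
}

# Write all stacks of a generated exam under out_dir.
write_exam_nifti <- function(exam, out_dir) {
  for (obs in seq_along(exam$stacks)) {
    for (sq in names(exam$stacks[[obs]])) {
      f <- file.path(out_dir, sprintf("%s_%s_obs%d.nii.gz",
                                      exam$exam_id, sq, obs))
      write_stack_nifti(exam$stacks[[obs]][[sq]], f)
    }
  }
  invisible(NULL)
}

# Read every stack of one exam back from a directory written by
# simulate_cohort(); returns the nested [[observer]][[sequence]] list.
read_exam_nifti <- function(dir, exam_id) {
  files <- list.files(dir, pattern = paste0("^", exam_id,
                                            "_.*_obs[0-9]+\\.nii(\\.gz)?$"),
                      full.names = TRUE)
  if (length(files) == 0) stop("no stacks found for ", exam_id)
  obs_ids <- as.integer(sub(".*_obs([0-9]+)\\.nii(\\.gz)?$", "\\1", files))
  stacks <- vector("list", max(obs_ids))
  for (i in seq_along(files)) {
    st <- read_stack_nifti(files[i])
    if (is.null(stacks[[obs_ids[i]]])) stacks[[obs_ids[i]]] <- list()
    stacks[[obs_ids[i]]][[st$sequence]] <- st
  }
  stacks
}
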