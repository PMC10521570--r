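# Prepared-slice container: a pair of NIfTI stacks (images, masks) plus a
# JSON manifest carrying per-slice provenance. Used by the command-line
# workflow to hand slice sets between stages.

#' Export a slice set
#'
#' Writes `<name>_images.nii.gz` (float32, H x W x N), `<name>_masks.nii.gz`
#' (uint8) and `<name>_manifest.json` (subject, modality, slice index and
#' transform per stacked slice) into `dir`.
#'
#' @param slices list of model-space `slice_pair` objects.
#' @param dir output directory.
#' @param name container stem.
#' @return invisibly, the three paths.
#' @export
export_slices <- function(slices, dir, name = "slices") {
  if (!length(slices)) stop("no slices to export")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- stack_slices(slices)
  d <- dim(st$image)
  img <- array(float32_snap(st$image), c(d[1L], d[2L], d[4L]))
  msk <- array(st$mask, c(d[1L], d[2L], d[4L]))
  p_img <- file.path(dir, paste0(name, "_images.nii.gz"))
  p_msk <- file.path(dir, paste0(name, "_masks.nii.gz"))
  p_man <- file.path(dir, paste0(name, "_manifest.json"))
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "float"), p_img)
  RNifti::writeNifti(RNifti::asNifti(msk, datatype = "uint8"), p_msk)
  manifest <- data.frame(
    subject = vapply(slices, function(s) s$subject_id, character(1)),
    modality = vapply(slices, function(s) s$modality, character(1)),
    slice_index = vapply(slices, function(s) s$slice_index, integer(1)),
    transform = vapply(slices, function(s) s$transform_id, character(1)))
  jsonlite::write_json(manifest, p_man, dataframe = "rows")
  invisible(c(images = p_img, masks = p_msk, manifest = p_man))
}

#' Import a slice set written by [export_slices()]
#'
#' @param dir directory.
#' @param name container stem.
#' @return list of `slice_pair` objects.
#' @export
import_slices <- function(dir, name = "slices") {
  img <- read_nifti_array(file.path(dir, paste0(name, "_images.nii.gz")))
  msk <- read_nifti_array(file.path(dir, paste0(name, "_masks.nii.gz")))
  man <- jsonlite::read_json(file.path(dir, paste0(name, "_manifest.json")),
                             simplifyVector = TRUE)
  if (length(dim(img)) == 2L) { dim(img) <- c(dim(img), 1L); dim(msk) <- c(dim(msk), 1L) }
  if (nrow(man) != dim(img)[3L])
    stop("manifest rows (", nrow(man), ") do not match stacked slices (",
         dim(img)[3L], ")")
  lapply(seq_len(nrow(man)), function(i)
    slice_pair(img[, , i], msk[, , i], man$subject[i], man$modality[i],
               man$slice_index[i], man$transform[i]))
}
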