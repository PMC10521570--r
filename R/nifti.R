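# NIfTI input/output for subject volumes.
#
# One image file and one mask file per subject-modality:
#   <subject>_<modality>.nii.gz   (float32 intensities)
#   <subject>_mask.nii.gz         (uint8 binary mask, shared by modalities)
# Intensities are snapped to the float32 grid at generation time, so the
# round trip is lossless.

#' Write a subject volume to NIfTI
#'
#' @param volume a [subject_volume()].
#' @param dir output directory (created if missing).
#' @return named character vector with the `image` and `mask` paths.
#' @export
write_nifti <- function(volume, dir) {
  stopifnot(inherits(volume, "subject_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, sprintf("%s_%s.nii.gz", volume$subject_id,
                                     volume$modality))
  mask_path <- file.path(dir, sprintf("%s_mask.nii.gz", volume$subject_id))
  RNifti::writeNifti(RNifti::asNifti(volume$image, datatype = "float"),
                     img_path)
  RNifti::writeNifti(RNifti::asNifti(volume$mask, datatype = "uint8"),
                     mask_path)
  c(image = img_path, mask = mask_path)
}

#' Read a subject volume from NIfTI
#'
#' @param image_path path to `<subject>_<modality>.nii.gz`.
#' @param mask_path path to the mask file; by default inferred from
#'   `image_path` by the cohort naming convention.
#' @param subject_id,modality provenance; by default parsed from the image
#'   filename.
#' @return a [subject_volume()].
#' @export
read_nifti <- function(image_path, mask_path = NULL, subject_id = NULL,
                       modality = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (is.null(subject_id))
    subject_id <- paste(parts[-length(parts)], collapse = "_")
  if (is.null(modality)) modality <- parts[length(parts)]
  if (is.null(mask_path))
    mask_path <- file.path(dirname(image_path),
                           sprintf("%s_mask.nii.gz", subject_id))
  img <- read_nifti_array(image_path)
  msk <- read_nifti_array(mask_path)
  subject_volume(img, msk, subject_id, modality)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(RNifti::readNifti(path),
                error = function(e) stop("not a readable NIfTI file: ", path,
                                         " (", conditionMessage(e), ")",
                                         call. = FALSE))
  a <- as.array(x)
  attributes(a) <- list(dim = dim(a))
  a
}

#' Write a whole cohort to NIfTI
#'
#' @param cohort list of `subject_volume` objects.
#' @param dir output directory.
#' @return invisibly, a character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- unlist(lapply(cohort, write_nifti, dir = dir))
  invisible(unique(paths))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory holding `<subject>_<modality>.nii.gz` and
#'   `<subject>_mask.nii.gz` files.
#' @return list of `subject_volume` objects, ordered by subject then
#'   modality filename.
#' @export
read_cohort <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE))
  imgs <- imgs[!grepl("_mask\\.nii", imgs)]
  if (!length(imgs)) stop("no NIfTI image files found in ", dir)
  lapply(imgs, read_nifti)
}
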