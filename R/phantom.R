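# Synthetic MRI-like phantom cohorts.
#
# Each subject is a 3-D stack of 2-D slices holding a bright elliptical
# "brain" on a dark noisy background, with one hyperintense ellipsoidal
# lesion spanning a contiguous slice interval. Two co-registered modalities
# share the lesion geometry (and mask) but have independent noise and a
# different lesion contrast, emulating DWI being the more conspicuous
# sequence. Everything downstream of the scanner — centering, slice
# selection, augmentation, training, evaluation — can be exercised on these
# cohorts without any clinical data.

#' Parameters of the synthetic phantom cohort
#'
#' Defaults mirror the acquisition the pipeline was designed around:
#' 60-slice volumes of 160x160 pixels, two modalities, and lesions visible
#' on 12-24 slices per subject (about 18 on average).
#'
#' @param n_subjects number of subjects.
#' @param slices_per_volume slices per 3-D volume.
#' @param height,width slice size in pixels.
#' @param lesion_slice_range inclusive interval (length 2) for the number
#'   of lesion-bearing slices per subject.
#' @param lesion_radius_range in-plane lesion semi-axis range, pixels.
#' @param lesion_contrast intensity offset of lesion over brain tissue
#'   (applied x1 in the first modality, x0.6 in the second).
#' @param noise_sd standard deviation of the smoothed background noise.
#' @param modalities ordered character vector of modality tags.
#' @param seed integer seed; cohorts are voxel-identical given the seed.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(n_subjects = 44L, slices_per_volume = 60L,
                           height = 160L, width = 160L,
                           lesion_slice_range = c(12L, 24L),
                           lesion_radius_range = NULL,
                           lesion_contrast = 0.5, noise_sd = 0.05,
                           modalities = c("DWI", "FLAIR"), seed = 1L) {
  if (is.null(lesion_radius_range))
    lesion_radius_range <- round(c(0.05, 0.12) * min(height, width))
  stopifnot(n_subjects >= 1, slices_per_volume >= 1, height >= 8,
            width >= 8, noise_sd >= 0, length(lesion_slice_range) == 2,
            length(modalities) >= 1)
  lesion_slice_range <- as.integer(lesion_slice_range)
  if (lesion_slice_range[1L] < 1L || lesion_slice_range[2L] > slices_per_volume ||
      lesion_slice_range[1L] > lesion_slice_range[2L])
    stop("lesion_slice_range must lie within [1, slices_per_volume]")
  brain_r <- 0.38 * min(height, width)
  if (max(lesion_radius_range) >= brain_r)
    stop("lesion radius (", max(lesion_radius_range),
         " px) exceeds the brain radius (", round(brain_r, 1), " px)")
  structure(list(n_subjects = as.integer(n_subjects),
                 slices_per_volume = as.integer(slices_per_volume),
                 height = as.integer(height), width = as.integer(width),
                 lesion_slice_range = lesion_slice_range,
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 modalities = as.character(modalities),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' One modality of one subject: image volume plus lesion mask
#'
#' @param image 3-D numeric array (H, W, D).
#' @param mask 3-D binary array, same dimensions.
#' @param subject_id,modality provenance tags.
#' @return a `subject_volume`.
#' @export
subject_volume <- function(image, mask, subject_id, modality) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
  structure(list(image = image, mask = mask,
                 subject_id = as.character(subject_id),
                 modality = as.character(modality)),
            class = "subject_volume")
}

#' @export
print.subject_volume <- function(x, ...) {
  cat(sprintf("<subject_volume> %s / %s: %s voxels, %d lesion voxels on %d slices\n",
              x$subject_id, x$modality, paste(dim(x$image), collapse = "x"),
              sum(x$mask), sum(apply(x$mask, 3, sum) > 0)))
  invisible(x)
}

#' Snap doubles to the float32 grid
#'
#' Volumes are stored in NIfTI as 32-bit floats; snapping intensities to
#' that grid at generation time makes the write/read round trip exact.
#'
#' @param x numeric array.
#' @return the array with every value representable in float32.
#' @export
float32_snap <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  dim(y) <- d
  y
}

# Smoothed uniform noise field, one (H, W, D) draw.
smooth_noise <- function(h, w, d, sd, sigma = 2) {
  z <- array(runif(h * w * d, -1, 1), c(h, w, d))
  if (sd == 0) return(array(0, c(h, w, d)))
  z <- EBImage::gblur(z, sigma = sigma)
  z * (sd / stats::sd(z))
}

#' Generate a synthetic phantom cohort
#'
#' @param params a [phantom_params()].
#' @return a list of `subject_volume` objects, one per subject per modality
#'   (all modalities of one subject share an identical mask).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$height; w <- params$width; d <- params$slices_per_volume
  rr <- params$lesion_radius_range
  withr::with_seed(params$seed, {
    vols <- list()
    xg <- matrix(seq_len(h), h, w)
    yg <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (s in seq_len(params$n_subjects)) {
      sid <- sprintf("sub%02d", s)
      # brain: ellipse with a random centre offset and semi-axes
      cx <- h / 2 + runif(1, -0.04, 0.04) * h
      cy <- w / 2 + runif(1, -0.04, 0.04) * w
      ax <- 0.38 * h * runif(1, 0.9, 1)
      ay <- 0.38 * w * runif(1, 0.9, 1)
      brain <- (((xg - cx) / ax)^2 + ((yg - cy) / ay)^2) <= 1
      # lesion: contiguous slice interval + in-plane ellipse per slice
      n_choices <- params$lesion_slice_range[1L]:params$lesion_slice_range[2L]
      n_les <- n_choices[sample.int(length(n_choices), 1L)]
      z0_choices <- seq_len(d - n_les + 1L)
      z0 <- z0_choices[sample.int(length(z0_choices), 1L)]
      zs <- z0:(z0 + n_les - 1L)
      rx <- runif(1, rr[1L], rr[2L]); ry <- runif(1, rr[1L], rr[2L])
      # lesion centre stays inside the brain with a radius margin
      th <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 1)
      lx <- cx + rad * (ax - rx - 2) * cos(th) * 0.8
      ly <- cy + rad * (ay - ry - 2) * sin(th) * 0.8
      mask <- array(0, c(h, w, d))
      cz <- mean(zs); rz <- (n_les - 1) / 2 + 0.75
      for (z in zs) {
        f <- sqrt(max(0, 1 - ((z - cz) / rz)^2))
        exi <- max(f * rx, 0.8); eyi <- max(f * ry, 0.8)
        mask[, , z] <- (((xg - lx) / exi)^2 + ((yg - ly) / eyi)^2) <= 1
      }
      stopifnot(all(apply(mask[, , zs, drop = FALSE], 3, sum) > 0))
      for (mi in seq_along(params$modalities)) {
        scale <- if (mi == 1L) 1 else 0.6
        img <- array(0.05, c(h, w, d)) +
          array(rep(brain * 0.5, d), c(h, w, d)) +
          mask * (params$lesion_contrast * scale) +
          smooth_noise(h, w, d, params$noise_sd)
        img[img < 0] <- 0
        vols[[length(vols) + 1L]] <-
          subject_volume(float32_snap(img), mask, sid,
                         params$modalities[mi])
      }
    }
    vols
  })
}
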