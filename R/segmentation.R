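#' En-face angiogram image container
#'
#' Wraps one 8-bit grayscale en-face OCTA image together with its physical
#' pixel pitch and acquisition labels (eye side and capillary plexus).
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]` (rows = image
#'   rows, columns = image columns). Must be square.
#' @param pixel_pitch Physical size of one pixel in mm (e.g. 0.012 for a
#'   500-pixel 6x6 mm scan).
#' @param eye_side `"right"` or `"left"`.
#' @param plexus `"SCP"` (superficial) or `"DCP"` (deep capillary plexus).
#' @param patient_id Optional patient identifier.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, pixel_pitch, eye_side = c("right", "left"),
                         plexus = c("SCP", "DCP"), patient_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) != ncol(pixels)) stop("image must be square")
  if (nrow(pixels) == 0L) stop("image must be non-empty")
  if (any(pixels < 0 | pixels > 255)) stop("intensities must lie in [0, 255]")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0) {
    stop("`pixel_pitch` must be a positive scalar (mm per pixel)")
  }
  eye_side <- match.arg(eye_side)
  plexus <- match.arg(plexus)
  structure(
    list(pixels = pixels, pixel_pitch = pixel_pitch, eye_side = eye_side,
         plexus = plexus, patient_id = patient_id),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %dx%d px, pitch %.4g mm/px, %s %s, patient %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch, x$eye_side,
              x$plexus, x$patient_id))
  invisible(x)
}

#' Binarize an en-face image by global intensity thresholding
#'
#' Classifies a pixel as vessel when its intensity strictly exceeds
#' `mean + std_coeff * sd`, where the mean and standard deviation are taken
#' over all pixels of the image. The standard deviation is the population SD
#' (divides by N). `std_coeff = 0.5` segments all vessels; `std_coeff = 1.3`
#' retains only the brightest (big) vessels.
#'
#' @param image An [enface_image] (or a bare numeric matrix).
#' @param std_coeff Positive threshold coefficient.
#' @return An object of class `vessel_map`: list with `mask` (logical matrix,
#'   `TRUE` = vessel), `std_coeff_used`, `threshold`, and `source`
#'   (`"all_vessels"` or `"big_vessels"`).
#' @export
binarize <- function(image, std_coeff = 0.5) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  if (!is.matrix(px) || length(px) == 0L) stop("image must be a non-empty matrix")
  if (!is.numeric(std_coeff) || length(std_coeff) != 1L || std_coeff <= 0) {
    stop("`std_coeff` must be a positive scalar")
  }
  mu <- mean(px)
  sd_pop <- sqrt(mean((px - mu)^2))
  thr <- mu + std_coeff * sd_pop
  structure(
    list(mask = px > thr, std_coeff_used = std_coeff, threshold = thr,
         source = if (std_coeff >= 1.3) "big_vessels" else "all_vessels"),
    class = "vessel_map"
  )
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %dx%d, %s, std_coeff %.3g, %d vessel px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), x$source, x$std_coeff_used,
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

# Morphological dilation by a disc of radius r (Euclidean, pixel centers).
# Exact: a pixel is set iff some foreground pixel lies within distance r.
dilate_disc <- function(mask, radius) {
  if (radius == 0 || !any(mask)) return(mask)
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, , drop = FALSE]
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  row0 <- (idx - 1L) %% nr + 1L
  col0 <- (idx - 1L) %/% nr + 1L
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off))) {
    rr <- row0 + off$dy[k]
    cc <- col0 + off$dx[k]
    keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out[cbind(rr[keep], cc[keep])] <- TRUE
  }
  out
}

#' Segment the big vessels of an en-face image
#'
#' Binarizes at the high coefficient (`std_coeff = 1.3` by default) so that
#' only the brightest, large arcade vessels remain, then optionally dilates
#' the mask by a disc structuring element to widen the exclusion region.
#'
#' @param image An [enface_image] or numeric matrix.
#' @param dilation_radius Disc radius in pixels (>= 0); 0 keeps the raw
#'   threshold mask.
#' @param std_coeff Threshold coefficient for the big-vessel segmentation.
#' @return A `vessel_map` with `source = "big_vessels"`.
#' @export
big_vessel_mask <- function(image, dilation_radius = 0, std_coeff = 1.3) {
  if (!is.numeric(dilation_radius) || length(dilation_radius) != 1L ||
      dilation_radius < 0) {
    stop("`dilation_radius` must be a non-negative scalar")
  }
  bm <- binarize(image, std_coeff = std_coeff)
  bm$mask <- dilate_disc(bm$mask, dilation_radius)
  bm$source <- "big_vessels"
  bm
}

#' Build the capillary analysis mask with big-vessel exclusion
#'
#' For the superficial plexus the big vessels are removed from the vessel
#' mask and their pixels are excluded from the measured area, so that vessel
#' density reflects the microcirculation only. For the deep plexus no
#' exclusion is applied unless `exclude_projection = TRUE`, in which case the
#' superficial big-vessel mask is used as an approximation of the projection
#' artifacts cast by the large vessels.
#'
#' @param all_vessels `vessel_map` from [binarize()] at the all-vessel
#'   coefficient.
#' @param big `vessel_map` from [big_vessel_mask()]; for the DCP with
#'   projection exclusion this is the SCP big-vessel mask. May be `NULL` when
#'   no exclusion applies.
#' @param plexus `"SCP"` or `"DCP"`.
#' @param exclude_projection For the DCP only: apply the (SCP) big-vessel
#'   mask as the exclusion region.
#' @return List with `capillary_mask` and `excluded_area_mask` (logical
#'   matrices, always disjoint).
#' @export
analysis_mask <- function(all_vessels, big = NULL, plexus = c("SCP", "DCP"),
                          exclude_projection = FALSE) {
  plexus <- match.arg(plexus)
  av <- if (inherits(all_vessels, "vessel_map")) all_vessels$mask else all_vessels
  bg <- if (inherits(big, "vessel_map")) big$mask else big
  if (!is.null(bg) && !identical(dim(av), dim(bg))) {
    stop("vessel and big-vessel masks must share the same shape")
  }
  exclude <- if (plexus == "SCP") !is.null(bg) else (exclude_projection && !is.null(bg))
  if (exclude) {
    list(capillary_mask = av & !bg, excluded_area_mask = bg)
  } else {
    list(capillary_mask = av, excluded_area_mask = matrix(FALSE, nrow(av), ncol(av)))
  }
}
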