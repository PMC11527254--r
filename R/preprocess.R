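#' Rolling-ball background subtraction
#'
#' Subtracts, independently from each z-slice, the grayscale morphological
#' opening of the slice with a flat disk (the standard rolling-ball
#' equivalent). Flat backgrounds and plateaus wider than the ball are
#' suppressed; structures narrower than the ball (somata, fiber tracts) are
#' preserved. The default 20-pixel radius matches common practice for
#' light-sheet TH immunofluorescence.
#'
#' @param vol a `scalar_volume`.
#' @param radius_px disk radius in pixels (>= 1).
#' @return background-subtracted `scalar_volume` (non-negative, <= input).
#' @export
rolling_ball_subtract <- function(vol, radius_px = 20L) {
  radius_px <- as.integer(radius_px)
  if (is.na(radius_px) || radius_px < 1L) stop("radius_px must be >= 1")
  bg <- open_disk_cpp(as.numeric(vol$values), dim(vol$values), radius_px)
  out <- vol$values - array(bg, dim(vol$values))
  out[out < 0] <- 0  # guard against float round-off; opening <= input
  scalar_volume(out, vol$grid)
}

#' Gaussian smoothing in world units
#'
#' Isotropic Gaussian convolution with sigma given in millimetres (the unit
#' convention of `fslmaths -s`); per-axis sigma in voxels is
#' `sigma_mm * 1000 / spacing_um`. Separable convolution with zero padding
#' (brains are surrounded by zeros after masking). `sigma_mm = 0` is the
#' identity. The discrete kernel is truncated at 4 sigma and normalised to
#' unit sum.
#'
#' @param vol a `scalar_volume`.
#' @param sigma_mm Gaussian sigma in mm (>= 0); default 0.05.
#' @return smoothed `scalar_volume`.
#' @export
gaussian_smooth <- function(vol, sigma_mm = 0.05) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(vol)
  out <- as.numeric(vol$values)
  dims <- dim(vol$values)
  for (axis in 0:2) {
    sig <- sigma_mm * 1000 / vol$grid$spacing[axis + 1]
    r <- max(1L, ceiling(4 * sig))
    k <- exp(-((-r):r)^2 / (2 * sig^2))
    k <- k / sum(k)
    out <- convolve_axis_cpp(out, dims, k, axis)
  }
  scalar_volume(array(out, dims), vol$grid)
}

#' Flip a volume across the mid-sagittal plane
#'
#' Reverses the x (left-right) axis: index `x -> shape_x - 1 - x`. Used to
#' compare left hemispheres with right hemispheres. An involution: flipping
#' twice restores the input bit-exactly.
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @return flipped volume of the same kind.
#' @export
flip_left_to_right <- function(vol) {
  if (inherits(vol, "label_volume")) {
    flipped <- vol$labels[rev(seq_len(dim(vol$labels)[1])), , , drop = FALSE]
    label_volume(flipped, vol$grid, vol$regions)
  } else {
    flipped <- vol$values[rev(seq_len(dim(vol$values)[1])), , , drop = FALSE]
    scalar_volume(flipped, vol$grid)
  }
}

#' Analysis exclusion mask
#'
#' Voxels eligible for voxel-wise statistics: labelled (inside the brain)
#' and not flagged excluded in the region table (ventricle-like and
#' undefined regions are excluded).
#'
#' @param atlas a `label_volume`.
#' @return logical array, TRUE where statistics are computed.
#' @export
exclusion_mask <- function(atlas) {
  excl_ids <- atlas$regions$label_id[atlas$regions$excluded]
  atlas$labels > 0L & !(atlas$labels %in% excl_ids)
}
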