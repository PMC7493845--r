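#' Median denoising
#'
#' Replaces each voxel by the median of its `window`^3 neighborhood
#' (reflected at the borders), the standard impulse-noise removal step for
#' subtraction angiography. The default 3x3x3 window matches the size used
#' for clinical DSA volumes.
#'
#' @param volume an [as_volume()] object.
#' @param window odd positive integer edge length of the cubic window.
#' @return A denoised [as_volume()] object.
#' @export
median_denoise <- function(volume, window = 3L) {
  stopifnot(is_volume(volume))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  out <- median3d_cpp(as.vector(volume$data), dim(volume$data), window)
  as_volume(array(out, dim(volume$data)), volume$spacing, volume$origin)
}

#' Min-max intensity normalization to [0, 1]
#'
#' Applies `(v - min) / (max - min)`. A constant volume has no dynamic
#' range; it is mapped to all zeros with a warning so that the iterative
#' detection loop can terminate gracefully once removal has emptied the
#' image.
#'
#' @param volume an [as_volume()] object.
#' @return A normalized [as_volume()] object with intensities in `[0, 1]`.
#' @export
normalize01 <- function(volume) {
  stopifnot(is_volume(volume))
  rng <- range(volume$data)
  if (diff(rng) == 0) {
    warning("constant volume: normalizing to all zeros")
    return(as_volume(array(0, dim(volume$data)), volume$spacing, volume$origin))
  }
  as_volume((volume$data - rng[1]) / diff(rng), volume$spacing, volume$origin)
}

#' Standard preprocessing: median denoise then normalize
#'
#' @param volume an [as_volume()] object.
#' @param median_window odd window for [median_denoise()]; use 0 to skip.
#' @return A preprocessed [as_volume()] object.
#' @export
preprocess_volume <- function(volume, median_window = 3L) {
  if (median_window >= 1L) volume <- median_denoise(volume, median_window)
  normalize01(volume)
}
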