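#' Pre-processing configuration
#'
#' Parameters for the contrast-enhancement and binarization stage. The
#' maxima-suppression depth `h` is chosen per slice from the equalized
#' image's mean brightness: predominantly dark slices (mean below
#' `brightness_split`) use `h_dark`, bright slices use `h_bright`. Both
#' depths are intensities on the normalized \[0, 1\] scale.
#'
#' @param n_bins Number of uniform histogram bins used by
#'   [equalize_histogram()]; default 64.
#' @param h_dark,h_bright Suppression depths in (0, 1) for dark and bright
#'   slices respectively.
#' @param brightness_split Mean-intensity cutoff in (0, 1) separating the
#'   two regimes.
#' @param connectivity Pixel connectivity (4 or 8) for plateaus and
#'   connected components.
#' @param use_minima If `TRUE`, suppress shallow minima (h-minima transform)
#'   instead of shallow maxima; the default targets hyperintense lesions.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(n_bins = 64L, h_dark = 0.30, h_bright = 0.55,
                              brightness_split = 0.5, connectivity = 4L,
                              use_minima = FALSE) {
  stopifnot(n_bins >= 2L, h_dark > 0, h_dark < 1, h_bright > 0, h_bright < 1,
            brightness_split > 0, brightness_split < 1)
  structure(
    list(n_bins = as.integer(n_bins), h_dark = h_dark, h_bright = h_bright,
         brightness_split = brightness_split,
         connectivity = check_connectivity(connectivity),
         use_minima = isTRUE(use_minima)),
    class = "preprocess_config"
  )
}

#' Histogram equalization
#'
#' Remaps intensities through the discrete cumulative distribution over
#' `n_bins` uniform bins on \[0, 1\], so that occupied gray levels spread
#' over the full output range and hyperintense regions are pushed toward 1.
#' Output levels are the CDF values of each bin, rescaled so the first
#' occupied bin maps to 0 and the last to 1; the mapping is monotone
#' non-decreasing, so pixel rank order is never inverted. A constant image
#' (a single occupied bin) is returned unchanged.
#'
#' @param img A [gray_image()] or numeric matrix with values in \[0, 1\].
#' @param n_bins Number of uniform bins.
#' @return Same type as `img`, equalized.
#' @export
equalize_histogram <- function(img, n_bins = 64L) {
  px <- as_pixels(img)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  bin <- pmin(floor(px * n_bins), n_bins - 1L)  # bin index 0..n_bins-1
  counts <- tabulate(bin + 1L, nbins = n_bins)
  cdf <- cumsum(counts) / length(px)
  occupied <- which(counts > 0L)
  cdf_min <- cdf[occupied[1L]]
  if (cdf_min >= 1) return(img)  # single occupied bin: constant image
  levels <- pmax((cdf - cdf_min) / (1 - cdf_min), 0)
  out <- array(levels[bin + 1L], dim(px))
  replace_pixels(img, out)
}

replace_pixels <- function(img, px) {
  if (inherits(img, "gray_image")) { img$pixels <- px; img } else px
}

#' Suppress shallow maxima (h-maxima transform)
#'
#' Grayscale reconstruction by dilation of `img - h` under `img`. Every
#' local maximum is lowered by up to `h`, and maxima whose height above
#' their surroundings is less than `h` disappear entirely, leaving only
#' peaks of dynamic at least `h` — the mechanism used to discard dim
#' structures before binarization.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param h Suppression depth in (0, 1).
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return Same type as `img`; pointwise `<= img`.
#' @export
suppress_maxima <- function(img, h, connectivity = 4L) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h >= 1)
    stop("h must be a single value in (0, 1)", call. = FALSE)
  px <- as_pixels(img)
  out <- reconstruct_dilate_cpp(px - h, px, check_connectivity(connectivity))
  replace_pixels(img, out)
}

#' Suppress shallow minima (h-minima transform)
#'
#' Dual of [suppress_maxima()]: `1 - suppress_maxima(1 - img, h)`. Raises
#' every local minimum by up to `h`, removing basins shallower than `h`.
#'
#' @inheritParams suppress_maxima
#' @return Same type as `img`; pointwise `>= img`.
#' @export
suppress_minima <- function(img, h, connectivity = 4L) {
  px <- as_pixels(img)
  inv <- suppress_maxima(1 - px, h, connectivity)
  replace_pixels(img, 1 - inv)
}

#' Regional maxima
#'
#' Marks every connected plateau of constant intensity whose exterior
#' neighbors are all strictly darker. Applied after maxima suppression, this
#' turns the slice into a binary image of its dominant bright structures.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param connectivity Plateau connectivity, 4 or 8.
#' @return Logical matrix; a constant image yields all `TRUE` (the whole
#'   image is one plateau with no lower neighbor).
#' @export
regional_maxima <- function(img, connectivity = 4L) {
  regional_maxima_cpp(as_pixels(img), check_connectivity(connectivity))
}

#' Choose the suppression depth for a slice
#'
#' Dispatches between the two configured depths on the mean intensity of the
#' (equalized) slice: below `brightness_split` the slice counts as
#' predominantly dark and `h_dark` is used, otherwise `h_bright`.
#'
#' @param img Equalized [gray_image()] or matrix.
#' @param cfg A [preprocess_config()].
#' @return A single intensity in (0, 1).
#' @export
select_h <- function(img, cfg = preprocess_config()) {
  if (mean(as_pixels(img)) < cfg$brightness_split) cfg$h_dark else cfg$h_bright
}

#' Binarize a slice into its bright structures
#'
#' The full pre-processing chain: histogram equalization, per-slice choice
#' of the suppression depth, h-maxima suppression (or h-minima when
#' `cfg$use_minima`), then regional-maxima extraction. The result is the
#' region-of-interest mask handed to the coordinate and area detectors.
#'
#' @param img A [gray_image()] or numeric matrix in \[0, 1\].
#' @param cfg A [preprocess_config()].
#' @return Logical matrix (never empty: every image has regional maxima).
#' @export
binarize <- function(img, cfg = preprocess_config()) {
  eq <- equalize_histogram(img, cfg$n_bins)
  h <- select_h(eq, cfg)
  adj <- if (cfg$use_minima) suppress_minima(eq, h, cfg$connectivity)
         else suppress_maxima(eq, h, cfg$connectivity)
  regional_maxima(adj, cfg$connectivity)
}
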