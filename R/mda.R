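#' Structuring elements
#'
#' Builds the flat structuring element used by the binary morphology stages:
#' `disk` (Euclidean distance <= radius), `square` (Chebyshev) or `cross`
#' (Manhattan). Radius 0 yields the single-pixel identity element.
#'
#' @param radius Non-negative integer radius in pixels.
#' @param shape `"disk"`, `"square"` or `"cross"`.
#' @return A 0/1 numeric matrix of size `2*radius + 1` squared.
#' @export
selem <- function(radius, shape = c("disk", "square", "cross")) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  d <- -radius:radius
  dist <- switch(shape,
    disk = outer(d^2, d^2, `+`) <= radius^2,
    square = outer(abs(d), abs(d), pmax) <= radius,
    cross = outer(abs(d), abs(d), `+`) <= radius)
  dist + 0
}

#' Detection-by-area configuration
#'
#' @param erosion_radius Structuring-element radius in pixels for the
#'   pre-filter erosion; `NULL` (default) scales a radius-2-at-256-pixels
#'   disk with the image width: `round(2 * X / 256)`.
#' @param selem_shape Element shape, see [selem()].
#' @param connectivity 4 or 8 for component labeling.
#' @return An `mda_config` list.
#' @export
mda_config <- function(erosion_radius = NULL,
                       selem_shape = c("disk", "square", "cross"),
                       connectivity = 4L) {
  if (!is.null(erosion_radius) && erosion_radius < 0)
    stop("erosion_radius must be >= 0", call. = FALSE)
  structure(list(erosion_radius = erosion_radius,
                 selem_shape = match.arg(selem_shape),
                 connectivity = check_connectivity(connectivity)),
            class = "mda_config")
}

# Resolve the resolution-proportional default radius for a given mask width.
resolve_radius <- function(radius, width) {
  if (is.null(radius)) max(1L, as.integer(round(2 * width / 256))) else
    as.integer(radius)
}

#' Binary erosion
#'
#' Erodes the mask with the configured structuring element, disconnecting
#' thin bridges between the tumor and spurious tissue and shrinking small
#' elements so the mean-area filter can remove them. Out-of-image pixels
#' count as foreground (border replication), so a mask touching the border
#' is not eaten from outside the frame. Radius 0 is the identity.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param cfg An [mda_config()].
#' @return Logical matrix, a subset of `mask`.
#' @export
erode_mask <- function(mask, cfg = mda_config()) {
  mask <- as_mask(mask)
  r <- resolve_radius(cfg$erosion_radius, ncol(mask))
  if (r == 0L) return(mask)
  EBImage::erode(mask + 0, selem(r, cfg$selem_shape)) > 0.5
}

#' Mean-area component filter
#'
#' Labels the connected components, computes the arithmetic mean of their
#' areas, and zeroes every component whose area is strictly smaller than
#' that mean. Ties survive, so a single component — or several of equal
#' area — is always kept, and the largest component can never be removed.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return Logical matrix; empty input passes through unchanged.
#' @export
mean_area_filter <- function(mask, connectivity = 4L) {
  mask <- as_mask(mask)
  ct <- label_components(mask, connectivity)
  if (length(ct$areas) == 0L) return(mask)
  drop <- which(ct$areas < mean(ct$areas))
  if (length(drop)) mask[ct$labels %in% drop] <- FALSE
  mask
}

#' Detection by area (MDA)
#'
#' Erodes the skull-stripped mask to disconnect and shrink spurious
#' elements, then removes every component smaller than the mean component
#' area, on the premise that the tumor region is larger than the average
#' leftover structure. If the erosion would erase the mask entirely the
#' pre-erosion mask is returned with a warning, since the later dilation
#' could not recover a fully erased tumor.
#'
#' @param mask Logical matrix from [mdc_segment()].
#' @param cfg An [mda_config()].
#' @return Logical matrix.
#' @export
mda_segment <- function(mask, cfg = mda_config()) {
  mask <- as_mask(mask)
  eroded <- erode_mask(mask, cfg)
  if (!any(eroded) && any(mask)) {
    warning("erosion removed the whole mask; skipping erosion", call. = FALSE)
    eroded <- mask
  }
  mean_area_filter(eroded, cfg$connectivity)
}
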