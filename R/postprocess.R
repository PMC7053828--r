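#' Post-processing configuration
#'
#' @param dilation_radius Radius in pixels for the recovery dilation;
#'   `NULL` (default) mirrors the MDA erosion radius so tissue lost to the
#'   erosion is recovered symmetrically.
#' @param selem_shape Element shape, see [selem()].
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(dilation_radius = NULL,
                               selem_shape = c("disk", "square", "cross")) {
  if (!is.null(dilation_radius) && dilation_radius < 0)
    stop("dilation_radius must be >= 0", call. = FALSE)
  structure(list(dilation_radius = dilation_radius,
                 selem_shape = match.arg(selem_shape)),
            class = "postprocess_config")
}

#' Binary dilation
#'
#' Dilates the tumor mask with the configured structuring element to
#' recover the tissue removed by the MDA erosion. Radius 0 is the identity;
#' the input is always a subset of the output.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param cfg A [postprocess_config()].
#' @return Logical matrix, a superset of `mask`.
#' @export
dilate_mask <- function(mask, cfg = postprocess_config()) {
  mask <- as_mask(mask)
  r <- resolve_radius(cfg$dilation_radius, ncol(mask))
  if (r == 0L) return(mask)
  EBImage::dilate(mask + 0, selem(r, cfg$selem_shape)) > 0.5
}

#' Fill enclosed holes
#'
#' Sets to foreground every background component that is not connected to
#' the image border. Background connectivity is the topological complement
#' of the foreground connectivity (8-connected foreground implies
#' 4-connected background and vice versa). Idempotent, and never removes
#' foreground.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity Foreground connectivity, 4 or 8.
#' @return Logical matrix, a superset of `mask`.
#' @export
fill_holes <- function(mask, connectivity = 4L) {
  mask <- as_mask(mask)
  bg_conn <- if (check_connectivity(connectivity) == 8L) 4L else 8L
  bg <- label_components_cpp(!mask, bg_conn)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

#' Apply a binary mask to the original slice
#'
#' Restores the tumor's true intensities by keeping the original pixel
#' value wherever the mask is foreground and zero elsewhere, so that the
#' segmented region has (close to) its real size and texture for any
#' downstream attribute extraction.
#'
#' @param original A [gray_image()] or numeric matrix.
#' @param mask Logical (or 0/1) matrix of the same shape.
#' @return Same type as `original`.
#' @export
apply_mask <- function(original, mask) {
  px <- as_pixels(original)
  mask <- as_mask(mask)
  if (!identical(dim(px), dim(mask)))
    stop("mask shape does not match image shape", call. = FALSE)
  replace_pixels(original, px * mask)
}
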