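#' Brain-edge displacement offsets
#'
#' The raw edge points found by [scan_edges()] land on the skull (the skull
#' is brighter than background, so the middle-line scans hit it first). The
#' brain lies a short, anatomically stable distance inside the skull, so
#' each edge is moved inward by a fixed fraction of the image dimension;
#' fractions keep the behavior identical across the 256, 512 and 704 pixel
#' acquisition matrices. Coronal and sagittal slices also contain the neck,
#' whose bright pixels drag the raw bottom edge far below the brain, so the
#' bottom edge is additionally raised by `neck_extra` for those views.
#'
#' @param d_left,d_right,d_top,d_bottom Inward displacement of each edge as
#'   a fraction of the image width (left/right) or height (top/bottom), in
#'   \[0, 0.4\].
#' @param neck_extra Additional upward displacement of the bottom edge for
#'   coronal/sagittal views, fraction of height in \[0, 0.4\].
#' @return An `edge_offsets` list.
#' @export
edge_offsets <- function(d_left = 0.04, d_right = 0.04, d_top = 0.04,
                         d_bottom = 0.04, neck_extra = 0.12) {
  v <- c(d_left = d_left, d_right = d_right, d_top = d_top,
         d_bottom = d_bottom, neck_extra = neck_extra)
  if (any(v < 0) || any(v > 0.4))
    stop("edge offsets must lie in [0, 0.4]", call. = FALSE)
  structure(as.list(v), class = "edge_offsets")
}

#' Locate the raw brain edges by middle-line scans
#'
#' Scans the middle row of the mask from left to right and the middle
#' column from top to bottom. The first and last foreground pixels on the
#' middle row give the raw left and right edges; the first and last on the
#' middle column give the raw top and bottom edges. Assumes the head sits
#' in the central region of the image, the usual MRI setting; if the exact
#' middle line is empty, nearby lines (up to 10% of the image dimension
#' away) are searched with a warning before giving up.
#'
#' @param mask Logical (or 0/1) matrix, typically from [binarize()].
#' @return List with integer elements `top`, `bottom`, `left`, `right`
#'   (1-based row/column indices, row 1 at the top).
#' @export
scan_edges <- function(mask) {
  mask <- as_mask(mask)
  ny <- nrow(mask); nx <- ncol(mask)
  row_hit <- scan_center_line(mask, floor(ny / 2) + 1L, ny, byrow = TRUE)
  col_hit <- scan_center_line(mask, floor(nx / 2) + 1L, nx, byrow = FALSE)
  list(top = col_hit[1L], bottom = col_hit[2L],
       left = row_hit[1L], right = row_hit[2L])
}

# Find first/last foreground index on the line at `center`, falling back to
# the nearest non-empty parallel line within +/- 10% of `extent`.
scan_center_line <- function(mask, center, extent, byrow) {
  line_at <- function(i) if (byrow) mask[i, ] else mask[, i]
  for (delta in 0:max(1L, round(0.1 * extent))) {
    for (i in unique(c(center - delta, center + delta))) {
      if (i < 1L || i > extent) next
      hits <- which(line_at(i))
      if (length(hits)) {
        if (delta > 0L)
          warning(sprintf("middle %s empty; used %s %d instead",
                          if (byrow) "row" else "column",
                          if (byrow) "row" else "column", i), call. = FALSE)
        return(c(hits[1L], hits[length(hits)]))
      }
    }
  }
  stop("edge detection failed: no foreground near the image center",
       call. = FALSE)
}

#' Displace raw edges onto the brain boundary
#'
#' Moves each raw edge inward by its configured fraction of the image
#' dimension (see [edge_offsets()]), applies the extra neck displacement to
#' the bottom edge for coronal and sagittal views, and clamps to the image.
#'
#' @param raw List with `top`, `bottom`, `left`, `right` from [scan_edges()].
#' @param offsets An [edge_offsets()].
#' @param view View plane; `neck_extra` applies only to `"coronal"` and
#'   `"sagittal"`.
#' @param shape Integer vector `c(Y, X)` of the mask dimensions.
#' @return A `brain_edges` list with integer `top < bottom`, `left < right`.
#' @export
displace_edges <- function(raw, offsets = edge_offsets(), view = "axial",
                           shape) {
  view <- match_view(view)
  ny <- shape[1L]; nx <- shape[2L]
  top <- raw$top + round(offsets$d_top * ny)
  bottom <- raw$bottom - round(offsets$d_bottom * ny)
  if (view %in% c("coronal", "sagittal"))
    bottom <- bottom - round(offsets$neck_extra * ny)
  left <- raw$left + round(offsets$d_left * nx)
  right <- raw$right - round(offsets$d_right * nx)
  top <- max(1L, min(as.integer(top), ny))
  bottom <- max(1L, min(as.integer(bottom), ny))
  left <- max(1L, min(as.integer(left), nx))
  right <- max(1L, min(as.integer(right), nx))
  if (top >= bottom || left >= right)
    stop("degenerate geometry: edges cross after displacement", call. = FALSE)
  structure(list(top = top, bottom = bottom, left = left, right = right),
            class = "brain_edges")
}

#' Label connected components with areas and bounding boxes
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return List of class `component_table`: `labels` (integer matrix, 0 =
#'   background), `areas` (pixel count per label) and `bboxes` (matrix with
#'   columns `min_row`, `min_col`, `max_row`, `max_col`, inclusive, one row
#'   per label).
#' @export
label_components <- function(mask, connectivity = 4L) {
  mask <- as_mask(mask)
  labels <- label_components_cpp(mask, check_connectivity(connectivity))
  n <- max(labels)
  if (n == 0L) {
    return(structure(list(labels = labels, areas = integer(0),
                          bboxes = matrix(integer(0), 0, 4,
                                          dimnames = list(NULL,
                            c("min_row", "min_col", "max_row", "max_col")))),
                     class = "component_table"))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  bboxes <- cbind(
    min_row = tapply(rows, lab, min), min_col = tapply(cols, lab, min),
    max_row = tapply(rows, lab, max), max_col = tapply(cols, lab, max))
  structure(list(labels = labels,
                 areas = as.integer(tabulate(lab, nbins = n)),
                 bboxes = bboxes[order(as.integer(rownames(bboxes))), ,
                                 drop = FALSE]),
            class = "component_table")
}

#' Remove components outside the brain rectangle
#'
#' Deletes every connected component whose bounding box has at least one
#' corner strictly outside the closed rectangle spanned by the brain edges
#' (a corner is outside if its row is above `top` or below `bottom`, or its
#' column is left of `left` or right of `right`). Components are removed
#' whole — all pixels of an offending label are zeroed — which strips the
#' skull annulus, meninges and fat surrounding the brain.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param edges A `brain_edges` object from [displace_edges()].
#' @param connectivity 4 or 8.
#' @return Logical matrix, a subset of `mask`.
#' @export
remove_external_components <- function(mask, edges, connectivity = 4L) {
  mask <- as_mask(mask)
  ct <- label_components(mask, connectivity)
  if (length(ct$areas) == 0L) return(mask)
  bb <- ct$bboxes
  outside <- bb[, "min_row"] < edges$top | bb[, "max_row"] > edges$bottom |
    bb[, "min_col"] < edges$left | bb[, "max_col"] > edges$right
  drop <- which(outside)
  if (length(drop)) mask[ct$labels %in% drop] <- FALSE
  mask
}

#' Detection by coordinates (MDC)
#'
#' The full skull-stripping stage: locate the raw brain edges by middle-line
#' scans, displace them onto the brain boundary, and remove every component
#' whose bounding box extends beyond the resulting rectangle. Never adds
#' pixels, and removes components whole.
#'
#' @param mask Logical matrix from [binarize()].
#' @param view View plane (drives the neck displacement).
#' @param offsets An [edge_offsets()].
#' @param connectivity 4 or 8.
#' @return List with elements `mask` (filtered logical matrix) and `edges`
#'   (the `brain_edges` used).
#' @export
mdc_segment <- function(mask, view = "axial", offsets = edge_offsets(),
                        connectivity = 4L) {
  mask <- as_mask(mask)
  raw <- scan_edges(mask)
  edges <- displace_edges(raw, offsets, view, dim(mask))
  list(mask = remove_external_components(mask, edges, connectivity),
       edges = edges)
}
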