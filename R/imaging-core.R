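#' Grayscale MRI slice
#'
#' A `gray_image` is a 2D matrix of intensities in \[0, 1\] (row 1 is the top
#' of the image) together with the acquisition metadata the segmentation
#' pipeline needs: the view plane and the pulse sequence. Intensities are
#' always min-max normalized, so DICOM, 8-bit and 16-bit sources behave
#' identically downstream.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\], at least 3x3.
#' @param view View plane: `"axial"`, `"coronal"` or `"sagittal"`.
#' @param sequence Pulse sequence: `"T1c"`, `"T2"` or `"FSPGR_T1c"`.
#' @return An object of class `gray_image` with elements `pixels`, `view`
#'   and `sequence`.
#' @seealso [normalize_intensity()], [read_slice()]
#' @export
gray_image <- function(pixels, view = "axial", sequence = "T2") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixels must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixels must lie in [0, 1]; use normalize_intensity()", call. = FALSE)
  structure(
    list(pixels = pixels, view = match_view(view),
         sequence = match_sequence(sequence)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, view=%s, sequence=%s, range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$view, x$sequence,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Accept either a gray_image or a bare matrix wherever only pixels matter.
as_pixels <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a gray_image or numeric matrix", call. = FALSE)
}

# Validate / coerce a binary mask to a logical matrix.
as_mask <- function(mask) {
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  if (is.matrix(mask) && is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("mask values must be exactly 0 or 1", call. = FALSE)
    return(mask > 0)
  }
  stop("expected a logical or 0/1 numeric matrix", call. = FALSE)
}

#' Min-max intensity normalization
#'
#' Rescales a raw pixel matrix linearly so the minimum maps to 0 and the
#' maximum to 1. A constant image maps to all zeros (background), never to
#' ones. MRI intensities carry no fixed tissue meaning across scanners, so
#' every slice is normalized per-slice on load.
#'
#' @param raw Numeric matrix of finite, non-negative raw intensities.
#' @return Numeric matrix with values in \[0, 1\].
#' @examples
#' normalize_intensity(matrix(c(0, 128, 255, 255), 2, 2))
#' @export
normalize_intensity <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("raw must be a 2D numeric matrix", call. = FALSE)
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("raw pixels must be finite", call. = FALSE)
  if (min(raw) < 0)
    stop("raw pixels must be non-negative", call. = FALSE)
  lo <- min(raw); hi <- max(raw)
  if (hi == lo) return(array(0, dim(raw)))
  (raw - lo) / (hi - lo)
}

#' Read a single MRI slice
#'
#' Reads a single-frame DICOM file (applying RescaleSlope/RescaleIntercept)
#' or an 8-/16-bit grayscale PNG or TIFF, then min-max normalizes the pixel
#' data. The view plane and pulse sequence are caller-supplied: DICOM
#' headers encode them inconsistently across vendors, so no automatic
#' detection is attempted.
#'
#' @param path Path to a `.dcm`, `.png`, `.tif`/`.tiff` file. Files without
#'   one of these extensions are sniffed for the DICOM magic bytes.
#' @param view,sequence Acquisition metadata, see [gray_image()].
#' @return A [gray_image()].
#' @export
read_slice <- function(path, view = "axial", sequence = "T2") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("png")) {
    read_gray_raster(png::readPNG(path), path)
  } else if (ext %in% c("tif", "tiff")) {
    read_gray_raster(tiff::readTIFF(path), path)
  } else if (ext %in% c("dcm", "dicom", "ima") || is_dicom_file(path)) {
    read_dicom_pixels(path)
  } else {
    stop("unrecognized image format: ", path, call. = FALSE)
  }
  gray_image(normalize_intensity(raw), view = view, sequence = sequence)
}

# Collapse a readPNG/readTIFF array to a single grayscale channel.
read_gray_raster <- function(arr, path) {
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L && !isTRUE(all.equal(arr[, , 1], arr[, , 2])))
      warning("color image ", path, ": using first channel", call. = FALSE)
    arr <- arr[, , 1]
  }
  if (length(dim(arr)) != 2L)
    stop("not a 2D grayscale image: ", path, call. = FALSE)
  arr
}

#' Write a binary mask as PNG
#'
#' Stores a segmentation mask losslessly as an 8-bit grayscale PNG with
#' foreground 255 and background 0; [read_mask()] inverts the encoding
#' exactly.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- read_gray_raster(png::readPNG(path), path)
  arr > 0.5
}
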