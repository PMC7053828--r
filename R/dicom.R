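# Minimal single-frame DICOM reader.
#
# Scope: uncompressed little-endian transfer syntaxes (implicit
# 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1), single-frame
# monochrome images, 8 or 16 bits allocated, signed or unsigned, with
# RescaleSlope/RescaleIntercept honored. Anything else (compressed pixel
# data, multi-frame, color) is rejected with an informative error. This
# deliberately covers only what a scanner-exported 2D MRI slice needs.

DICOM_TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

dcm_uint16 <- function(bytes, off) {
  as.integer(bytes[off + 1L]) + 256L * as.integer(bytes[off + 2L])
}
dcm_uint32 <- function(bytes, off) {
  # as double: element lengths can exceed .Machine$integer.max marker range
  sum(as.numeric(bytes[off + 1:4]) * c(1, 256, 65536, 16777216))
}

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
DICOM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

# Parse the data elements of one dataset fragment; returns a named list of
# raw values for the handful of tags the reader consumes.
read_dicom_pixels <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  off <- 0L
  explicit <- TRUE
  if (length(bytes) >= 132L && rawToChar(bytes[129:132]) == "DICM") {
    off <- 132L
    # file meta group (0002,xxxx) is always explicit little endian
    meta <- dcm_parse(bytes, off, explicit = TRUE, stop_after_group2 = TRUE)
    off <- meta$offset
    ts <- dcm_string(meta$elements[["0002,0010"]])
    if (nzchar(ts)) {
      if (ts == DICOM_TS_IMPLICIT_LE) explicit <- FALSE
      else if (ts != DICOM_TS_EXPLICIT_LE)
        stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
    }
  } else {
    # headerless stream: sniff VR bytes of the first element
    explicit <- length(bytes) >= 6L &&
      grepl("^[A-Z]{2}$", rawToChar(bytes[5:6]))
  }
  ds <- dcm_parse(bytes, off, explicit = explicit)
  el <- ds$elements

  need <- function(tag, what) {
    v <- el[[tag]]
    if (is.null(v)) stop("DICOM file lacks ", what, call. = FALSE)
    v
  }
  nframes <- el[["0028,0008"]]
  if (!is.null(nframes) && suppressWarnings(as.integer(dcm_string(nframes))) > 1L)
    stop("multi-frame DICOM is not supported", call. = FALSE)
  samples <- el[["0028,0002"]]
  if (!is.null(samples) && dcm_uint16(samples, 0L) != 1L)
    stop("only monochrome DICOM is supported", call. = FALSE)

  rows <- dcm_uint16(need("0028,0010", "Rows"), 0L)
  cols <- dcm_uint16(need("0028,0011", "Columns"), 0L)
  bits <- dcm_uint16(need("0028,0100", "BitsAllocated"), 0L)
  if (!bits %in% c(8L, 16L))
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  signed <- !is.null(el[["0028,0103"]]) && dcm_uint16(el[["0028,0103"]], 0L) == 1L
  slope <- if (is.null(el[["0028,1053"]])) 1 else as.numeric(dcm_string(el[["0028,1053"]]))
  inter <- if (is.null(el[["0028,1052"]])) 0 else as.numeric(dcm_string(el[["0028,1052"]]))

  px <- need("7fe0,0010", "PixelData")
  npix <- rows * cols
  if (length(px) < npix * bits / 8L)
    stop("PixelData shorter than Rows x Columns", call. = FALSE)
  vals <- if (bits == 8L) {
    as.numeric(px[seq_len(npix)])
  } else {
    readBin(px, "integer", n = npix, size = 2L, signed = FALSE,
            endian = "little")
  }
  if (signed && bits == 16L) vals <- ifelse(vals >= 32768, vals - 65536, vals)
  vals <- vals * slope + inter
  if (min(vals) < 0) vals <- vals - min(vals)  # shift HU-style offsets
  matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
}

# Walk data elements from `off`; store raw value bytes keyed "gggg,eeee".
dcm_parse <- function(bytes, off, explicit, stop_after_group2 = FALSE) {
  n <- length(bytes)
  elements <- list()
  while (off + 8L <= n) {
    group <- dcm_uint16(bytes, off)
    elem <- dcm_uint16(bytes, off + 2L)
    if (stop_after_group2 && group != 2L) break
    tag <- sprintf("%04x,%04x", group, elem)
    vr <- NULL
    if (explicit || group == 2L) {
      vr <- rawToChar(bytes[off + 5:6])
      if (vr %in% DICOM_LONG_VRS) {
        len <- dcm_uint32(bytes, off + 8L)
        off <- off + 12L
      } else {
        len <- dcm_uint16(bytes, off + 6L)
        off <- off + 8L
      }
    } else {
      len <- dcm_uint32(bytes, off + 4L)
      off <- off + 8L
    }
    if (len == 4294967295) {  # undefined length: sequence or encapsulation
      if (identical(tag, "7fe0,0010"))
        stop("encapsulated (compressed) PixelData is not supported",
             call. = FALSE)
      off <- dcm_skip_undefined(bytes, off)
      next
    }
    if (off + len > n)
      stop("truncated DICOM element ", tag, call. = FALSE)
    if (tag %in% c("0002,0010", "0028,0002", "0028,0008", "0028,0010",
                   "0028,0011", "0028,0100", "0028,0103", "0028,1052",
                   "0028,1053", "7fe0,0010")) {
      elements[[tag]] <- bytes[off + seq_len(len)]
    }
    off <- off + as.integer(len)
    if (identical(tag, "7fe0,0010")) break
  }
  list(elements = elements, offset = off)
}

# Skip an undefined-length sequence by scanning for its delimitation item
# (FFFE,E0DD) at any nesting depth; item delimiters (FFFE,E00D) are passed
# through. Sufficient for skipping private/icon sequences in slice exports.
dcm_skip_undefined <- function(bytes, off) {
  n <- length(bytes)
  depth <- 1L
  while (off + 8L <= n) {
    group <- dcm_uint16(bytes, off)
    elem <- dcm_uint16(bytes, off + 2L)
    len <- dcm_uint32(bytes, off + 4L)
    off <- off + 8L
    if (group == 0xFFFE && elem == 0xE0DD) {
      depth <- depth - 1L
      if (depth == 0L) return(off)
    } else if (group == 0xFFFE && elem == 0xE000) {
      if (len == 4294967295) next else off <- off + as.integer(len)
    } else if (len == 4294967295) {
      depth <- depth + 1L
    } else {
      off <- off + as.integer(len)
    }
  }
  stop("unterminated DICOM sequence", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decode a padded DICOM string value (NUL/space padded raw bytes).
dcm_string <- function(v) {
  if (is.null(v)) return("")
  trimws(rawToChar(v[v != as.raw(0L)]))
}
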