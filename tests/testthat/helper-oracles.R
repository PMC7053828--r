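# Brute-force reference implementations used as independent oracles.
# All are deliberately naive (explicit loops / literal fixpoints) and share
# no code with the package internals they check.

neighbors_of <- function(r, c, nr, nc, connectivity) {
  d <- if (connectivity == 8)
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  out <- cbind(r + d[, "dr"], c + d[, "dc"])
  out[out[, 1] >= 1 & out[, 1] <= nr & out[, 2] >= 1 & out[, 2] <= nc, ,
      drop = FALSE]
}

# geodesic reconstruction by dilation: literal fixpoint iteration
oracle_reconstruct <- function(seed, mask, connectivity = 4) {
  nr <- nrow(seed); nc <- ncol(seed)
  repeat {
    nxt <- seed
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      nb <- neighbors_of(r, c, nr, nc, connectivity)
      hi <- max(seed[r, c], seed[cbind(nb[, 1], nb[, 2])])
      nxt[r, c] <- min(hi, mask[r, c])
    }
    if (identical(nxt, seed)) return(nxt)
    seed <- nxt
  }
}

oracle_hmax <- function(img, h, connectivity = 4) {
  oracle_reconstruct(img - h, img, connectivity)
}

# regional maxima by plateau enumeration + exhaustive boundary check
oracle_regional_maxima <- function(img, connectivity = 4) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  seen <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    level <- img[r0, c0]
    # flood the equal-value plateau
    plateau <- matrix(FALSE, nr, nc)
    stack <- list(c(r0, c0)); plateau[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      nb <- neighbors_of(p[1], p[2], nr, nc, connectivity)
      for (k in seq_len(nrow(nb))) {
        if (img[nb[k, 1], nb[k, 2]] == level && !plateau[nb[k, 1], nb[k, 2]]) {
          plateau[nb[k, 1], nb[k, 2]] <- TRUE
          stack[[length(stack) + 1]] <- nb[k, ]
        }
      }
    }
    is_max <- TRUE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!plateau[r, c]) next
      nb <- neighbors_of(r, c, nr, nc, connectivity)
      if (any(img[cbind(nb[, 1], nb[, 2])] > level)) is_max <- FALSE
    }
    out[plateau] <- out[plateau] | is_max
    seen <- seen | plateau
  }
  out
}

# binary erosion/dilation with explicit offset loops;
# erosion treats out-of-image as foreground, dilation as background
oracle_erode <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- (nrow(se) - 1) / 2
  out <- matrix(TRUE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
      if (se[i, j] == 0) next
      rr <- r + i - 1 - rad; cc <- c + j - 1 - rad
      v <- if (rr < 1 || rr > nr || cc < 1 || cc > nc) TRUE else mask[rr, cc]
      if (!v) out[r, c] <- FALSE
    }
  }
  out
}

oracle_dilate <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- (nrow(se) - 1) / 2
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
      if (se[i, j] == 0) next
      rr <- r + i - 1 - rad; cc <- c + j - 1 - rad
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc])
        out[r, c] <- TRUE
    }
  }
  out
}

# hole filling by flood from the border over background
oracle_fill_holes <- function(mask, connectivity = 4) {
  bg_conn <- if (connectivity == 8) 4 else 8
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  stack <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if ((r == 1 || r == nr || c == 1 || c == nc) && !mask[r, c] && !reach[r, c]) {
      reach[r, c] <- TRUE; stack[[length(stack) + 1]] <- c(r, c)
    }
  }
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nb <- neighbors_of(p[1], p[2], nr, nc, bg_conn)
    for (k in seq_len(nrow(nb))) {
      if (!mask[nb[k, 1], nb[k, 2]] && !reach[nb[k, 1], nb[k, 2]]) {
        reach[nb[k, 1], nb[k, 2]] <- TRUE
        stack[[length(stack) + 1]] <- nb[k, ]
      }
    }
  }
  mask | !reach
}

# naive component labeling (flood fill per seed pixel)
oracle_label <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    lab[r0, c0] <- nxt
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      nb <- neighbors_of(p[1], p[2], nr, nc, connectivity)
      for (k in seq_len(nrow(nb))) {
        if (mask[nb[k, 1], nb[k, 2]] && lab[nb[k, 1], nb[k, 2]] == 0L) {
          lab[nb[k, 1], nb[k, 2]] <- nxt
          stack[[length(stack) + 1]] <- nb[k, ]
        }
      }
    }
  }
  lab
}

# mean-area filter by explicit enumeration
oracle_mean_area_filter <- function(mask, connectivity = 4) {
  lab <- oracle_label(mask, connectivity)
  n <- max(lab)
  if (n == 0) return(mask)
  areas <- sapply(seq_len(n), function(l) sum(lab == l))
  keep <- which(areas >= mean(areas))
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# external-component removal by explicit per-component corner test
oracle_remove_external <- function(mask, edges, connectivity = 4) {
  lab <- oracle_label(mask, connectivity)
  out <- mask
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    corners <- expand.grid(r = range(px[, 1]), c = range(px[, 2]))
    bad <- any(corners$r < edges$top | corners$r > edges$bottom |
                 corners$c < edges$left | corners$c > edges$right)
    if (bad) out[lab == l] <- FALSE
  }
  out
}

# seeded random test images
random_gray <- function(seed, nr = 8, nc = nr, levels = 10) {
  set.seed(seed)
  matrix(sample(0:(levels - 1), nr * nc, replace = TRUE) / levels, nr, nc)
}

random_blobs <- function(seed, nr = 16, nc = nr, p = 0.35) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}

small_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, size = 160, ...))
}

# Minimal DICOM writer (explicit VR little endian) for reader tests.
write_test_dicom <- function(path, pixels, slope = 1, intercept = 0,
                             bits = 16L, extra = list()) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  el_short <- function(g, e, vr, val) {
    u16(g); u16(e); writeChar(vr, con, eos = NULL)
    u16(length(val)); writeBin(val, con)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con); writeChar("DICM", con, eos = NULL)
  ts <- c(charToRaw("1.2.840.10008.1.2.1"), as.raw(0))
  el_short(0x0002, 0x0010, "UI", ts)
  el_us <- function(g, e, v) { u16(g); u16(e); writeChar("US", con, eos = NULL); u16(2); u16(v) }
  el_ds <- function(g, e, s) {
    b <- charToRaw(if (nchar(s) %% 2) paste0(s, " ") else s)
    el_short(g, e, "DS", b)
  }
  el_us(0x0028, 0x0002, 1L)                       # SamplesPerPixel
  for (nm in names(extra)) {
    x <- extra[[nm]]
    el_short(x$g, x$e, x$vr, x$val)
  }
  el_us(0x0028, 0x0010, nrow(pixels))             # Rows
  el_us(0x0028, 0x0011, ncol(pixels))             # Columns
  el_us(0x0028, 0x0100, bits)                     # BitsAllocated
  el_us(0x0028, 0x0103, 0L)                       # PixelRepresentation
  el_ds(0x0028, 0x1052, as.character(intercept))
  el_ds(0x0028, 0x1053, as.character(slope))
  vals <- as.integer(t(pixels))                   # row-major order
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0)
  writeBin(as.integer(length(vals) * bits / 8), con, size = 4, endian = "little")
  if (bits == 16L) u16(vals) else writeBin(as.raw(vals), con)
  invisible(path)
}
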