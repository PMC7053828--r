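#' Synthetic head-phantom specification
#'
#' Describes one synthetic MRI head slice: a centered brain ellipse of
#' mid-intensity noisy tissue surrounded by a bright skull annulus on a
#' black background, with a hyperintense tumor disk (the gold standard),
#' optional bright ventricle slivers (CSF-like confounders typical of T2
#' slices) and, for coronal/sagittal views, a neck protrusion below the
#' skull. Geometry is axis-aligned and rasterized at pixel centers —
#' the segmentation pipeline depends only on topology and contrast, not on
#' anatomical realism.
#'
#' Per-sequence defaults follow the acquisition classes the pipeline
#' targets: output size 256 (T2), 512 (FSPGR T1c) or 704 (T1c) pixels
#' square, and a markedly reduced tumor/brain contrast for T1c (tumor 0.55
#' vs brain 0.40), where tumor tissue renders close to normal brain, versus
#' the well-contrasted T2/FSPGR classes (tumor 0.90 vs brain 0.35).
#'
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @param sequence `"T1c"`, `"T2"` or `"FSPGR_T1c"`.
#' @param size Output resolution (square, pixels); `NULL` uses the
#'   sequence default.
#' @param tumor_center `c(row, col)` in pixels, or `NULL` for an automatic
#'   off-center position inside the brain.
#' @param tumor_radius Tumor disk radius in pixels; `NULL` scales 8% of the
#'   image size. Use `0` for a tumor-free slice (empty gold mask).
#' @param tumor_intensity,brain_intensity,skull_intensity Intensities in
#'   \[0, 1\]; tumor must exceed brain (hyperintense lesions only).
#' @param add_ventricles Add two thin bright slivers near the brain center.
#' @param add_neck Add the neck protrusion; `NULL` means on exactly for
#'   coronal/sagittal views (it is forced on for those views regardless).
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   brain and neck tissue (intensity units; result clipped to \[0, 1\]).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1L, view = "axial", sequence = "T2",
                         size = NULL, tumor_center = NULL,
                         tumor_radius = NULL, tumor_intensity = NULL,
                         brain_intensity = NULL, skull_intensity = 0.85,
                         add_ventricles = FALSE, add_neck = NULL,
                         noise_sd = 0.03) {
  view <- match_view(view)
  sequence <- match_sequence(sequence)
  if (is.null(size)) size <- SEQUENCE_SIZES[[sequence]]
  size <- as.integer(size)
  if (size < 32L) stop("phantom size must be >= 32 pixels", call. = FALSE)
  if (is.null(brain_intensity))
    brain_intensity <- if (sequence == "T1c") 0.40 else 0.35
  if (is.null(tumor_intensity))
    tumor_intensity <- if (sequence == "T1c") 0.55 else 0.90
  if (tumor_intensity <= brain_intensity)
    stop("tumor must be hyperintense: tumor_intensity > brain_intensity",
         call. = FALSE)
  if (is.null(tumor_radius)) tumor_radius <- round(0.08 * size)
  if (is.null(add_neck)) add_neck <- view != "axial"
  add_neck <- add_neck || view != "axial"
  structure(
    list(seed = as.integer(seed), view = view, sequence = sequence,
         size = size, tumor_center = tumor_center,
         tumor_radius = as.integer(tumor_radius),
         tumor_intensity = tumor_intensity,
         brain_intensity = brain_intensity,
         skull_intensity = skull_intensity,
         add_ventricles = isTRUE(add_ventricles), add_neck = add_neck,
         noise_sd = noise_sd),
    class = "phantom_spec"
  )
}

# TRUE inside the axis-aligned ellipse centered at (cy, cx), semi-axes (ry, rx)
ellipse_mask <- function(size, cy, cx, ry, rx) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
}

#' Generate a synthetic head slice with its gold tumor mask
#'
#' Deterministic for a fixed spec (seed included). The tumor disk and the
#' skull annulus are constant-intensity plateaus; Gaussian noise is applied
#' to brain and neck tissue only, so the tumor remains the dominant
#' hyperintense plateau inside the brain — the structural premise the
#' coordinate and area detectors rely on.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [gray_image()]) and `gold` (logical mask of
#'   exactly the tumor pixels).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  n <- spec$size
  # head geometry: shift the head up a little when a neck is present
  cy <- if (spec$add_neck) round(0.44 * n) else round(0.50 * n)
  cx <- round(0.50 * n)
  skull_ry <- 0.42 * n; skull_rx <- 0.38 * n
  skull_thickness <- max(3, round(0.03 * n))
  brain_ry <- skull_ry - skull_thickness
  brain_rx <- skull_rx - skull_thickness

  skull_outer <- ellipse_mask(n, cy, cx, skull_ry, skull_rx)
  brain <- ellipse_mask(n, cy, cx, brain_ry, brain_rx)
  skull <- skull_outer & !brain

  neck <- matrix(FALSE, n, n)
  if (spec$add_neck) {
    neck_top <- round(cy + 0.8 * skull_ry)
    neck_bottom <- min(n, round(0.97 * n))
    half_w <- round(0.12 * n)
    if (neck_bottom > neck_top)
      neck[neck_top:neck_bottom, max(1, cx - half_w):min(n, cx + half_w)] <- TRUE
    neck <- neck & !skull_outer
  }

  # tumor: a disk strictly inside the brain ellipse, off-center by default
  tc <- spec$tumor_center
  if (is.null(tc)) tc <- c(round(cy - 0.25 * brain_ry), round(cx + 0.30 * brain_rx))
  gold <- matrix(FALSE, n, n)
  if (spec$tumor_radius > 0L) {
    gold <- ellipse_mask(n, tc[1], tc[2], spec$tumor_radius, spec$tumor_radius)
    shrunk <- ellipse_mask(n, cy, cx, brain_ry - 2, brain_rx - 2)
    if (any(gold & !shrunk))
      stop("invalid phantom spec: tumor extends outside the brain", call. = FALSE)
  }

  ventricles <- matrix(FALSE, n, n)
  if (spec$add_ventricles) {
    for (s in c(-1, 1)) {
      v <- ellipse_mask(n, cy, cx + s * round(0.10 * n),
                        0.10 * n, max(2, 0.015 * n))
      ventricles <- ventricles | v
    }
    ventricles <- ventricles & brain & !gold
  }

  img <- matrix(0, n, n)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  tissue <- (brain | neck) & !gold & !ventricles
  img[tissue] <- spec$brain_intensity + rnorm(sum(tissue), 0, spec$noise_sd)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  img[skull] <- spec$skull_intensity
  img[ventricles] <- min(1, spec$tumor_intensity + 0.05)
  img[gold] <- spec$tumor_intensity
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(n, n)

  list(image = gray_image(img, view = spec$view, sequence = spec$sequence),
       gold = gold)
}

#' Generate a reproducible suite of phantoms
#'
#' Produces `n` phantom slices with per-slice seeds derived from
#' `base_seed`, cycling views, drawing sequences with the given mix, and
#' making a fixed fraction tumor-free (empty gold mask), mirroring an
#' evaluation set that pairs every tumor slice with a tumor-free one.
#' Tumor position and radius are jittered per slice.
#'
#' @param n Number of slices (>= 1).
#' @param base_seed Integer seed controlling the whole suite.
#' @param mix Named numeric vector of sequence proportions; the default
#'   reflects a T1c-light, FSPGR-heavy clinical archive.
#' @param views Views to cycle through.
#' @param tumor_free_fraction Fraction of slices generated without a tumor
#'   (`floor(n * fraction)` slices, deterministically placed).
#' @param add_ventricles_fraction Fraction of slices given ventricle
#'   confounders.
#' @return List of records, each with `image`, `gold`, `spec`.
#' @export
generate_phantom_suite <- function(n, base_seed = 1L,
                                   mix = c(T1c = 0.15, T2 = 0.37,
                                           FSPGR_T1c = 0.48),
                                   views = MRI_VIEWS,
                                   tumor_free_fraction = 0,
                                   add_ventricles_fraction = 0) {
  stopifnot(n >= 1L)
  mix <- mix / sum(mix)
  seqs <- rep(names(mix), times = diff(round(cumsum(c(0, mix)) * n)))
  if (length(seqs) < n) seqs <- c(seqs, rep(names(mix)[which.max(mix)],
                                            n - length(seqs)))
  n_free <- floor(n * tumor_free_fraction)
  free <- rep(FALSE, n)
  if (n_free > 0L) {
    idx <- unique(round(seq(1, n, length.out = n_free)))
    while (length(idx) < n_free) idx <- union(idx, setdiff(seq_len(n), idx)[1L])
    free[idx] <- TRUE
  }
  n_vent <- floor(n * add_ventricles_fraction)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(base_seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sz <- SEQUENCE_SIZES[[seqs[i]]]
    jitter_r <- round(runif(1, 0.06, 0.10) * sz)
    ang <- runif(1, 0, 2 * pi)
    rad <- runif(1, 0.1, 0.45)
    spec <- phantom_spec(
      seed = base_seed * 1000L + i, view = views[(i - 1L) %% length(views) + 1L],
      sequence = seqs[i], tumor_radius = if (free[i]) 0L else jitter_r,
      add_ventricles = i <= n_vent)
    # jitter the tumor center within the brain (polar draw around center)
    cy <- if (spec$add_neck) round(0.44 * sz) else round(0.50 * sz)
    spec$tumor_center <- c(round(cy + rad * 0.30 * sz * sin(ang)),
                           round(0.5 * sz + rad * 0.26 * sz * cos(ang)))
    out[[i]] <- c(generate_phantom(spec), list(spec = spec))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  out
}
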