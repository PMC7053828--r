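#' Full pipeline configuration
#'
#' Bundles the stage configurations in processing order: pre-processing
#' (equalization, maxima suppression, binarization), coordinate detection
#' (edge offsets), area detection (erosion + mean-area filter),
#' post-processing (dilation, hole fill) and the evaluation overlap
#' threshold.
#'
#' @param preprocess A [preprocess_config()].
#' @param offsets An [edge_offsets()].
#' @param mda An [mda_config()].
#' @param post A [postprocess_config()].
#' @param min_overlap Per-component Dice threshold used by [judge_slice()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            offsets = edge_offsets(), mda = mda_config(),
                            post = postprocess_config(), min_overlap = 0.1) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(offsets, "edge_offsets"), inherits(mda, "mda_config"),
            inherits(post, "postprocess_config"),
            min_overlap > 0, min_overlap <= 1)
  structure(list(preprocess = preprocess, offsets = offsets, mda = mda,
                 post = post, min_overlap = min_overlap),
            class = "pipeline_config")
}

#' Segment one MRI slice
#'
#' Runs the full automatic segmentation in stage order: binarization
#' (equalization, h-maxima suppression, regional maxima), detection by
#' coordinates (skull stripping), detection by area (erosion + mean-area
#' filter), then dilation, hole filling and masking of the original slice.
#' Deterministic for a fixed input and configuration. If the edge scan
#' finds no foreground near the image center the result degrades to an
#' empty mask with a warning instead of an error, so batch runs survive
#' pathological slices.
#'
#' @param img A [gray_image()] (see [read_slice()]).
#' @param cfg A [pipeline_config()].
#' @return A `segmentation_result` list: `tumor_mask` (logical matrix),
#'   `masked_image` ([gray_image()] with original intensities inside the
#'   mask), `edges` (`brain_edges` or `NULL` on failure) and `stage_log`
#'   (data.frame of per-stage foreground pixel and component counts).
#' @export
segment_slice <- function(img, cfg = pipeline_config()) {
  stopifnot(inherits(img, "gray_image"))
  conn <- cfg$preprocess$connectivity
  log_rows <- list()
  note <- function(stage, mask) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, pixels = sum(mask),
      components = max(label_components_cpp(mask, conn)))
  }

  roi <- binarize(img, cfg$preprocess)
  note("binarize", roi)

  edges <- NULL
  mdc_mask <- tryCatch({
    res <- mdc_segment(roi, img$view, cfg$offsets, conn)
    edges <- res$edges
    res$mask
  }, error = function(e) {
    warning("edge detection failed (", conditionMessage(e),
            "); returning empty segmentation", call. = FALSE)
    NULL
  })
  if (is.null(mdc_mask)) {
    empty <- matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
    return(structure(list(tumor_mask = empty,
                          masked_image = apply_mask(img, empty),
                          edges = NULL,
                          stage_log = do.call(rbind, log_rows)),
                     class = "segmentation_result"))
  }
  note("mdc", mdc_mask)
  if (!any(mdc_mask))
    warning("no components inside the brain rectangle; segmentation is empty",
            call. = FALSE)

  mda_in <- erode_mask(mdc_mask, cfg$mda)
  if (!any(mda_in) && any(mdc_mask)) {
    warning("erosion removed the whole mask; skipping erosion", call. = FALSE)
    mda_in <- mdc_mask
  }
  note("erode", mda_in)
  mda_mask <- mean_area_filter(mda_in, cfg$mda$connectivity)
  note("mda", mda_mask)

  post_cfg <- cfg$post
  if (is.null(post_cfg$dilation_radius))  # symmetric recovery of the erosion
    post_cfg$dilation_radius <- resolve_radius(cfg$mda$erosion_radius,
                                               ncol(img$pixels))
  dilated <- dilate_mask(mda_mask, post_cfg)
  note("dilate", dilated)
  filled <- fill_holes(dilated, conn)
  note("fill_holes", filled)

  structure(list(tumor_mask = filled, masked_image = apply_mask(img, filled),
                 edges = edges, stage_log = do.call(rbind, log_rows)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  print(x$stage_log)
  invisible(x)
}

#' Segment a batch of slices listed in a manifest
#'
#' The manifest is a CSV with columns `path`, `view`, `sequence` and
#' optionally `gold` (path to a gold-standard mask PNG). Every slice is
#' segmented; rows whose image cannot be read are recorded as errors and
#' the batch continues. When gold masks are present the per-sequence
#' evaluation table is computed via [aggregate_judgements()].
#'
#' @param manifest Path to the manifest CSV, or a data.frame with the same
#'   columns. Relative paths resolve against the manifest's directory.
#' @param cfg A [pipeline_config()].
#' @param out_dir If non-`NULL`, the tumor mask of row `i` is written to
#'   `<out_dir>/mask_<i>.png` and the evaluation table (if any) to
#'   `<out_dir>/evaluation.csv`.
#' @return List with `results` (per-row `segmentation_result` or error
#'   message), `judgements` (when gold masks were given) and `table` (the
#'   evaluation data.frame, or `NULL`).
#' @export
run_batch <- function(manifest, cfg = pipeline_config(), out_dir = NULL) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("path", "view", "sequence") %in% names(manifest)))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  results <- vector("list", nrow(manifest))
  judgements <- list(); jseq <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- read_slice(resolve(row$path), row$view, row$sequence)
      segment_slice(img, cfg)
    }, error = function(e) conditionMessage(e))
    results[[i]] <- res
    if (!inherits(res, "segmentation_result")) next
    if (!is.null(out_dir))
      write_mask(res$tumor_mask, file.path(out_dir, sprintf("mask_%03d.png", i)))
    if (!is.null(manifest$gold) && !is.na(row$gold) && nzchar(row$gold)) {
      gold <- read_mask(resolve(row$gold))
      judgements[[length(judgements) + 1L]] <-
        judge_slice(res$tumor_mask, gold, cfg$min_overlap,
                    cfg$preprocess$connectivity)
      jseq <- c(jseq, row$sequence)
    }
  }
  tab <- NULL
  if (length(judgements)) {
    tab <- aggregate_judgements(judgements, jseq)
    if (!is.null(out_dir))
      write.csv(tab, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  }
  list(results = results, judgements = judgements, table = tab)
}

#' Read a pipeline configuration from a key = value text file
#'
#' Recognized keys: `n_bins`, `h_dark`, `h_bright`, `brightness_split`,
#' `connectivity`, `use_minima`, `d_left`, `d_right`, `d_top`, `d_bottom`,
#' `neck_extra`, `erosion_radius`, `selem_shape`, `dilation_radius`,
#' `min_overlap`. Unset keys keep their defaults; `#` starts a comment.
#'
#' @param path Path to the configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  vals <- character(0)
  if (length(lines)) {
    kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
    vals <- stats::setNames(trimws(kv[, 2]), trimws(kv[, 1]))
  }
  num <- function(key, default) if (key %in% names(vals))
    as.numeric(vals[[key]]) else default
  chr <- function(key, default) if (key %in% names(vals))
    vals[[key]] else default
  flag <- function(key, default) if (key %in% names(vals))
    tolower(vals[[key]]) %in% c("true", "1", "yes") else default
  conn <- as.integer(num("connectivity", 4L))
  shape <- chr("selem_shape", "disk")
  er <- num("erosion_radius", NA)
  dr <- num("dilation_radius", NA)
  pipeline_config(
    preprocess = preprocess_config(
      n_bins = as.integer(num("n_bins", 64L)),
      h_dark = num("h_dark", 0.30), h_bright = num("h_bright", 0.55),
      brightness_split = num("brightness_split", 0.5),
      connectivity = conn, use_minima = flag("use_minima", FALSE)),
    offsets = edge_offsets(
      d_left = num("d_left", 0.04), d_right = num("d_right", 0.04),
      d_top = num("d_top", 0.04), d_bottom = num("d_bottom", 0.04),
      neck_extra = num("neck_extra", 0.12)),
    mda = mda_config(erosion_radius = if (is.na(er)) NULL else er,
                     selem_shape = shape, connectivity = conn),
    post = postprocess_config(dilation_radius = if (is.na(dr)) NULL else dr,
                              selem_shape = shape),
    min_overlap = num("min_overlap", 0.1))
}

#' Write a phantom suite to disk with a batch manifest
#'
#' Renders each phantom slice and its gold mask as PNG pairs and writes a
#' manifest CSV (`path`, `view`, `sequence`, `seed`, `has_tumor`, `gold`)
#' directly consumable by [run_batch()].
#'
#' @param suite Output of [generate_phantom_suite()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_phantom_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(suite), function(i) {
    rec <- suite[[i]]
    img_path <- sprintf("phantom_%03d.png", i)
    gold_path <- sprintf("gold_%03d.png", i)
    png::writePNG(rec$image$pixels, file.path(dir, img_path))
    write_mask(rec$gold, file.path(dir, gold_path))
    data.frame(path = img_path, view = rec$spec$view,
               sequence = rec$spec$sequence, seed = rec$spec$seed,
               has_tumor = any(rec$gold), gold = gold_path)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
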