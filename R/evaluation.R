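#' Evaluation counts
#'
#' Detection counts over a set of slices: the number of gold-standard
#' tumor slices (`GS`), true positives (`TP`), false positives (`FP`) and
#' false negatives (`FN`). Note that `GS = TP + FN` is deliberately not
#' enforced: published per-sequence tallies of this kind do not always
#' satisfy it, and the metrics below depend only on GS, TP and FP.
#'
#' @param GS,TP,FP,FN Non-negative counts, `TP <= GS`.
#' @return An `eval_counts` list.
#' @export
eval_counts <- function(GS, TP, FP = 0L, FN = 0L) {
  if (any(c(GS, TP, FP, FN) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (TP > GS) stop("TP cannot exceed GS", call. = FALSE)
  structure(list(GS = GS, TP = TP, FP = FP, FN = FN), class = "eval_counts")
}

#' Hit rate
#'
#' The detection rate `HR = TP / GS * 100` (percent). Returned at full
#' precision; for tabular display the field convention truncates (not
#' rounds) to two decimals, see [display_hr()].
#'
#' @param c An [eval_counts()] with `GS > 0`.
#' @return Percentage in \[0, 100\].
#' @export
hit_rate <- function(c) {
  if (c$GS <= 0) stop("hit rate undefined for GS = 0", call. = FALSE)
  c$TP / c$GS * 100
}

#' Matching rate
#'
#' The false-positive-penalized agreement `MR = (TP - 0.5 * FP) / GS`.
#' The ideal value is 1, a perfect match with the gold standard; values
#' near 1 mean true positives far outnumber false positives. Returned at
#' full precision; displayed rounded to two decimals, see [display_mr()].
#'
#' @param c An [eval_counts()] with `GS > 0`.
#' @return Ratio (can be negative when FP is large).
#' @export
matching_rate <- function(c) {
  if (c$GS <= 0) stop("matching rate undefined for GS = 0", call. = FALSE)
  (c$TP - 0.5 * c$FP) / c$GS
}

#' Display conventions for the evaluation table
#'
#' `display_hr()` truncates the hit rate to two decimals (91.8367 -> 91.83);
#' `display_mr()` rounds the matching rate to two decimals. These are the
#' conventions used in the per-sequence results table; internal values stay
#' at full precision.
#'
#' @param x Numeric value(s).
#' @return Numeric, reduced to two decimals.
#' @export
display_hr <- function(x) trunc(x * 100 + 1e-9) / 100

#' @rdname display_hr
#' @export
display_mr <- function(x) round(x, 2)

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`, defined as 1 when both masks are empty.
#'
#' @param a,b Logical (or 0/1) matrices of equal shape.
#' @return Value in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

#' Judge one segmented slice against its gold standard
#'
#' Component-wise scoring: the slice is a true positive if some predicted
#' connected component overlaps the gold mask with Dice at least
#' `min_overlap`; a false negative if the gold mask is non-empty and no
#' component does; and every predicted component with zero gold overlap
#' counts one false positive. `overlap` is the whole-mask Dice.
#'
#' @param pred,gold Logical (or 0/1) matrices of equal shape.
#' @param min_overlap Minimum per-component Dice for a true positive.
#' @param connectivity 4 or 8 for the predicted components.
#' @return A `slice_judgement` list: `tp`, `fn` (flags), `fp_count`,
#'   `overlap`.
#' @export
judge_slice <- function(pred, gold, min_overlap = 0.1, connectivity = 4L) {
  pred <- as_mask(pred); gold <- as_mask(gold)
  if (!identical(dim(pred), dim(gold)))
    stop("mask shapes differ", call. = FALSE)
  ct <- label_components(pred, connectivity)
  n <- length(ct$areas)
  gold_area <- sum(gold)
  tp <- FALSE; fp_count <- 0L
  if (n > 0L) {
    inter <- tabulate(ct$labels[gold & ct$labels > 0L], nbins = n)
    comp_dice <- 2 * inter / (ct$areas + gold_area)
    tp <- any(comp_dice >= min_overlap)
    fp_count <- sum(inter == 0L)
  }
  structure(list(tp = tp, fn = gold_area > 0L && !tp, fp_count = fp_count,
                 overlap = dice_coefficient(pred, gold)),
            class = "slice_judgement")
}

#' Aggregate slice judgements into a per-sequence results table
#'
#' Sums the per-slice judgements into [eval_counts()] per pulse sequence
#' plus a `Total` row, and derives the hit and matching rates for each row
#' (HR truncated, MR rounded to two decimals per the display convention).
#' `GS` counts the slices whose gold mask was non-empty (`tp` or `fn`).
#'
#' @param judgements List of `slice_judgement` objects.
#' @param sequences Character vector of pulse-sequence labels, one per
#'   judgement.
#' @return A `data.frame` with columns `sequence`, `GS`, `TP`, `FP`, `FN`,
#'   `HR`, `MR`; rows with `GS = 0` carry `NA` rates.
#' @export
aggregate_judgements <- function(judgements, sequences) {
  if (length(judgements) == 0L) stop("no judgements to aggregate", call. = FALSE)
  if (length(sequences) != length(judgements))
    stop("one sequence label per judgement required", call. = FALSE)
  one_row <- function(js, label) {
    tp <- sum(vapply(js, `[[`, logical(1), "tp"))
    fn <- sum(vapply(js, `[[`, logical(1), "fn"))
    fp <- sum(vapply(js, `[[`, integer(1), "fp_count"))
    gs <- tp + fn
    cnt <- if (gs > 0) eval_counts(gs, tp, fp, fn) else NULL
    data.frame(sequence = label, GS = gs, TP = tp, FP = fp, FN = fn,
               HR = if (is.null(cnt)) NA_real_ else display_hr(hit_rate(cnt)),
               MR = if (is.null(cnt)) NA_real_ else display_mr(matching_rate(cnt)))
  }
  seqs <- unique(sequences)
  rows <- lapply(seqs, function(s) one_row(judgements[sequences == s], s))
  rows <- c(rows, list(one_row(judgements, "Total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
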