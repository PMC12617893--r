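#' Intersection over union of two intervals
#'
#' The number of residues in the intersection of two half-open intervals
#' divided by the number in their union:
#' `max(min(endA, endB) - max(startA, startB), 0) /
#'  (max(endA, endB) - min(startA, startB))`.
#' Vectorized over its arguments.
#'
#' @param a_start,a_end,b_start,b_end interval bounds (0-based
#'   half-open).
#' @return numeric in `[0, 1]`.
#' @export
iou <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(pmin(a_end, b_end) - pmax(a_start, b_start), 0)
  union <- pmax(a_end, b_end) - pmin(a_start, b_start)
  ifelse(union > 0, inter / union, 0)
}

#' Filter annotations into the positive evaluation set
#'
#' Keeps annotations at least 30 residues long that do not span the
#' entire protein, from proteins at least 60 residues long — the
#' positive set definition used for segmentation benchmarking.
#'
#' @param annotations annotation `data.frame`.
#' @param protein_lengths named integer vector of protein lengths.
#' @param min_length minimum annotation length (inclusive, default 30).
#' @param min_protein_length minimum protein length (inclusive, default
#'   60).
#' @return the filtered annotation `data.frame`.
#' @export
filter_positives <- function(annotations, protein_lengths,
                             min_length = 30L, min_protein_length = 60L) {
  if (nrow(annotations) == 0) return(annotations)
  L <- protein_lengths[annotations$protein_id]
  if (any(is.na(L))) {
    stop("missing protein length for: ",
         paste(unique(annotations$protein_id[is.na(L)]), collapse = ", "))
  }
  len <- annotations$end - annotations$start
  keep <- len >= min_length & len < L & L >= min_protein_length
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best IoU of each interval in `a` against any interval in `b` on the
# same protein (0 when the protein has none). Returns the best values
# and the index into b of the best partner (NA when no overlap at all).
best_iou_per_side <- function(a, b) {
  n <- nrow(a)
  best <- numeric(n)
  partner <- rep(NA_integer_, n)
  if (n == 0) return(list(best = best, partner = partner))
  b_idx_by_prot <- split(seq_len(nrow(b)), b$protein_id)
  for (i in seq_len(n)) {
    idx <- b_idx_by_prot[[a$protein_id[i]]]
    if (is.null(idx)) next
    v <- iou(a$start[i], a$end[i], b$start[idx], b$end[idx])
    j <- order(-v, b$start[idx])[1]   # ties: earlier start
    best[i] <- v[j]
    if (v[j] > 0) partner[i] <- idx[j]
  }
  list(best = best, partner = partner)
}

#' Evaluate predicted segments against positive annotations
#'
#' Matching is "best IoU per side", not one-to-one assignment:
#' `aiou_pred` is the mean over predictions of each prediction's best
#' IoU against any positive on the same protein, `aiou_pos` the
#' symmetric quantity for positives. A prediction whose best IoU reaches
#' `iou_threshold` is a true positive; precision and recall follow. An
#' empty prediction set yields `precision = NA` and `recall = 0`.
#'
#' @param pred,pos segment-like `data.frame`s (`protein_id`, `start`,
#'   `end`).
#' @param iou_threshold IoU at or above which a match counts (default
#'   0.5).
#' @return a list of class `"zps_eval"` with `n_pred`, `n_pos`,
#'   `aiou_pred`, `aiou_pos`, `precision`, `recall`, `unpaired_pos`
#'   (positives with no overlapping prediction at all) and `matches`
#'   (per-positive best partner and IoU).
#' @export
evaluate_segmentation <- function(pred, pos, iou_threshold = 0.5) {
  n_pred <- nrow(pred)
  n_pos <- nrow(pos)
  pred_side <- best_iou_per_side(pred, pos)
  pos_side <- best_iou_per_side(pos, pred)
  matches <- data.frame(
    pos_index = seq_len(n_pos),
    pred_index = pos_side$partner,
    iou = pos_side$best
  )
  structure(list(
    n_pred = n_pred,
    n_pos = n_pos,
    aiou_pred = if (n_pred > 0) mean(pred_side$best) else NA_real_,
    aiou_pos = if (n_pos > 0) mean(pos_side$best) else NA_real_,
    precision = if (n_pred > 0) mean(pred_side$best >= iou_threshold) else NA_real_,
    recall = if (n_pos > 0) mean(pos_side$best >= iou_threshold) else 0,
    unpaired_pos = sum(pos_side$best == 0),
    iou_threshold = iou_threshold,
    matches = matches
  ), class = "zps_eval")
}

#' @export
print.zps_eval <- function(x, ...) {
  cat(sprintf(
    "segmentation evaluation: %d predicted / %d positive segments\n",
    x$n_pred, x$n_pos))
  cat(sprintf("  AIoU(pred) = %.3f  AIoU(pos) = %.3f\n", x$aiou_pred, x$aiou_pos))
  cat(sprintf("  precision = %s  recall = %.3f  (IoU >= %.2f)\n",
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              x$recall, x$iou_threshold))
  cat(sprintf("  unpaired positives: %d\n", x$unpaired_pos))
  invisible(x)
}

#' Boundary-distance evaluation
#'
#' Each positive annotation is paired with the overlapping prediction of
#' highest IoU (any overlap counts; ties broken by earlier start). The
#' start-to-start and end-to-end distances each contribute one boundary
#' to the within-tolerance percentage, counted as a hit when the
#' distance is strictly less than `tol` residues. Positives with no
#' overlapping prediction ("unpaired") contribute their two boundaries
#' as misses, so the denominator is always `2 * n_pos` and the measure
#' is relative to the total number of annotations.
#'
#' @param pred,pos segment-like `data.frame`s.
#' @param tol distance tolerance in residues (strict `<`, default 10).
#' @return list with `n_pos`, `n_unpaired`, `n_boundaries`
#'   (`= 2 * n_pos`), `n_within`, `fraction_within` and `pct_within`
#'   (`= 100 * fraction`).
#' @export
boundary_distance_eval <- function(pred, pos, tol = 10L) {
  n_pos <- nrow(pos)
  side <- best_iou_per_side(pos, pred)
  paired <- !is.na(side$partner)
  n_within <- 0L
  if (any(paired)) {
    p <- side$partner[paired]
    d_start <- abs(pos$start[paired] - pred$start[p])
    d_end <- abs(pos$end[paired] - pred$end[p])
    n_within <- sum(d_start < tol) + sum(d_end < tol)
  }
  list(
    n_pos = n_pos,
    n_unpaired = sum(!paired),
    n_boundaries = 2L * n_pos,
    n_within = n_within,
    fraction_within = if (n_pos > 0) n_within / (2 * n_pos) else NA_real_,
    pct_within = if (n_pos > 0) 100 * n_within / (2 * n_pos) else NA_real_
  )
}

#' Deduplicate overlapping scored predictions
#'
#' External tools can emit multiple near-identical predictions. Among
#' pairs with IoU strictly above `iou_threshold`, the worse-scoring
#' member is removed, greedily from the best-scoring prediction down
#' (higher-better for profile scores, lower-better for e-/p-values).
#'
#' @param pred segment-like `data.frame` with a `score` column.
#' @param iou_threshold overlap above which two predictions are
#'   considered duplicates (default 0.5, strict `>`).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return the surviving predictions, in the original row order.
#' @export
dedupe_overlapping_predictions <- function(pred, iou_threshold = 0.5,
                                           direction = c("higher_better",
                                                         "lower_better")) {
  direction <- match.arg(direction)
  if (nrow(pred) == 0) return(pred)
  if (!"score" %in% names(pred) || any(is.na(pred$score))) {
    stop("dedupe requires a score for every prediction")
  }
  key <- if (direction == "higher_better") -pred$score else pred$score
  ord <- order(key, pred$protein_id, pred$start)   # best first, ties stable
  keep <- logical(nrow(pred))
  for (i in ord) {
    kept <- which(keep & pred$protein_id == pred$protein_id[i])
    if (length(kept) > 0) {
      v <- iou(pred$start[i], pred$end[i], pred$start[kept], pred$end[kept])
      if (any(v > iou_threshold)) next
    }
    keep[i] <- TRUE
  }
  out <- pred[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision and recall at k predictions
#'
#' Predictions are ranked by score (ties broken deterministically by
#' protein and start); for every prefix size `k = 1..n_pred` the
#' precision and recall of the top-k subset are computed with
#' [evaluate_segmentation()]. Reported this way because score
#' distributions of the compared tools are heavy-tailed, and because
#' recall does not reach 1 even as precision nears 0: no segmentation
#' method proposes all possible segments.
#'
#' @param pred scored segment-like `data.frame`.
#' @param pos positive segment-like `data.frame`.
#' @param iou_threshold IoU threshold for a true positive (default 0.5).
#' @param direction score direction, as in
#'   [dedupe_overlapping_predictions()].
#' @return `data.frame` with columns `k`, `precision`, `recall`.
#' @export
pr_at_k <- function(pred, pos, iou_threshold = 0.5,
                    direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (nrow(pred) == 0) return(data.frame(k = integer(0), precision = numeric(0),
                                         recall = numeric(0)))
  if (!"score" %in% names(pred) || any(is.na(pred$score))) {
    stop("pr_at_k requires a score for every prediction")
  }
  key <- if (direction == "higher_better") -pred$score else pred$score
  ord <- order(key, pred$protein_id, pred$start)
  ranked <- pred[ord, , drop = FALSE]
  out <- lapply(seq_len(nrow(ranked)), function(k) {
    ev <- evaluate_segmentation(ranked[seq_len(k), , drop = FALSE], pos,
                                iou_threshold)
    data.frame(k = k, precision = ev$precision, recall = ev$recall)
  })
  do.call(rbind, out)
}
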