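#' Nearest-neighbour policy
#'
#' Controls the exclusion rules of the 1-nn assessments. For
#' protein-level labels predictions must come from a different protein
#' (every segment of a protein shares such labels); for segment-level
#' labels matches from the same protein are allowed so long as the two
#' segments are not adjacent along the sequence. When the raw nearest
#' neighbour is excluded, the next nearest admissible one is selected.
#' "Adjacent" means sharing an endpoint coordinate on the same protein.
#'
#' @param exclude `"protein"` (no same-protein predictions) or
#'   `"adjacent"` (same protein allowed unless adjacent).
#' @return a list of class `"nn_policy"`.
#' @export
nn_policy <- function(exclude = c("adjacent", "protein")) {
  exclude <- match.arg(exclude)
  structure(list(exclude = exclude), class = "nn_policy")
}

# Cosine-similarity matrix with exclusions applied as -Inf.
# segments provides protein_id/start/end metadata for the exclusions.
masked_similarity <- function(E, segments, policy) {
  S <- cosine_similarity_matrix(E)
  diag(S) <- -Inf                       # a segment never predicts itself
  same_prot <- outer(segments$protein_id, segments$protein_id, "==")
  if (policy$exclude == "protein") {
    S[same_prot] <- -Inf
  } else {
    touching <- outer(segments$end, segments$start, "==") |
      outer(segments$start, segments$end, "==")
    S[same_prot & touching] <- -Inf
  }
  S
}

#' Nearest neighbour of every segment in a corpus
#'
#' Exact all-by-all cosine search with the policy's exclusion rules.
#'
#' @param E numeric matrix of segment embeddings (one row per segment).
#' @param segments segment `data.frame` aligned with the rows of `E`.
#' @param policy an [nn_policy()].
#' @return integer vector: for each row, the index of its admissible
#'   nearest neighbour.
#' @export
nearest_neighbors <- function(E, segments, policy = nn_policy()) {
  stopifnot(nrow(E) == nrow(segments))
  S <- masked_similarity(E, segments, policy)
  nn <- apply(S, 1, which.max)
  if (any(!is.finite(S[cbind(seq_len(nrow(S)), nn)]))) {
    stop("some segments have no admissible neighbour under the exclusion policy")
  }
  as.integer(nn)
}

#' Binomial proportion confidence interval
#'
#' Wald (normal-approximation) interval by default, the flavour quoted
#' alongside 1-nn precisions; Wilson available by flag.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @return numeric vector `c(lower, upper)`, clamped to `[0, 1]`.
#' @export
binom_ci <- function(x, n, conf = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half; hi <- p + half
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half; hi <- centre + half
  }
  c(max(0, lo), min(1, hi))
}

#' Multi-class 1-nn assessment
#'
#' Each labelled segment is predicted with the (single) label of its
#' admissible nearest neighbour. The confusion matrix of counts
#' `C[true, predicted]` is column-normalized by the number of
#' predictions for each label, so the diagonal reads precision. Each
#' precision carries a binomial proportion confidence interval.
#' Unlabelled segments (`NA`) stay in the corpus as neighbour candidates
#' but are not evaluated.
#'
#' @param E segment-embedding matrix.
#' @param segments aligned segment `data.frame` with a `label` column.
#' @param policy an [nn_policy()].
#' @param ci_method passed to [binom_ci()].
#' @return list with `confusion` (counts), `normalized` (columns sum to
#'   1 where defined), `precision` (named vector), `ci` (2-column
#'   matrix), `n_predictions` (per predicted label) and
#'   `average_precision`.
#' @export
evaluate_multiclass_1nn <- function(E, segments, policy = nn_policy(),
                                    ci_method = "wald") {
  stopifnot("label" %in% names(segments))
  nn <- nearest_neighbors(E, segments, policy)
  eval_idx <- which(!is.na(segments$label) & !is.na(segments$label[nn]))
  truth <- segments$label[eval_idx]
  predicted <- segments$label[nn[eval_idx]]
  labels <- sort(unique(c(truth, predicted)))
  C <- table(factor(truth, levels = labels), factor(predicted, levels = labels))
  C <- unclass(C)
  dimnames(C) <- list(true = labels, predicted = labels)
  n_pred <- colSums(C)
  norm <- sweep(C, 2, ifelse(n_pred > 0, n_pred, NA_real_), "/")
  precision <- diag(norm)
  ci <- t(vapply(labels, function(l) {
    if (n_pred[l] == 0) return(c(NA_real_, NA_real_))
    binom_ci(C[l, l], n_pred[l], method = ci_method)
  }, numeric(2)))
  dimnames(ci) <- list(labels, c("lower", "upper"))
  list(confusion = C, normalized = norm, precision = precision, ci = ci,
       n_predictions = n_pred,
       average_precision = mean(precision, na.rm = TRUE))
}

#' Multi-label 1-nn assessment
#'
#' Every label is evaluated as a binary classification task: a segment
#' is predicted positive for a label when the label is in its nearest
#' neighbour's label set. Per-label TP/FP/TN/FN tallies yield precision,
#' recall and accuracy with binomial confidence intervals.
#'
#' @param E segment-embedding matrix.
#' @param segments aligned segment `data.frame` with a `labels`
#'   list-column.
#' @param policy an [nn_policy()].
#' @param ci_method passed to [binom_ci()].
#' @return `data.frame` with one row per label (`tp`, `fp`, `tn`, `fn`,
#'   `precision`, `recall`, `accuracy` and CI bounds), plus attribute
#'   `average_precision`.
#' @export
evaluate_multilabel_1nn <- function(E, segments, policy = nn_policy(),
                                    ci_method = "wald") {
  stopifnot("labels" %in% names(segments))
  nn <- nearest_neighbors(E, segments, policy)
  all_labels <- sort(unique(unlist(segments$labels)))
  rows <- lapply(all_labels, function(l) {
    truth <- vapply(segments$labels, function(x) l %in% x, logical(1))
    pred <- vapply(segments$labels[nn], function(x) l %in% x, logical(1))
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    acc <- (tp + tn) / length(truth)
    ci <- if (tp + fp > 0) binom_ci(tp, tp + fp, method = ci_method)
          else c(NA_real_, NA_real_)
    data.frame(label = l, tp = tp, fp = fp, tn = tn, fn = fn,
               precision = prec, recall = rec, accuracy = acc,
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "average_precision") <- mean(out$precision, na.rm = TRUE)
  out
}

#' k-nearest-neighbour discovery query
#'
#' Returns the top-k most cosine-similar corpus segments for each query
#' embedding, then pools the results across queries, removes duplicate
#' segments, and joins adjacent result segments from the same protein
#' into single intervals (the cluster-merge semantics of
#' [merge_by_cluster()]). Exact self matches (same protein and
#' coordinates as a query) are excluded.
#'
#' @param query_E matrix of query embeddings (rows are queries).
#' @param query_segments segment `data.frame` aligned with `query_E`.
#' @param corpus_E matrix of corpus embeddings.
#' @param corpus_segments segment `data.frame` aligned with `corpus_E`.
#' @param k neighbours per query (default 10); if `k` exceeds the
#'   corpus size everything is returned with a warning.
#' @return segment `data.frame` of pooled, deduplicated, adjacency-joined
#'   result intervals, sorted by `(protein_id, start)`.
#' @export
knn_query <- function(query_E, query_segments, corpus_E, corpus_segments,
                      k = 10L) {
  if (is.vector(query_E)) query_E <- matrix(query_E, nrow = 1)
  n_corpus <- nrow(corpus_E)
  if (k > n_corpus) {
    warning("k = ", k, " exceeds corpus size ", n_corpus, "; returning all")
    k <- n_corpus
  }
  qn <- query_E / pmax(sqrt(rowSums(query_E^2)), .Machine$double.eps)
  cn <- corpus_E / pmax(sqrt(rowSums(corpus_E^2)), .Machine$double.eps)
  S <- tcrossprod(qn, cn)
  hits <- integer(0)
  for (i in seq_len(nrow(S))) {
    self <- corpus_segments$protein_id == query_segments$protein_id[i] &
      corpus_segments$start == query_segments$start[i] &
      corpus_segments$end == query_segments$end[i]
    s <- S[i, ]
    s[self] <- -Inf
    ord <- order(-s, corpus_segments$protein_id, corpus_segments$start)
    hits <- c(hits, ord[seq_len(min(k, sum(is.finite(s))))])
  }
  res <- corpus_segments[sort(unique(hits)), , drop = FALSE]
  # joining adjacent results = collapsing runs under one shared label
  joined <- merge_by_cluster(res, rep("hit", nrow(res)))
  joined$label <- NULL
  joined
}
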