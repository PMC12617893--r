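interval_intersection <- function(a_start, a_end, b_start, b_end) {
  pmax(pmin(a_end, b_end) - pmax(a_start, b_start), 0L)
}

#' Transfer the best-matching annotation to a segment (multi-class)
#'
#' Among the protein's annotations whose intersection with the segment
#' covers at least `min_overlap` (default 30%) of the *segment*, the one
#' with the highest IoU wins. Annotations of any size are allowed. Ties
#' on IoU are broken deterministically (longer annotation first, then
#' lexicographic label). Returns `NA` when nothing qualifies.
#'
#' @param seg_start,seg_end 0-based half-open segment bounds.
#' @param annotations annotation `data.frame` for the same protein.
#' @param min_overlap minimum intersection as a fraction of segment
#'   length (inclusive threshold).
#' @return a single label, or `NA_character_`.
#' @export
transfer_multiclass <- function(seg_start, seg_end, annotations,
                                min_overlap = 0.30) {
  if (nrow(annotations) == 0) return(NA_character_)
  seg_len <- seg_end - seg_start
  inter <- interval_intersection(seg_start, seg_end,
                                 annotations$start, annotations$end)
  qualifies <- inter >= min_overlap * seg_len
  if (!any(qualifies)) return(NA_character_)
  ann <- annotations[qualifies, , drop = FALSE]
  iou_v <- iou(seg_start, seg_end, ann$start, ann$end)
  ann_len <- ann$end - ann$start
  ord <- order(-iou_v, -ann_len, ann$label)
  ann$label[ord[1]]
}

#' Transfer all qualifying annotations to a segment (multi-label)
#'
#' Every label whose best same-label annotation intersects at least
#' `min_overlap` of the segment is transferred. Multiple annotations
#' with the same label collapse to one membership (set semantics).
#'
#' @inheritParams transfer_multiclass
#' @return character vector of labels (possibly empty), sorted.
#' @export
transfer_multilabel <- function(seg_start, seg_end, annotations,
                                min_overlap = 0.30) {
  if (nrow(annotations) == 0) return(character(0))
  seg_len <- seg_end - seg_start
  inter <- interval_intersection(seg_start, seg_end,
                                 annotations$start, annotations$end)
  qualifies <- inter >= min_overlap * seg_len
  sort(unique(annotations$label[qualifies]))
}

#' Flag a segment as an intrinsically disordered region
#'
#' A segment is flagged as an IDR when the union of its overlaps with
#' disorder annotations (MobiDB-style) covers at least `min_overlap`
#' (default 30%) of its residues.
#'
#' @inheritParams transfer_multiclass
#' @param disorder_annotations annotation `data.frame` already filtered
#'   to the disorder source.
#' @return logical scalar.
#' @export
flag_idr <- function(seg_start, seg_end, disorder_annotations,
                     min_overlap = 0.30) {
  if (nrow(disorder_annotations) == 0) return(FALSE)
  covered <- rep(FALSE, seg_end - seg_start)
  for (i in seq_len(nrow(disorder_annotations))) {
    s <- max(seg_start, disorder_annotations$start[i])
    e <- min(seg_end, disorder_annotations$end[i])
    if (e > s) covered[(s - seg_start + 1L):(e - seg_start)] <- TRUE
  }
  sum(covered) >= min_overlap * (seg_end - seg_start)
}

#' Transfer annotations across a whole segment corpus
#'
#' Applies [transfer_multiclass()] or [transfer_multilabel()] to every
#' segment, matching annotations by protein. In multi-class mode the
#' result has at most one label per segment (column `label`); in
#' multi-label mode a list-column `labels`.
#'
#' @param segments segment `data.frame`.
#' @param annotations annotation `data.frame` (all proteins).
#' @param mode `"multiclass"` or `"multilabel"`.
#' @param min_overlap fraction-of-segment threshold (default 0.30).
#' @param idr_annotations optional disorder annotation table; when
#'   given, an `is_idr` column is added via [flag_idr()].
#' @return `segments` with the transfer columns added.
#' @export
transfer_annotations <- function(segments, annotations,
                                 mode = c("multiclass", "multilabel"),
                                 min_overlap = 0.30,
                                 idr_annotations = NULL) {
  mode <- match.arg(mode)
  validate_segments(segments)
  by_prot <- split(annotations, annotations$protein_id)
  empty <- annotations[0, , drop = FALSE]
  get_ann <- function(id) if (id %in% names(by_prot)) by_prot[[id]] else empty
  out <- segments
  if (mode == "multiclass") {
    out$label <- vapply(seq_len(nrow(segments)), function(i) {
      transfer_multiclass(segments$start[i], segments$end[i],
                          get_ann(segments$protein_id[i]), min_overlap)
    }, character(1))
  } else {
    out$labels <- lapply(seq_len(nrow(segments)), function(i) {
      transfer_multilabel(segments$start[i], segments$end[i],
                          get_ann(segments$protein_id[i]), min_overlap)
    })
  }
  if (!is.null(idr_annotations)) {
    idr_by_prot <- split(idr_annotations, idr_annotations$protein_id)
    get_idr <- function(id) if (id %in% names(idr_by_prot)) idr_by_prot[[id]] else empty
    out$is_idr <- vapply(seq_len(nrow(segments)), function(i) {
      flag_idr(segments$start[i], segments$end[i],
               get_idr(segments$protein_id[i]), min_overlap)
    }, logical(1))
  }
  out
}

#' Drop rare labels from a labelled corpus
#'
#' Labels occurring fewer than `min_n` times across the corpus (default
#' 25) are removed: in multi-class mode the segment becomes unlabelled
#' (`NA`), in multi-label mode the label leaves each segment's set.
#' Segments left without labels stay in the corpus (they can still serve
#' as nearest-neighbour candidates) but are excluded from label-based
#' evaluation by the evaluation functions.
#'
#' @param labeled a segment `data.frame` with a `label` column
#'   (multi-class) or a `labels` list-column (multi-label).
#' @param min_n minimum corpus-wide count (inclusive).
#' @return the filtered `data.frame`.
#' @export
filter_labels_by_count <- function(labeled, min_n = 25L) {
  if (nrow(labeled) == 0) return(labeled)
  if ("label" %in% names(labeled)) {
    counts <- table(labeled$label[!is.na(labeled$label)])
    keep <- names(counts)[counts >= min_n]
    labeled$label[!labeled$label %in% keep] <- NA_character_
  }
  if ("labels" %in% names(labeled)) {
    counts <- table(unlist(labeled$labels))
    keep <- names(counts)[counts >= min_n]
    labeled$labels <- lapply(labeled$labels, function(l) l[l %in% keep])
  }
  labeled
}

#' Transfer protein-level labels to segments
#'
#' Whole-protein label sets (e.g. compartment localization) are
#' inherited by each eligible segment. With `idr_only = TRUE` only
#' segments flagged as IDRs receive labels, the restriction used when
#' protein-level localization annotations are evaluated on disordered
#' segments only.
#'
#' @param segments segment `data.frame`, with an `is_idr` column when
#'   `idr_only = TRUE`.
#' @param protein_labels named list mapping protein id to a character
#'   vector of labels.
#' @param idr_only logical; restrict transfer to IDR segments.
#' @return `segments` with a `labels` list-column.
#' @export
transfer_protein_level <- function(segments, protein_labels, idr_only = FALSE) {
  validate_segments(segments)
  if (idr_only && !"is_idr" %in% names(segments)) {
    stop("idr_only = TRUE requires an is_idr column (see transfer_annotations)")
  }
  segments$labels <- lapply(seq_len(nrow(segments)), function(i) {
    if (idr_only && !isTRUE(segments$is_idr[i])) return(character(0))
    labs <- protein_labels[[segments$protein_id[i]]]
    if (is.null(labs)) character(0) else sort(unique(labs))
  })
  segments
}
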