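#' Correct over-segmentation by cosine merging
#'
#' Within each protein, the all-pairs cosine similarity of the pooled
#' segment embeddings is computed; if the globally most-similar pair is
#' adjacent along the sequence, the pair is merged (interval union, with
#' the embedding re-pooled from the residue matrix) and the procedure
#' repeats. Merging stops when the most-similar pair is not adjacent or
#' when fewer than `min_segments` segments remain. Proteins that start
#' with fewer than `min_segments` (default 6) segments are left
#' untouched: with very few segments a middle segment is adjacent to
#' nearly everything and would be merged "accidentally" regardless of
#' similarity.
#'
#' @param segments segment `data.frame`, tiling each protein.
#' @param store named list of residue embedding matrices.
#' @param min_segments merge only proteins with at least this many
#'   segments (default 6).
#' @param iterate logical; repeat to a fixed point (default) or apply a
#'   single merge per protein.
#' @return the merged segment `data.frame` (never more segments than the
#'   input).
#' @export
merge_oversegmentation <- function(segments, store, min_segments = 6L,
                                   iterate = TRUE) {
  validate_segments(segments)
  missing <- setdiff(unique(segments$protein_id), names(store))
  if (length(missing) > 0) {
    stop("no embedding matrix for protein(s): ", paste(missing, collapse = ", "))
  }
  parts <- split(segments, segments$protein_id)
  merged <- lapply(names(parts), function(id) {
    merge_protein_cosine(parts[[id]], store[[id]], min_segments, iterate)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$protein_id, out$start), , drop = FALSE]
}

merge_protein_cosine <- function(seg, matrix, min_segments, iterate) {
  seg <- seg[order(seg$start), , drop = FALSE]
  repeat {
    n <- nrow(seg)
    if (n < min_segments) break
    E <- t(vapply(seq_len(n), function(i) {
      pool_segment(matrix, seg$start[i], seg$end[i])
    }, numeric(ncol(matrix))))
    S <- cosine_similarity_matrix(E)
    S[lower.tri(S, diag = TRUE)] <- -Inf
    best <- arrayInd(which.max(S), dim(S))
    i <- best[1]; j <- best[2]
    adjacent <- (j == i + 1L) && (seg$end[i] == seg$start[j])
    if (!adjacent) break
    seg$end[i] <- seg$end[j]
    seg <- seg[-j, , drop = FALSE]
    seg$score <- NA_real_   # scores no longer reflect the new boundaries
    if (!iterate) break
  }
  rownames(seg) <- NULL
  seg
}

cosine_similarity_matrix <- function(E) {
  nrm <- sqrt(rowSums(E^2))
  nrm[nrm == 0] <- 1
  tcrossprod(E / nrm)
}

#' Join adjacent segments sharing a cluster label
#'
#' Maximal runs of adjacent segments (same protein, touching
#' coordinates) that carry the same cluster label collapse to one
#' segment each. This is the over-segmentation correction used when
#' segments have already been grouped by a clustering.
#'
#' @param segments segment `data.frame`.
#' @param labels vector of cluster labels, one per row of `segments`.
#' @return the collapsed segment `data.frame` with a `label` column.
#' @export
merge_by_cluster <- function(segments, labels) {
  validate_segments(segments)
  if (length(labels) != nrow(segments)) {
    stop("need exactly one label per segment (got ", length(labels),
         " labels for ", nrow(segments), " segments)")
  }
  if (nrow(segments) == 0) {
    out <- segments
    out$label <- character(0)
    return(out)
  }
  seg <- segments
  seg$label <- as.character(labels)
  seg <- seg[order(seg$protein_id, seg$start), , drop = FALSE]
  # run id increments whenever protein, label, or adjacency breaks
  n <- nrow(seg)
  new_run <- c(TRUE, seg$protein_id[-1] != seg$protein_id[-n] |
                     seg$label[-1] != seg$label[-n] |
                     seg$start[-1] != seg$end[-n])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(seg, run), function(r) {
    data.frame(protein_id = r$protein_id[1],
               start = min(r$start), end = max(r$end),
               score = NA_real_, color = NA_character_,
               label = r$label[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$protein_id, out$start), , drop = FALSE]
}
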