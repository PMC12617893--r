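cosine_distance_matrix <- function(E) {
  S <- cosine_similarity_matrix(E)
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Default 3-D reducer for segment colours
#'
#' Reduces a corpus of segment embeddings to 3 dimensions for the RGB
#' colour map. Uses UMAP (via `uwot`) with a fixed seed when available;
#' otherwise a deterministic principal-component projection. Both
#' satisfy the reducer contract: corpus of D-vectors in, corpus of
#' 3-vectors out, deterministic for a fixed seed.
#'
#' @param seed integer seed for the stochastic reducer.
#' @return a function `f(E) -> n x 3 matrix`.
#' @export
reducer_default <- function(seed = 42L) {
  function(E) {
    n <- nrow(E)
    if (requireNamespace("uwot", quietly = TRUE) && n >= 15) {
      return(with_local_seed(seed, {
        uwot::umap(E, n_components = 3,
                   n_neighbors = min(15, n - 1), n_threads = 1)
      }))
    }
    p <- stats::prcomp(E, center = TRUE, scale. = FALSE)
    X <- p$x[, seq_len(min(3, ncol(p$x))), drop = FALSE]
    if (ncol(X) < 3) X <- cbind(X, matrix(0, n, 3 - ncol(X)))
    unname(X)
  }
}

#' Map segment embeddings to RGB colours
#'
#' The corpus of segment embeddings is reduced to 3 dimensions
#' `X = [X1, X2, X3]`; each dimension is mean-centred across the whole
#' corpus, squashed through a sigmoid and scaled by 255:
#' `channel = 255 / (1 + exp(-(X - mean(X))))`, with `X1 -> R`,
#' `X2 -> G`, `X3 -> B`. Centring plus the sigmoid turns the roughly
#' normal reduced coordinates into a more uniform spread, pushing
#' colours away from mid-tone greys. A segment sitting exactly at the
#' corpus mean maps to 127.5 on that channel.
#'
#' @param E segment-embedding matrix (`n x D`, `n >= 2`: the reducer and
#'   the mean need a population).
#' @param reducer function `f(E) -> n x 3` matrix; default
#'   [reducer_default()].
#' @return list with `rgb` (`n x 3` matrix, columns R/G/B, values in
#'   `[0, 255]`, floats — rounding happens only at serialization),
#'   `coords` (the reduced 3-D coordinates) and `means` (per-dimension
#'   corpus means).
#' @export
embeddings_to_rgb <- function(E, reducer = reducer_default()) {
  if (is.vector(E)) E <- matrix(E, nrow = 1)
  if (nrow(E) < 2) stop("need at least 2 segments to define corpus means")
  X <- reducer(E)
  if (!is.matrix(X) || nrow(X) != nrow(E) || ncol(X) != 3) {
    stop("reducer must return an n x 3 matrix")
  }
  means <- colMeans(X)
  centred <- sweep(X, 2, means)
  rgb <- 255 / (1 + exp(-centred))
  colnames(rgb) <- c("R", "G", "B")
  list(rgb = rgb, coords = X, means = means)
}

#' Serialize RGB rows as "R,G,B" strings
#'
#' @param rgb `n x 3` matrix of channel values in `[0, 255]`.
#' @return character vector; values rounded to integers here only.
#' @export
rgb_strings <- function(rgb) {
  apply(round(rgb), 1, paste, collapse = ",")
}

#' Render a protein's segments as an SVG colour diagram
#'
#' One horizontal bar per protein with one coloured block per segment,
#' widths proportional to segment length and boundary coordinates
#' annotated — the segment-diagram style used throughout the molecular
#' biology literature. The output is a deterministic SVG string:
#' byte-identical across runs for the same input.
#'
#' @param segments tiling segment `data.frame` for one protein, with a
#'   `color` column of `"R,G,B"` strings (missing colours render grey).
#' @param path optional output path; when given the SVG is written
#'   there.
#' @param width,height canvas size in pixels.
#' @return the SVG document as a single string (invisibly when `path`
#'   is given).
#' @export
render_segment_diagram <- function(segments, path = NULL,
                                   width = 600, height = 60) {
  validate_segments(segments)
  if (length(unique(segments$protein_id)) != 1) {
    stop("render_segment_diagram draws one protein at a time")
  }
  seg <- segments[order(segments$start), , drop = FALSE]
  if (seg$start[1] != 0 || any(seg$start[-1] != seg$end[-nrow(seg)])) {
    stop("segments must tile the protein with no gaps or overlaps")
  }
  L <- seg$end[nrow(seg)]
  bar_h <- height - 20
  px <- function(x) formatC(width * x / L, format = "f", digits = 2)
  blocks <- vapply(seq_len(nrow(seg)), function(i) {
    col <- seg$color[i]
    fill <- if (is.na(col)) "rgb(200,200,200)"
            else sprintf("rgb(%s)", gsub(",", ",", col))
    sprintf('<rect x="%s" y="0" width="%s" height="%d" fill="%s" stroke="black" stroke-width="0.5"/>',
            px(seg$start[i]), px(seg$end[i] - seg$start[i]), bar_h, fill)
  }, character(1))
  ticks <- vapply(unique(c(seg$start, L)), function(b) {
    sprintf('<text x="%s" y="%d" font-size="9" text-anchor="middle">%d</text>',
            px(b), height - 5, b)
  }, character(1))
  svg <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<title>', seg$protein_id[1], '</title>',
    paste(blocks, collapse = ""), paste(ticks, collapse = ""),
    '</svg>')
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}

#' Heatmap leaf order by agglomerative clustering with optimal leaf
#' ordering
#'
#' Rows are clustered by average-linkage agglomerative clustering under
#' cosine distance, and the dendrogram's leaves are arranged by optimal
#' leaf ordering (the dynamic program that minimizes the summed
#' distance between adjacent leaves over all `2^(n-1)` flips). Used to
#' order embedding heatmaps so similar rows sit together.
#'
#' @param E numeric matrix, one row per object (`n >= 2`).
#' @return an integer permutation of `1..n`. All-identical rows return
#'   the stable input order.
#' @export
cluster_leaf_order <- function(E) {
  n <- nrow(E)
  stopifnot(n >= 2)
  D <- cosine_distance_matrix(E)
  if (all(D < 1e-12)) return(seq_len(n))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  optimal_leaf_order(hc, D)
}

# Bar-Joseph optimal leaf ordering over an hclust tree.
# For every subtree and every (leftmost, rightmost) leaf pair, the
# minimal sum of adjacent-leaf distances is computed bottom-up; the best
# root pair is then traced back to a full ordering.
optimal_leaf_order <- function(hc, D) {
  n <- nrow(D)
  merge <- hc$merge
  leaves <- vector("list", nrow(merge))   # leaf sets per internal node
  M <- vector("list", nrow(merge))        # cost matrices [a, b]
  argA <- vector("list", nrow(merge))     # best a' (left child end)
  argB <- vector("list", nrow(merge))     # best b' (right child start)
  node_leaves <- function(v) if (v < 0) -v else leaves[[v]]
  node_M <- function(v, ls) {
    if (v < 0) return(matrix(0, 1, 1, dimnames = list(-v, -v)))
    M[[v]]
  }
  for (v in seq_len(nrow(merge))) {
    l <- merge[v, 1]; r <- merge[v, 2]
    ll <- node_leaves(l); rl <- node_leaves(r)
    ML <- node_M(l); MR <- node_M(r)
    nL <- length(ll); nR <- length(rl)
    d_lr <- D[ll, rl, drop = FALSE]
    cost <- matrix(Inf, nL, nR, dimnames = list(ll, rl))
    aA <- matrix(NA_integer_, nL, nR)
    aB <- matrix(NA_integer_, nL, nR)
    for (ai in seq_len(nL)) {
      # over a' (end of left block) then b' (start of right block)
      bridge <- ML[ai, ] + d_lr            # nL x nR: a' rows, b' cols
      u <- apply(bridge, 2, min)
      ua <- apply(bridge, 2, which.min)
      for (bi in seq_len(nR)) {
        tot <- u + MR[, bi]
        bb <- which.min(tot)
        cost[ai, bi] <- tot[bb]
        aA[ai, bi] <- ua[bb]
        aB[ai, bi] <- bb
      }
    }
    leaves[[v]] <- c(ll, rl)
    full <- matrix(Inf, nL + nR, nL + nR,
                   dimnames = list(leaves[[v]], leaves[[v]]))
    full[seq_len(nL), nL + seq_len(nR)] <- cost
    full[nL + seq_len(nR), seq_len(nL)] <- t(cost)   # reversed orientation
    M[[v]] <- full
    argA[[v]] <- aA
    argB[[v]] <- aB
  }
  root <- nrow(merge)
  best <- arrayInd(which.min(M[[root]]), dim(M[[root]]))
  order_node <- function(v, a, b) {
    if (v < 0) return(-v)
    l <- merge[v, 1]; r <- merge[v, 2]
    ll <- node_leaves(l); rl <- node_leaves(r)
    if (a %in% ll) {
      ai <- match(a, ll); bi <- match(b, rl)
      ap <- ll[argA[[v]][ai, bi]]
      bp <- rl[argB[[v]][ai, bi]]
      c(order_node(l, a, ap), order_node(r, bp, b))
    } else {
      rev(order_node(v, b, a))
    }
  }
  names_root <- as.integer(rownames(M[[root]]))
  order_node(root, names_root[best[1]], names_root[best[2]])
}

#' Flat clusters of residue embeddings
#'
#' Average-linkage agglomerative clustering on cosine distance, cut at
#' a fixed distance threshold (default 0.5) — the procedure used to
#' group individual residue embeddings (e.g. all arginines of a protein
#' family) into clusters for enrichment testing.
#'
#' @param E residue-embedding matrix (one row per residue).
#' @param distance_threshold cosine-distance cut height (default 0.5).
#' @return integer cluster labels, one per row (a partition of the
#'   input).
#' @export
residue_cluster <- function(E, distance_threshold = 0.5) {
  n <- nrow(E)
  if (n == 1) return(1L)
  D <- cosine_distance_matrix(E)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  as.integer(stats::cutree(hc, h = distance_threshold))
}
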