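#' Change-point configuration
#'
#' Parameters of the sliding-window kernel change-point analysis. The
#' defaults are the settings used throughout: a window of 30 residues
#' (each candidate boundary compares the 15 residues before it to the 15
#' after) and a budget of 3 boundaries per 100 amino acids, a ceiling at
#' which the number of returned boundaries saturates because the peaks in
#' the gain curve, not the budget, become limiting.
#'
#' @param window even integer `>= 4`; sliding-window size in residues.
#' @param boundaries_per_100aa positive number; boundary budget per 100
#'   residues (`ceiling(budget * L / 100)` boundaries allowed).
#' @param rbf_bandwidth_rule `"median_heuristic"` (gamma = 1 / median
#'   pairwise squared row distance, resolved once per protein) or
#'   `"fixed"`.
#' @param bandwidth_value fixed gamma when `rbf_bandwidth_rule = "fixed"`.
#' @param min_spacing minimum distance in residues between selected
#'   boundaries (non-maximum suppression); default `window / 2`.
#' @param seed integer seed for the sampled median heuristic.
#' @return a list of class `"zps_config"`.
#' @export
changepoint_config <- function(window = 30L,
                               boundaries_per_100aa = 3,
                               rbf_bandwidth_rule = c("median_heuristic", "fixed"),
                               bandwidth_value = NULL,
                               min_spacing = NULL,
                               seed = 1L) {
  rbf_bandwidth_rule <- match.arg(rbf_bandwidth_rule)
  window <- as.integer(window)
  if (window < 4L || window %% 2L != 0L) stop("window must be even and >= 4")
  if (boundaries_per_100aa <= 0) stop("boundaries_per_100aa must be positive")
  if (rbf_bandwidth_rule == "fixed" &&
      (is.null(bandwidth_value) || bandwidth_value <= 0)) {
    stop("fixed bandwidth rule requires a positive bandwidth_value")
  }
  structure(list(
    window = window,
    boundaries_per_100aa = boundaries_per_100aa,
    rbf_bandwidth_rule = rbf_bandwidth_rule,
    bandwidth_value = bandwidth_value,
    min_spacing = if (is.null(min_spacing)) window %/% 2L else as.integer(min_spacing),
    seed = as.integer(seed)
  ), class = "zps_config")
}

# Run expr with the global RNG state saved and restored, seeded locally.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' RBF kernel least-squares cost of a block of rows
#'
#' For `n` rows `x_1..x_n` the cost is
#' `n - (1/n) * sum_{i,j} exp(-gamma * ||x_i - x_j||^2)` (the kernel
#' least-squares segment cost with `k(x, x) = 1`). It is 0 for a single
#' row or for identical rows and grows with within-block heterogeneity.
#'
#' @param rows numeric matrix (`n x D`), the rows of one candidate block.
#' @param gamma positive RBF bandwidth.
#' @return non-negative scalar cost.
#' @export
rbf_cost <- function(rows, gamma) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1)
  stopifnot(is.numeric(rows), gamma > 0)
  if (!all(is.finite(rows))) stop("non-finite rows passed to rbf_cost")
  n <- nrow(rows)
  if (n == 1L) return(0)
  sq <- rowSums(rows^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(rows)
  d2[d2 < 0] <- 0
  ksum <- sum(exp(-gamma * d2))
  max(n - ksum / n, 0)
}

#' Resolve the RBF bandwidth for one protein
#'
#' Median heuristic: gamma = 1 / median of pairwise squared row
#' distances, computed over all pairs for short proteins and a seeded
#' sample of pairs otherwise. Falls back to 1 when the median is 0
#' (degenerate constant matrices).
#'
#' @param matrix `L x D` residue embedding matrix.
#' @param config a [changepoint_config()].
#' @param max_pairs sample size cap for the heuristic.
#' @return positive scalar gamma.
#' @export
rbf_bandwidth <- function(matrix, config = changepoint_config(), max_pairs = 2000L) {
  if (config$rbf_bandwidth_rule == "fixed") return(config$bandwidth_value)
  L <- nrow(matrix)
  if (L < 2L) return(1)
  n_pairs <- L * (L - 1) / 2
  if (n_pairs <= max_pairs) {
    d2 <- as.vector(stats::dist(matrix))^2
  } else {
    d2 <- with_local_seed(config$seed, {
      i <- sample.int(L, max_pairs, replace = TRUE)
      j <- sample.int(L - 1L, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      rowSums((matrix[i, , drop = FALSE] - matrix[j, , drop = FALSE])^2)
    })
  }
  med <- stats::median(d2)
  if (med <= 0) 1 else 1 / med
}

# Kernel sums over the diagonal band, reused by gain_curve.
# Returns S(s, m) = sum over pairs i < j within rows s..s+m-1 of K[i, j],
# as a function closure over cumulative band sums.
band_kernel_sums <- function(matrix, width, gamma) {
  L <- nrow(matrix)
  cumK <- vector("list", width - 1L)
  for (o in seq_len(width - 1L)) {
    d2 <- rowSums((matrix[1:(L - o), , drop = FALSE] -
                   matrix[(1 + o):L, , drop = FALSE])^2)
    cumK[[o]] <- c(0, cumsum(exp(-gamma * d2)))
  }
  function(s, m) {
    total <- 0
    for (o in seq_len(min(m - 1L, width - 1L))) {
      total <- total + cumK[[o]][s + m - o] - cumK[[o]][s]
    }
    total
  }
}

#' Sliding-window discrepancy (gain) curve
#'
#' For each admissible boundary position `t` (0-based, between rows), the
#' gain compares the 30-residue window centred on `t` to its two
#' 15-residue halves under the RBF kernel cost:
#' `gain(t) = cost(both halves together) - cost(left) - cost(right)`.
#' Large gains mean the two flanks look different in embedding space.
#' The bandwidth is resolved once per protein.
#'
#' @param matrix `L x D` residue embedding matrix.
#' @param config a [changepoint_config()].
#' @return list with `positions` (candidate boundary indices, 0-based, in
#'   `[window/2, L - window/2]`), `gains`, `gamma`, `window`, `L`.
#'   Proteins shorter than the window yield an empty curve (one
#'   whole-protein segment downstream).
#' @export
gain_curve <- function(matrix, config = changepoint_config()) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!all(is.finite(matrix))) stop("non-finite embedding matrix")
  L <- nrow(matrix)
  w <- config$window
  h <- w %/% 2L
  if (L < w) {
    return(list(positions = integer(0), gains = numeric(0),
                gamma = NA_real_, window = w, L = L))
  }
  gamma <- rbf_bandwidth(matrix, config)
  S <- band_kernel_sums(matrix, w, gamma)
  cost_from_S <- function(s, m) (m - 1) - 2 * S(s, m) / m
  positions <- h:(L - h)
  gains <- vapply(positions, function(t) {
    s <- t - h + 1L              # first row (1-based) of the full window
    cost_from_S(s, w) - cost_from_S(s, h) - cost_from_S(s + h, h)
  }, numeric(1))
  list(positions = positions, gains = gains, gamma = gamma, window = w, L = L)
}

#' Select boundaries from a gain curve
#'
#' Boundaries are local maxima of the gain curve with strictly positive
#' gain, taken greedily in decreasing gain order under a minimum-spacing
#' constraint (non-maximum suppression), and capped at the budget
#' `ceiling(boundaries_per_100aa * L / 100)`. When fewer qualifying
#' peaks exist than the budget allows, fewer boundaries are returned —
#' raising the budget then changes nothing (saturation).
#'
#' @param curve output of [gain_curve()].
#' @param config a [changepoint_config()].
#' @return sorted integer vector of boundary positions (possibly empty).
#' @export
select_boundaries <- function(curve, config = changepoint_config()) {
  g <- curve$gains
  pos <- curve$positions
  if (length(g) == 0) return(integer(0))
  n <- length(g)
  # gains that are zero up to the cancellation error of the windowed
  # kernel sums do not qualify as boundaries
  tol <- 1e-8 * max(abs(g), 1)
  left <- c(-Inf, g[-n])
  right <- c(g[-1], -Inf)
  is_peak <- g > tol & g > left & g >= right
  if (!any(is_peak)) return(integer(0))
  peaks <- pos[is_peak]
  peak_g <- g[is_peak]
  ord <- order(-peak_g, peaks)
  budget <- ceiling(config$boundaries_per_100aa * curve$L / 100)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= budget) break
    if (all(abs(peaks[i] - chosen) >= config$min_spacing)) {
      chosen <- c(chosen, peaks[i])
    }
  }
  sort(chosen)
}

#' Zero-shot segmentation of one protein
#'
#' Runs the full change-point pipeline on a residue embedding matrix:
#' gain curve, boundary selection, and segment construction. Boundaries
#' `a, b, c` on a protein of length 100 produce the segments
#' `(0, a), (a, b), (b, c), (c, 100)` in 0-based half-open coordinates;
#' the segments always tile `[0, L)` exactly. With `score = TRUE` each
#' segment also carries the mean of its boundary t-scores (see
#' [boundary_score()]).
#'
#' @param matrix `L x D` residue embedding matrix.
#' @param protein_id identifier recorded in the output table.
#' @param config a [changepoint_config()].
#' @param score logical; attach boundary-derived segment scores.
#' @return a segment `data.frame` (see [segment_table()]).
#' @export
zps_segment <- function(matrix, protein_id = "protein",
                        config = changepoint_config(), score = TRUE) {
  curve <- gain_curve(matrix, config)
  bounds <- select_boundaries(curve, config)
  L <- nrow(matrix)
  starts <- c(0L, bounds)
  ends <- c(bounds, L)
  seg <- segment_table(protein_id = protein_id, start = starts, end = ends)
  if (score) seg$score <- segment_scores(seg, matrix)
  seg
}

#' Boundary confidence score (two-sample t statistic)
#'
#' Compares the up-to-15 residues before a boundary to the up-to-15
#' after it (truncated at the protein termini) with a per-dimension
#' Welch two-sample t statistic, aggregated as the mean absolute t over
#' embedding dimensions. Higher means a more confident boundary.
#'
#' @param matrix `L x D` residue embedding matrix.
#' @param boundary 0-based boundary position in `(0, L)`.
#' @param flank window on each side (default 15).
#' @return scalar score, or `NA` when fewer than 2 rows are available on
#'   either side.
#' @export
boundary_score <- function(matrix, boundary, flank = 15L) {
  L <- nrow(matrix)
  if (boundary <= 0 || boundary >= L) stop("boundary must lie strictly inside (0, L)")
  before <- max(1L, boundary - flank + 1L):boundary
  after <- (boundary + 1L):min(L, boundary + flank)
  if (length(before) < 2L || length(after) < 2L) return(NA_real_)
  a <- matrix[before, , drop = FALSE]
  b <- matrix[after, , drop = FALSE]
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se <- sqrt(v1 / nrow(a) + v2 / nrow(b))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  mean(abs(t))
}

#' Segment scores from boundary scores
#'
#' Each segment's score is the average of the scores of the two
#' boundaries that define it; the protein termini carry no score, so
#' terminal segments use their single scored boundary and a single
#' whole-protein segment has score `NA`.
#'
#' @param segments tiling segment table for one protein, sorted by start.
#' @param matrix the protein's residue embedding matrix.
#' @return numeric vector of per-segment scores.
#' @export
segment_scores <- function(segments, matrix) {
  seg <- segments[order(segments$start), , drop = FALSE]
  n <- nrow(seg)
  if (n == 1L) return(NA_real_)
  inner <- seg$start[-1]                     # interior boundaries
  bscore <- vapply(inner, function(b) boundary_score(matrix, b), numeric(1))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) bscore[i - 1L] else NA_real_
    right <- if (i < n) bscore[i] else NA_real_
    vals <- c(left, right)
    vals <- vals[!is.na(vals)]
    scores[i] <- if (length(vals)) mean(vals) else NA_real_
  }
  scores[order(order(segments$start))]
}
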