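# Shared fixture builders for the test suite. Everything is generated in
# code; no files ship with the package.

# A block-structured residue matrix with explicit block means (rows of
# `means`), zero noise unless sd > 0.
block_matrix <- function(block_lengths, means, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(block_lengths), function(i) {
    matrix(rep(means[i, ], each = block_lengths[i]),
           nrow = block_lengths[i])
  }))
  if (sd > 0) rows <- rows + matrix(rnorm(length(rows), sd = sd), nrow(rows))
  rows
}

# Random intervals on [0, L) for property tests.
random_intervals <- function(n, L, protein_id = "P1") {
  start <- sample.int(L - 1L, n, replace = TRUE) - 1L
  len <- sample.int(L %/% 2L, n, replace = TRUE)
  end <- pmin(start + len, L)
  ok <- end > start
  segment_table(protein_id = protein_id, start = start[ok], end = end[ok])
}

# Position-set IoU oracle: counts shared / total residue positions.
iou_positions <- function(a_start, a_end, b_start, b_end) {
  a <- seq.int(a_start, a_end - 1L)
  b <- seq.int(b_start, b_end - 1L)
  length(intersect(a, b)) / length(union(a, b))
}

# O(n^2) double-loop RBF cost oracle, independent of the implementation.
rbf_cost_oracle <- function(rows, gamma) {
  n <- nrow(rows)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + exp(-gamma * sum((rows[i, ] - rows[j, ])^2))
    }
  }
  n - total / n
}

# Tiny labelled embedding corpus for neighbour tests: class means on
# orthogonal axes, tight Gaussian clusters.
tiny_nn_corpus <- function(n_per_class = 10, n_classes = 3, d = 8,
                           spread = 0.05, seed = 1) {
  set.seed(seed)
  E <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    centre <- numeric(d); centre[k] <- 1
    matrix(rep(centre, each = n_per_class), n_per_class) +
      matrix(rnorm(n_per_class * d, sd = spread), n_per_class)
  }))
  n <- n_per_class * n_classes
  seg <- segment_table(protein_id = paste0("P", seq_len(n)),
                       start = 0L, end = 10L)
  seg$label <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
  list(E = E, segments = seg)
}
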