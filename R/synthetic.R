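#' Specification for synthetic block-structured embedding corpora
#'
#' The generator emulates what a protein language model's per-residue
#' embedding matrix looks like to the segmentation engine: a protein is
#' a sequence of blocks (segments), each block drawing its rows from a
#' class-specific mean vector plus isotropic Gaussian noise. Planted
#' boundaries and block labels are recorded as ground truth. Class mean
#' vectors are placed on scaled orthogonal basis directions so every
#' pair of classes sits at exactly `mean_separation` Euclidean distance.
#' Everything is a pure function of `(spec, seed)`.
#'
#' @param n_proteins number of proteins in the corpus.
#' @param protein_length residues per protein (constant length).
#' @param n_boundaries planted boundaries per protein.
#' @param n_classes number of segment classes (`<= dim`).
#' @param dim embedding dimension (default 32; every algorithm is
#'   dimension-agnostic, so a small D trades nothing but resolution).
#' @param noise_sd per-dimension within-class noise SD (> 0 unless a
#'   noise-free corpus is requested with 0).
#' @param mean_separation per-dimension class separation in units of
#'   `noise_sd`: any two class means sit at Euclidean distance
#'   `mean_separation * noise_sd * sqrt(dim / 2)`, the distance of two
#'   blocks whose means differ by `mean_separation` SDs in half the
#'   embedding dimensions. This mirrors how segment classes differ in
#'   real embedding space — densely, across many dimensions — and
#'   matches the univariate change-point signal-to-noise convention
#'   applied coordinate-wise.
#' @param min_block minimum block length in residues; default
#'   `floor(protein_length / (2 * (n_boundaries + 1)))`.
#' @param seed integer seed; all generation is keyed to it.
#' @return a list of class `"zps_synth_spec"`.
#' @export
synthetic_spec <- function(n_proteins = 100L, protein_length = 300L,
                           n_boundaries = 3L, n_classes = 4L, dim = 32L,
                           noise_sd = 1, mean_separation = 2,
                           min_block = NULL, seed = 1L) {
  stopifnot(n_classes >= 1, n_classes <= dim, noise_sd >= 0,
            mean_separation > 0, protein_length >= n_boundaries + 1)
  if (is.null(min_block)) {
    min_block <- max(1L, protein_length %/% (2L * (n_boundaries + 1L)))
  }
  means <- matrix(0, n_classes, dim)
  # noise-free corpora keep a unit reference SD so the means stay apart
  ref_sd <- if (noise_sd > 0) noise_sd else 1
  scale <- mean_separation * ref_sd * sqrt(dim) / 2
  for (k in seq_len(n_classes)) {
    means[k, k] <- scale
  }
  rownames(means) <- paste0("class", seq_len(n_classes))
  structure(list(
    n_proteins = as.integer(n_proteins),
    protein_length = as.integer(protein_length),
    n_boundaries = as.integer(n_boundaries),
    n_classes = as.integer(n_classes),
    dim = as.integer(dim),
    noise_sd = noise_sd,
    mean_separation = mean_separation,
    min_block = as.integer(min_block),
    class_means = means,
    seed = as.integer(seed)
  ), class = "zps_synth_spec")
}

protein_seed <- function(spec, index) {
  as.integer((as.double(spec$seed) * 1000003 + index) %% 2147483647)
}

#' Generate one synthetic protein
#'
#' Draws planted boundary positions (blocks at least `min_block` long),
#' assigns each block a class different from its neighbour, and fills
#' the rows with the class mean plus isotropic noise. Deterministic per
#' `(seed, index)`.
#'
#' @param spec a [synthetic_spec()].
#' @param index protein index (also keys the per-protein RNG stream).
#' @return list with `protein_id`, `matrix` (`L x D`), `boundaries`
#'   (planted 0-based boundary positions), `labels` (class of each
#'   block) and `blocks` (the true segments as a labelled segment
#'   table).
#' @export
make_protein <- function(spec, index) {
  L <- spec$protein_length
  nb <- spec$n_boundaries
  with_local_seed(protein_seed(spec, index), {
    boundaries <- integer(0)
    if (nb > 0) {
      for (try in 1:200) {
        b <- sort(sample(seq(spec$min_block, L - spec$min_block), nb))
        if (all(diff(c(0L, b, L)) >= spec$min_block)) break
        b <- NULL
      }
      if (is.null(b)) {  # fall back to even spacing, still valid
        b <- round(seq_len(nb) * L / (nb + 1))
      }
      boundaries <- as.integer(b)
    }
    starts <- c(0L, boundaries)
    ends <- c(boundaries, L)
    labels <- integer(nb + 1L)
    labels[1] <- sample.int(spec$n_classes, 1)
    if (nb > 0) {
      for (i in 2:(nb + 1L)) {
        choices <- setdiff(seq_len(spec$n_classes), labels[i - 1])
        labels[i] <- if (length(choices) == 1) choices else sample(choices, 1)
      }
    }
    m <- matrix(0, L, spec$dim)
    for (i in seq_along(starts)) {
      rows <- (starts[i] + 1L):ends[i]
      m[rows, ] <- matrix(spec$class_means[labels[i], ], length(rows),
                          spec$dim, byrow = TRUE)
    }
    if (spec$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(L * spec$dim, sd = spec$noise_sd), L, spec$dim)
    }
    id <- sprintf("SYN%04d", index)
    blocks <- segment_table(protein_id = id, start = starts, end = ends)
    blocks$label <- rownames(spec$class_means)[labels]
    list(protein_id = id, matrix = m, boundaries = boundaries,
         labels = blocks$label, blocks = blocks)
  })
}

#' Generate a labelled synthetic corpus
#'
#' Builds every protein of the spec, pools each true block into a
#' segment embedding, and returns the pieces every downstream test
#' needs: the embedding store, the labelled true segments, their pooled
#' embeddings, and the planted boundaries.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `store` (named list of matrices), `segments`
#'   (labelled segment `data.frame` over the whole corpus), `E` (pooled
#'   segment embeddings, rows aligned with `segments`), `boundaries`
#'   (named list of planted boundary vectors) and `lengths` (named
#'   protein lengths).
#' @export
make_labeled_corpus <- function(spec) {
  prots <- lapply(seq_len(spec$n_proteins), function(i) make_protein(spec, i))
  store <- stats::setNames(lapply(prots, `[[`, "matrix"),
                           vapply(prots, `[[`, "", "protein_id"))
  segments <- do.call(rbind, lapply(prots, `[[`, "blocks"))
  rownames(segments) <- NULL
  E <- pool_segments(segments, store)
  boundaries <- stats::setNames(lapply(prots, `[[`, "boundaries"), names(store))
  lengths <- stats::setNames(rep(spec$protein_length, length(store)), names(store))
  list(store = store, segments = segments, E = E,
       boundaries = boundaries, lengths = lengths)
}

#' Jittered annotations from true blocks
#'
#' Turns the planted blocks into an annotation table emulating curated
#' interval annotations: endpoints perturbed by rounded Gaussian jitter
#' (interior boundaries only; resampled if the perturbation would
#' invert or empty the interval), and a fraction of rows dropped.
#' Labels follow the block classes.
#'
#' @param blocks labelled segment `data.frame` (the `blocks`/`segments`
#'   of the generator).
#' @param lengths named protein lengths.
#' @param jitter_sd SD in residues of the endpoint jitter (>= 0).
#' @param drop_rate fraction of annotations dropped at random.
#' @param source source tag recorded on every row.
#' @param seed RNG seed.
#' @return an annotation `data.frame`.
#' @export
make_annotations <- function(blocks, lengths, jitter_sd = 0, drop_rate = 0,
                             source = "synthetic", seed = 1L) {
  stopifnot(jitter_sd >= 0, drop_rate >= 0, drop_rate <= 1)
  with_local_seed(seed, {
    n <- nrow(blocks)
    start <- blocks$start
    end <- blocks$end
    if (jitter_sd > 0) {
      for (i in seq_len(n)) {
        L <- lengths[[blocks$protein_id[i]]]
        repeat {
          s <- if (start[i] == 0) 0L else
            max(0L, min(L - 1L, start[i] + as.integer(round(stats::rnorm(1, 0, jitter_sd)))))
          e <- if (end[i] == L) L else
            max(1L, min(L, end[i] + as.integer(round(stats::rnorm(1, 0, jitter_sd)))))
          if (e > s) { start[i] <- s; end[i] <- e; break }
        }
      }
    }
    keep <- if (drop_rate > 0) stats::runif(n) >= drop_rate else rep(TRUE, n)
    annotation_table(
      protein_id = blocks$protein_id[keep],
      start = start[keep], end = end[keep],
      label = blocks$label[keep], source = source
    )
  })
}
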