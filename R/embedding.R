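#' Average-pool a residue embedding matrix over a segment
#'
#' The segment embedding is the column-wise arithmetic mean of the rows
#' covered by the segment: a segment spanning residues `[100, 125)` of an
#' `L x 1024` matrix pools 25 rows down to a single 1024-vector.
#' Fragments are never re-embedded; pooling is the only reduction.
#'
#' @param matrix numeric `L x D` per-residue embedding matrix.
#' @param start,end 0-based half-open segment bounds, `0 <= start < end <= L`.
#' @return numeric vector of length `D`.
#' @export
pool_segment <- function(matrix, start, end) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  L <- nrow(matrix)
  if (end <= start) stop("empty segment: [", start, ", ", end, ")")
  if (start < 0 || end > L) stop("segment [", start, ", ", end, ") outside [0, ", L, ")")
  rows <- (start + 1L):end   # 0-based half-open -> 1-based row indices
  colMeans(matrix[rows, , drop = FALSE])
}

#' Pool every segment of a table against an embedding store
#'
#' @param segments segment `data.frame`.
#' @param store named list of `L x D` matrices (see
#'   [read_embedding_store()]).
#' @return numeric matrix with one pooled row per segment, rows in the
#'   order of `segments`.
#' @export
pool_segments <- function(segments, store) {
  validate_segments(segments)
  missing <- setdiff(unique(segments$protein_id), names(store))
  if (length(missing) > 0) {
    stop("no embedding matrix for protein(s): ", paste(missing, collapse = ", "))
  }
  D <- ncol(store[[1]])
  out <- matrix(NA_real_, nrow(segments), D)
  for (i in seq_len(nrow(segments))) {
    out[i, ] <- pool_segment(store[[segments$protein_id[i]]],
                             segments$start[i], segments$end[i])
  }
  out
}

# 21-letter alphabet used for k-mer counting: the 20 standard amino acids
# plus X; ambiguous/nonstandard letters U, Z, O, B are mapped to X first.
kmer_alphabet <- function() c("A","C","D","E","F","G","H","I","K","L",
                              "M","N","P","Q","R","S","T","V","W","Y","X")

#' Overlapping k-mer embedding of a sequence fragment
#'
#' Counts all overlapping k-mers (`length - k + 1` windows) of the
#' fragment over the 21-letter alphabet (20 amino acids + X; U, Z, O and
#' B map to X, mirroring common language-model tokenization), in
#' lexicographic dimension order, then normalizes the count vector to
#' unit Euclidean norm. 1-mers are the one-hot (composition) baseline;
#' 3-mers are the sequence baseline used against pooled embeddings.
#'
#' @param fragment amino-acid string of length `>= k`.
#' @param k k-mer size, 1 or 3.
#' @param normalize logical; return the unit-norm vector (default) or
#'   raw counts.
#' @return named numeric vector of length `21^k`.
#' @export
kmer_embedding <- function(fragment, k = 3L, normalize = TRUE) {
  stopifnot(k %in% c(1L, 3L))
  fragment <- toupper(fragment)
  n <- nchar(fragment)
  if (n < k) stop("fragment shorter than k (", n, " < ", k, ")")
  fragment <- chartr("UZOB", "XXXX", fragment)
  alpha <- kmer_alphabet()
  chars <- strsplit(fragment, "")[[1]]
  if (any(!chars %in% alpha)) {
    stop("unexpected character(s) in fragment: ",
         paste(unique(chars[!chars %in% alpha]), collapse = ", "))
  }
  # lexicographic order over the sorted alphabet
  sorted <- sort(alpha)
  if (k == 1L) {
    dims <- sorted
  } else {
    grid <- expand.grid(c3 = sorted, c2 = sorted, c1 = sorted,
                        stringsAsFactors = FALSE)
    dims <- paste0(grid$c1, grid$c2, grid$c3)
  }
  counts <- stats::setNames(numeric(length(dims)), dims)
  wins <- substring(fragment, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  tab <- table(wins)
  counts[names(tab)] <- as.numeric(tab)
  if (normalize) {
    nrm <- sqrt(sum(counts^2))
    if (nrm > 0) counts <- counts / nrm
  }
  counts
}

#' Embedding providers
#'
#' A provider maps a protein (id + sequence) to its `L x D` residue
#' embedding matrix. Three providers are available: a precomputed store,
#' the synthetic generator (see [make_protein()]), and an adapter slot
#' for a ProtT5-style encoder. The adapter refuses sequences of 8000
#' residues or more (the length cap applied when embedding the human
#' proteome) and requires a user-supplied encoder function; no model is
#' bundled or downloaded.
#'
#' @param store named list of matrices for `provider_store`.
#' @return a function `f(id, sequence)` returning an `L x D` matrix.
#' @export
provider_store <- function(store) {
  check_embedding_store(store)
  function(id, sequence = NULL) {
    if (!id %in% names(store)) stop("protein not in embedding store: ", id)
    m <- store[[id]]
    if (!is.null(sequence) && nrow(m) != nchar(sequence)) {
      stop("embedding rows do not match sequence length for: ", id)
    }
    m
  }
}

#' @rdname provider_store
#' @param encoder optional function `f(sequence) -> L x D matrix`
#'   wrapping an external protein language model.
#' @param max_length sequences at or above this length are refused
#'   (default 8000).
#' @export
provider_prott5 <- function(encoder = NULL, max_length = 8000L) {
  function(id, sequence) {
    if (nchar(sequence) >= max_length) {
      stop("sequence ", id, " has length ", nchar(sequence),
           " >= ", max_length, "; refused by the pLM adapter")
    }
    if (is.null(encoder)) {
      stop("no encoder configured; supply encoder = function(sequence) ... ",
           "or use a precomputed embedding store")
    }
    m <- encoder(sequence)
    if (nrow(m) != nchar(sequence)) stop("encoder returned wrong row count for: ", id)
    m
  }
}
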