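#' Construct a segment table
#'
#' Segments are stored as a plain data frame with 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive), the convention used
#' internally everywhere in this package.
#'
#' @param protein_id character vector of protein identifiers.
#' @param start,end integer vectors; `0 <= start < end <= L`.
#' @param score optional numeric score per segment.
#' @param color optional colour per segment, either a character
#'   `"R,G,B"` string or `NA`.
#' @return a `data.frame` with columns `protein_id`, `start`, `end`,
#'   `score`, `color`.
#' @export
segment_table <- function(protein_id, start, end, score = NA_real_,
                          color = NA_character_) {
  if (length(protein_id) == 0) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      color = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    protein_id = as.character(protein_id),
    start = as.integer(start),
    end = as.integer(end),
    score = as.numeric(score),
    color = as.character(color),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
  df
}

validate_segments <- function(df, protein_lengths = NULL) {
  stopifnot(is.data.frame(df),
            all(c("protein_id", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- df$start < 0L | df$end <= df$start
  if (any(bad)) {
    stop("invalid segment interval(s) for protein(s): ",
         paste(unique(df$protein_id[bad]), collapse = ", "))
  }
  if (!is.null(protein_lengths)) {
    L <- protein_lengths[df$protein_id]
    over <- !is.na(L) & df$end > L
    if (any(over)) {
      stop("segment end exceeds protein length for: ",
           paste(unique(df$protein_id[over]), collapse = ", "))
    }
  }
  invisible(df)
}

#' Construct an annotation table
#'
#' Annotations are labelled intervals on proteins, with a source tag
#' (UniProt / MobiDB / ProRule-like) and an optional score (e-value,
#' p-value or profile score for external predictions). Coordinates are
#' 0-based half-open, as for [segment_table()].
#'
#' @inheritParams segment_table
#' @param label character vector of non-empty labels.
#' @param source character vector of source tags.
#' @return a `data.frame` with columns `protein_id`, `start`, `end`,
#'   `label`, `source`, `score`.
#' @export
annotation_table <- function(protein_id, start, end, label, source = "unknown",
                             score = NA_real_) {
  if (length(protein_id) == 0) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      source = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    protein_id = as.character(protein_id),
    start = as.integer(start),
    end = as.integer(end),
    label = as.character(label),
    source = as.character(source),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0 && any(!nzchar(df$label))) stop("annotation labels must be non-empty")
  if (nrow(df) > 0 && any(df$start < 0L | df$end <= df$start)) {
    stop("invalid annotation interval(s)")
  }
  df
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased. Letters outside the 20 standard amino acids
#' plus `X, U, B, Z, O` are rejected (default) or mapped to `X`.
#'
#' @param path path to a FASTA file.
#' @param nonstandard one of `"error"` or `"map_to_X"`; what to do with
#'   characters outside the accepted alphabet.
#' @return a named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path, nonstandard = c("error", "map_to_X")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) return(character(0))
  seqs <- toupper(as.character(aa))
  # keep only the first whitespace-delimited token of each header as the id
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  accepted <- "ACDEFGHIKLMNPQRSTVWYXUBZO"
  bad <- grepl(paste0("[^", accepted, "]"), seqs)
  if (any(bad)) {
    if (nonstandard == "error") {
      stop("non-amino-acid characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
    seqs <- gsub(paste0("[^", accepted, "]"), "X", seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Read an interval-annotation table
#'
#' Reads a TSV with columns `protein_id`, `start`, `end`, `label`,
#' `source` (and optionally `score`). Rows whose positions contain
#' non-numeric characters (UniProt-style `"1-?"`, `"<1-100"` uncertainty)
#' are dropped and counted. UniProt-style tables are declared 1-based
#' inclusive and converted to the internal 0-based half-open convention.
#'
#' @param path path to the TSV file.
#' @param one_based_inclusive logical; if `TRUE` the file's coordinates
#'   are 1-based inclusive and are converted via `(start-1, end)`.
#' @return the annotation `data.frame`, with attributes `n_dropped`
#'   (non-numeric positions) and `n_rejected` (inverted intervals).
#' @export
read_annotations <- function(path, one_based_inclusive = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  need <- c("protein_id", "start", "end", "label", "source")
  if (!all(need %in% names(raw))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  numeric_ok <- grepl("^[0-9]+$", raw$start) & grepl("^[0-9]+$", raw$end)
  n_dropped <- sum(!numeric_ok)
  raw <- raw[numeric_ok, , drop = FALSE]
  start <- as.integer(raw$start)
  end <- as.integer(raw$end)
  if (one_based_inclusive) start <- start - 1L
  ok <- start >= 0L & end > start
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " annotation row(s) rejected (end <= start after conversion)")
  }
  df <- annotation_table(
    protein_id = raw$protein_id[ok], start = start[ok], end = end[ok],
    label = raw$label[ok], source = raw$source[ok],
    score = if ("score" %in% names(raw)) suppressWarnings(as.numeric(raw$score[ok])) else NA_real_
  )
  attr(df, "n_dropped") <- n_dropped
  attr(df, "n_rejected") <- n_rejected
  df
}

#' Write an annotation table
#'
#' Inverse of [read_annotations()]: internal 0-based half-open
#' coordinates are converted back to 1-based inclusive when requested, so
#' read/write is an involution on clean tables.
#'
#' @param annotations annotation `data.frame`.
#' @param path output path.
#' @param one_based_inclusive logical, as in [read_annotations()].
#' @export
write_annotations <- function(annotations, path, one_based_inclusive = TRUE) {
  out <- annotations
  if (one_based_inclusive) out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a per-protein embedding store
#'
#' The store holds one named `L x D` numeric matrix per protein in a
#' single file (R serialization, which round-trips every float
#' bit-exactly). Half- or single-precision inputs from other toolchains
#' are promoted to double on read. All matrices in one store must share
#' the embedding dimension `D`.
#'
#' @param store named list of numeric matrices (names are protein ids).
#' @param path file path.
#' @return `read_embedding_store()` returns the named list of matrices.
#' @export
write_embedding_store <- function(store, path) {
  check_embedding_store(store)
  saveRDS(store, path, version = 3)
  invisible(path)
}

#' @rdname write_embedding_store
#' @param sequences optional named character vector; when given, each
#'   matrix's row count is checked against its sequence length.
#' @export
read_embedding_store <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("embedding store not found: ", path)
  store <- readRDS(path)
  check_embedding_store(store, sequences)
  store
}

check_embedding_store <- function(store, sequences = NULL) {
  stopifnot(is.list(store))
  if (length(store) == 0) return(invisible(store))
  if (is.null(names(store)) || any(!nzchar(names(store)))) {
    stop("embedding store entries must be named by protein id")
  }
  dims <- vapply(store, ncol, integer(1))
  if (length(unique(dims)) > 1) {
    stop("inconsistent embedding dimension across store: D = ",
         paste(sort(unique(dims)), collapse = ", "))
  }
  for (id in names(store)) {
    m <- store[[id]]
    if (!is.matrix(m) || !is.numeric(m)) stop("store entry is not a numeric matrix: ", id)
    if (!all(is.finite(m))) stop("non-finite embedding values for protein: ", id)
    if (!is.null(sequences) && id %in% names(sequences) &&
        nrow(m) != nchar(sequences[[id]])) {
      stop("embedding rows (", nrow(m), ") do not match sequence length (",
           nchar(sequences[[id]]), ") for protein: ", id)
    }
  }
  invisible(store)
}

#' Write segments as a BED-like TSV
#'
#' Output columns are `protein_id, start, end, score, color` in 0-based
#' half-open coordinates (stated in a header comment), sorted by
#' `(protein_id, start)` so the output is deterministic. Colours are
#' serialized as `"R,G,B"`.
#'
#' @param segments segment `data.frame` (see [segment_table()]).
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  seg <- segments[order(segments$protein_id, segments$start), , drop = FALSE]
  if (is.null(seg$score)) seg$score <- NA_real_
  if (is.null(seg$color)) seg$color <- NA_character_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords=0-based,half-open", con)
  writeLines("protein_id\tstart\tend\tscore\tcolor", con)
  if (nrow(seg) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                     seg$protein_id, seg$start, seg$end,
                     ifelse(is.na(seg$score), ".", format(seg$score, digits = 10)),
                     ifelse(is.na(seg$color), ".", seg$color))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  # any interval table with protein_id/start/end qualifies; score and
  # colour columns are optional
  score <- if ("score" %in% names(raw)) {
    ifelse(raw$score == ".", NA, suppressWarnings(as.numeric(raw$score)))
  } else NA_real_
  color <- if ("color" %in% names(raw)) {
    ifelse(raw$color == ".", NA_character_, raw$color)
  } else NA_character_
  segment_table(
    protein_id = raw$protein_id,
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    score = score,
    color = color
  )
}
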