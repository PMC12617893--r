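#' Shuffle-based enrichment test for a residue cluster
#'
#' Tests whether a residue cluster (e.g. an embedding-defined arginine
#' cluster) is enriched for flagged sites (e.g. annotated methylation
#' sites). The observed statistic is the fraction of residues in the
#' target cluster that are flagged. The null distribution is obtained
#' by permuting the flags among exchangeable residues — within each
#' protein (`scope = "within_protein"`, i.e. among residues of the same
#' type in the same protein, the input being restricted to one residue
#' type) or within each annotated region (`scope = "within_region"`,
#' which requires a `region_id` column). Each shuffle is a permutation
#' without replacement. The empirical p-value is the fraction of null
#' statistics at least as large as the observed one, reported as
#' `"<1/n"` when none reaches it (no +1 smoothing).
#'
#' @param residues `data.frame` with columns `protein_id`, `flag`
#'   (logical), `cluster`, and `region_id` when
#'   `scope = "within_region"`.
#' @param target_cluster the cluster whose flag fraction is tested.
#' @param scope `"within_protein"` or `"within_region"`.
#' @param n number of shuffles (default 10000).
#' @param seed RNG seed.
#' @return list of class `"zps_shuffle"` with `observed_fraction`,
#'   `null_mean`, `null_sd`, `z_score`, `empirical_p` (numeric,
#'   `r / n`), `p_label` (`"r/n"` or `"<1/n"`), `n_shuffles`.
#' @export
shuffle_enrichment_test <- function(residues, target_cluster,
                                    scope = c("within_protein", "within_region"),
                                    n = 10000L, seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(all(c("protein_id", "flag", "cluster") %in% names(residues)))
  if (scope == "within_region" && !"region_id" %in% names(residues)) {
    stop("scope = \"within_region\" requires a region_id column")
  }
  flag <- as.logical(residues$flag)
  in_cluster <- residues$cluster == target_cluster
  if (!any(in_cluster)) stop("target cluster is empty")
  if (!any(flag)) stop("no flagged residues anywhere")
  group <- if (scope == "within_protein") residues$protein_id
           else paste(residues$protein_id, residues$region_id, sep = "\r")
  idx_by_group <- split(seq_along(flag), group)
  cluster_size <- sum(in_cluster)
  observed <- sum(flag & in_cluster) / cluster_size
  null <- with_local_seed(seed, {
    vapply(seq_len(n), function(s) {
      shuffled <- flag
      for (idx in idx_by_group) {
        if (length(idx) > 1) shuffled[idx] <- flag[sample(idx)]
      }
      sum(shuffled & in_cluster) / cluster_size
    }, numeric(1))
  })
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  r <- sum(null >= observed)
  structure(list(
    observed_fraction = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    z_score = if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_,
    empirical_p = r / n,
    p_label = if (r == 0) paste0("<1/", n) else paste0(r, "/", n),
    n_shuffles = n
  ), class = "zps_shuffle")
}

#' @export
print.zps_shuffle <- function(x, ...) {
  cat(sprintf("shuffle enrichment test (n = %d)\n", x$n_shuffles))
  cat(sprintf("  observed fraction: %.3f  null: %.3f +/- %.3f\n",
              x$observed_fraction, x$null_mean, x$null_sd))
  cat(sprintf("  Z-score = %.2f, empirical P-value = %s\n",
              x$z_score, x$p_label))
  invisible(x)
}

#' Cluster unannotated segments by graph communities (Leiden)
#'
#' Builds a cosine k-nearest-neighbour graph over the segment
#' embeddings in their full dimension (no dimensionality reduction
#' before clustering) and partitions it with the Leiden algorithm at
#' resolution 2, iterated to convergence. Deterministic for a fixed
#' seed; every segment receives a label. Fewer than 2 segments form a
#' single cluster.
#'
#' @param E segment-embedding matrix (one row per unannotated segment).
#' @param resolution Leiden resolution parameter (default 2).
#' @param k neighbours for the kNN graph (default 15, capped at
#'   `n - 1`).
#' @param seed RNG seed.
#' @return integer cluster labels, one per row.
#' @export
cluster_unannotated <- function(E, resolution = 2, k = 15L, seed = 1L) {
  if (is.vector(E)) E <- matrix(E, nrow = 1)
  n <- nrow(E)
  if (n < 2) return(rep(1L, n))
  k <- min(k, n - 1L)
  S <- cosine_similarity_matrix(E)
  off <- S[upper.tri(S)]
  # structureless input (all pairwise similarities equal, e.g. identical
  # embeddings): nothing to partition
  if (max(off) - min(off) < 1e-12) return(rep(1L, n))
  diag(S) <- -Inf
  edges <- integer(0)
  weights <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(-S[i, ])[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
    weights <- c(weights, pmax(S[i, nb], 1e-12))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::E(g)$weight <- weights
  g <- igraph::simplify(g, edge.attr.comb = "max")
  memb <- with_local_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = -1)$membership
  })
  as.integer(memb)
}
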