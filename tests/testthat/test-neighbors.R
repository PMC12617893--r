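brute_force_nn <- function(E, segments, policy) {
  n <- nrow(E)
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- -Inf; bi <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      same <- segments$protein_id[i] == segments$protein_id[j]
      if (policy$exclude == "protein" && same) next
      adj <- same && (segments$end[i] == segments$start[j] ||
                      segments$start[i] == segments$end[j])
      if (policy$exclude == "adjacent" && adj) next
      s <- sum(E[i, ] * E[j, ]) /
        (sqrt(sum(E[i, ]^2)) * sqrt(sum(E[j, ]^2)))
      if (s > best) { best <- s; bi <- j }
    }
    out[i] <- bi
  }
  out
}

test_that("exact 1-nn matches a brute-force distance scan under both policies", {
  set.seed(73)
  n <- 80
  E <- matrix(rnorm(n * 6), n, 6)
  seg <- segment_table(protein_id = rep(paste0("P", 1:20), each = 4),
                       start = rep(c(0, 25, 50, 75), 20),
                       end = rep(c(25, 50, 75, 100), 20))
  for (pol in list(nn_policy("adjacent"), nn_policy("protein"))) {
    expect_identical(nearest_neighbors(E, seg, pol),
                     brute_force_nn(E, seg, pol))
  }
})

test_that("an excluded raw nearest falls through to the next nearest", {
  # segment 2 is adjacent to segment 1 on the same protein and is its
  # closest vector; segment 3 (other protein) is second closest
  E <- rbind(c(1, 0), c(0.99, 0.1), c(0.9, 0.2), c(-1, 0.5))
  seg <- segment_table(protein_id = c("P1", "P1", "P2", "P2"),
                       start = c(0, 50, 0, 60), end = c(50, 90, 60, 80))
  nn <- nearest_neighbors(E, seg, nn_policy("adjacent"))
  expect_equal(nn[1], 3)   # not the adjacent segment 2
  nn_free <- nearest_neighbors(E, seg, nn_policy("protein"))
  expect_equal(nn_free[1], 3)
  expect_error(nearest_neighbors(E[1:2, ], seg[1:2, ], nn_policy("protein")),
               "no admissible neighbour")
})

test_that("well-separated classes give an identity confusion matrix", {
  corp <- tiny_nn_corpus(n_per_class = 8, n_classes = 3, seed = 79)
  res <- evaluate_multiclass_1nn(corp$E, corp$segments)
  expect_equal(unname(res$precision), c(1, 1, 1))
  expect_equal(res$average_precision, 1)
  off <- res$normalized; diag(off) <- 0
  expect_true(all(off == 0, na.rm = TRUE))
})

test_that("confusion columns are prediction-normalized with matching CIs", {
  set.seed(83)
  n <- 40
  E <- matrix(rnorm(n * 5), n, 5)
  seg <- segment_table(protein_id = paste0("P", 1:n), start = 0, end = 10)
  seg$label <- sample(c("A", "B", "C"), n, replace = TRUE)
  res <- evaluate_multiclass_1nn(E, seg)
  sums <- colSums(res$normalized)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
  # diagonal equals an independent per-label recount
  nn <- nearest_neighbors(E, seg, nn_policy("adjacent"))
  for (l in colnames(res$confusion)) {
    predicted_l <- which(seg$label[nn] == l)
    if (length(predicted_l) == 0) next
    expect_equal(unname(res$precision[l]),
                 mean(seg$label[predicted_l] == l))
    expect_equal(unname(res$ci[l, ]),
                 binom_ci(sum(seg$label[predicted_l] == l), length(predicted_l)),
                 ignore_attr = TRUE)
  }
})

test_that("Wald and Wilson intervals match their closed forms", {
  p <- 0.8; n <- 10; z <- qnorm(0.975)
  expect_equal(binom_ci(8, 10),
               c(p - z * sqrt(p * (1 - p) / n),
                 min(1, p + z * sqrt(p * (1 - p) / n))))
  p2 <- 0.5
  expect_equal(binom_ci(5, 10),
               p2 + c(-1, 1) * z * sqrt(p2 * (1 - p2) / n))
  w <- binom_ci(8, 10, method = "wilson")
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  expect_lt(abs(mean(w) - centre), 1e-10)
  expect_equal(binom_ci(10, 10)[2], 1)   # clamped
})

test_that("multilabel 1-nn tallies equal an exhaustive recount", {
  set.seed(89)
  n <- 30
  E <- matrix(rnorm(n * 4), n, 4)
  seg <- segment_table(protein_id = paste0("P", 1:n), start = 0, end = 10)
  seg$labels <- lapply(1:n, function(i) {
    sample(c("x", "y"), sample(0:2, 1))
  })
  res <- evaluate_multilabel_1nn(E, seg)
  nn <- nearest_neighbors(E, seg, nn_policy("adjacent"))
  for (l in c("x", "y")) {
    truth <- vapply(seg$labels, function(s) l %in% s, logical(1))
    pred <- vapply(seg$labels[nn], function(s) l %in% s, logical(1))
    row <- res[res$label == l, ]
    expect_equal(row$tp, sum(truth & pred))
    expect_equal(row$fp, sum(!truth & pred))
    expect_equal(row$fn, sum(truth & !pred))
    expect_equal(row$tn, sum(!truth & !pred))
  }
})

test_that("identical neighbour label sets give precision 1 everywhere", {
  E <- rbind(c(1, 0), c(1, 0.001), c(0, 1), c(0.001, 1))
  seg <- segment_table(protein_id = paste0("P", 1:4), start = 0, end = 10)
  seg$labels <- list(c("a"), c("a"), c("b"), c("b"))
  res <- evaluate_multilabel_1nn(E, seg)
  expect_equal(res$precision, c(1, 1))
})

test_that("knn_query pools, dedupes, and joins adjacent hits", {
  corpus_seg <- segment_table(
    protein_id = c("P1", "P1", "P2", "P3"),
    start = c(0, 50, 0, 0), end = c(50, 90, 40, 30))
  corpus_E <- rbind(c(1, 0), c(0.95, 0.05), c(0, 1), c(-1, 0))
  query_seg <- segment_table("Q1", 0, 20)
  res <- knn_query(matrix(c(1, 0), 1), query_seg, corpus_E, corpus_seg, k = 2)
  # top-2 hits are the two adjacent P1 segments -> joined to one interval
  expect_equal(nrow(res), 1)
  expect_equal(c(res$start, res$end), c(0, 90))

  # a duplicate embedding under another id ranks first and is kept
  res2 <- knn_query(corpus_E[3, , drop = FALSE],
                    segment_table("Q2", 0, 10), corpus_E, corpus_seg, k = 1)
  expect_equal(res2$protein_id, "P2")

  expect_warning(knn_query(matrix(c(1, 0), 1), query_seg, corpus_E,
                           corpus_seg, k = 10), "exceeds corpus size")
})
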