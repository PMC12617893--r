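test_that("rbf_cost matches its closed forms and the double-loop oracle", {
  gamma <- 0.5
  expect_equal(rbf_cost(matrix(1, 5, 3), gamma), 0)
  expect_equal(rbf_cost(matrix(c(1, 2, 3), 1, 3), gamma), 0)

  # two distinct rows at squared distance d2 -> 1 - exp(-gamma d2)
  rows <- rbind(c(0, 0), c(3, 4))
  d2 <- 25
  expect_equal(rbf_cost(rows, gamma), 1 - exp(-gamma * d2), tolerance = 1e-12)
  expect_equal(rbf_cost(rows, gamma), rbf_cost_oracle(rows, gamma),
               tolerance = 1e-12)

  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(rnorm(20 * 6), 20, 6)
    g <- 1 / median(as.vector(dist(m))^2)
    expect_equal(rbf_cost(m, g), rbf_cost_oracle(m, g), tolerance = 1e-9)
  }
  expect_error(rbf_cost(matrix(c(1, NA), 1, 2), gamma), "non-finite")
})

test_that("gain_curve equals a from-scratch evaluation of the window formula", {
  set.seed(5)
  m <- matrix(rnorm(60 * 4), 60, 4)
  cfg <- changepoint_config(window = 10, rbf_bandwidth_rule = "fixed",
                            bandwidth_value = 0.3)
  cv <- gain_curve(m, cfg)
  h <- 5L
  for (idx in seq_along(cv$positions)) {
    t <- cv$positions[idx]
    full <- m[(t - h + 1):(t + h), , drop = FALSE]
    left <- m[(t - h + 1):t, , drop = FALSE]
    right <- m[(t + 1):(t + h), , drop = FALSE]
    oracle <- rbf_cost(full, 0.3) - rbf_cost(left, 0.3) - rbf_cost(right, 0.3)
    expect_equal(cv$gains[idx], oracle, tolerance = 1e-8)
  }
  expect_equal(range(cv$positions), c(5, 55))
})

test_that("gain_curve degenerate cases: constant matrix and short proteins", {
  cv <- gain_curve(matrix(2, 80, 4))
  expect_true(all(abs(cv$gains) < 1e-8))
  expect_length(select_boundaries(cv), 0)

  short <- gain_curve(matrix(rnorm(29 * 4), 29, 4))   # L = window - 1
  expect_length(short$positions, 0)
  seg <- zps_segment(matrix(rnorm(29 * 4), 29, 4), "P1", score = FALSE)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(0, 29))
})

test_that("gain curve peaks at a planted two-block boundary", {
  means <- rbind(rep(0, 8), rep(3, 8))
  m <- block_matrix(c(60, 60), means)
  cv <- gain_curve(m)
  expect_equal(cv$positions[which.max(cv$gains)], 60)
})

test_that("select_boundaries applies peaks, spacing, and the budget", {
  mkcurve <- function(gains, L, w = 30L) {
    list(positions = seq.int(w / 2, length.out = length(gains)),
         gains = gains, window = w, L = L)
  }
  expect_length(select_boundaries(mkcurve(rep(0, 50), 100)), 0)

  g <- rep(0, 50); g[20] <- 5
  expect_equal(select_boundaries(mkcurve(g, 100)), 15 + 19)

  # 10 strong well-separated peaks on L = 100 -> budget caps at 3
  g2 <- rep(0, 171)                      # positions 15..185 on L = 100
  peak_at <- seq(5, 170, by = 17)
  g2[peak_at] <- 10 + seq_along(peak_at) # distinct heights
  cfg <- changepoint_config()
  chosen <- select_boundaries(mkcurve(g2, 100), cfg)
  expect_length(chosen, ceiling(3 * 100 / 100))
  # the three highest peaks win
  top3 <- sort((15:185)[order(-g2)[1:3]])
  expect_equal(chosen, top3)
})

test_that("segments tile the protein for any boundary outcome", {
  spec <- synthetic_spec(n_proteins = 5, noise_sd = 1, mean_separation = 2,
                         seed = 21)
  for (i in 1:5) {
    p <- make_protein(spec, i)
    seg <- zps_segment(p$matrix, p$protein_id, score = FALSE)
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], nrow(p$matrix))
    if (nrow(seg) > 1) expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
})

test_that("three-block synthetic proteins recover planted boundaries", {
  spec <- synthetic_spec(n_proteins = 10, noise_sd = 1, mean_separation = 2,
                         seed = 31)
  for (i in 1:10) {
    p <- make_protein(spec, i)
    seg <- zps_segment(p$matrix, score = FALSE)
    found <- seg$start[-1]
    for (b in p$boundaries) {
      expect_lte(min(abs(found - b)), 3)
    }
  }
})

test_that("boundary t-scores are zero for identical flanks and grow with shift", {
  base <- matrix(rnorm(30 * 4), 30, 4)
  mirrored <- rbind(base[1:15, ], base[1:15, ])
  expect_equal(boundary_score(mirrored, 15), 0)

  set.seed(13)
  deltas <- c(0.5, 1, 2, 4)
  scores <- vapply(deltas, function(d) {
    mean(replicate(20, {
      m <- matrix(rnorm(30 * 4), 30, 4)
      m[16:30, 1] <- m[16:30, 1] + d
      boundary_score(m, 15)
    }))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("segment scores average the two flanking boundary scores", {
  set.seed(17)
  m <- matrix(rnorm(90 * 4), 90, 4)
  seg <- segment_table("P1", start = c(0, 30, 60), end = c(30, 60, 90))
  s <- segment_scores(seg, m)
  b1 <- boundary_score(m, 30)
  b2 <- boundary_score(m, 60)
  expect_equal(s, c(b1, mean(c(b1, b2)), b2))
})
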