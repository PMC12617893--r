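test_that("iou matches its closed form and the position-set oracle", {
  expect_equal(iou(0, 10, 0, 10), 1)
  expect_equal(iou(0, 10, 20, 30), 0)
  expect_equal(iou(0, 10, 5, 15), 5 / 15)
  expect_equal(iou(0, 10, 5, 15), iou_positions(0, 10, 5, 15))

  set.seed(61)
  for (rep in 1:100) {
    a <- sort(sample(0:50, 2)); if (a[1] == a[2]) a[2] <- a[2] + 1
    b <- sort(sample(0:50, 2)); if (b[1] == b[2]) b[2] <- b[2] + 1
    expect_identical(iou(a[1], a[2], b[1], b[2]),
                     iou_positions(a[1], a[2], b[1], b[2]))
  }
})

test_that("filter_positives applies length and whole-protein rules", {
  lens <- c(P1 = 60, P2 = 59, P3 = 200)
  ann <- annotation_table(
    protein_id = c("P1", "P1", "P2", "P3"),
    start = c(0, 0, 0, 0),
    end = c(29, 30, 40, 200),
    label = "x")
  out <- filter_positives(ann, lens)
  expect_equal(nrow(out), 1)
  expect_equal(out$protein_id, "P1")   # 30 aa on a 60-aa protein is kept
  # 29-aa too short; P2 protein too short; P3 spans the whole protein
})

test_that("evaluate_segmentation is exact on identity and toy layouts", {
  pos <- segment_table("P1", start = c(0, 50), end = c(40, 100))
  ev <- evaluate_segmentation(pos, pos)
  expect_equal(ev$aiou_pred, 1)
  expect_equal(ev$aiou_pos, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$unpaired_pos, 0)

  lonely <- segment_table("P1", start = 200, end = 240)
  pos1 <- segment_table("P1", start = 0, end = 40)
  ev2 <- evaluate_segmentation(lonely, pos1)
  expect_equal(ev2$precision, 0)
  expect_equal(ev2$unpaired_pos, 1)

  # 3 preds / 2 pos toy layout vs an exhaustive all-pairs oracle
  pred <- segment_table("P1", start = c(0, 45, 80), end = c(35, 75, 95))
  pos2 <- segment_table("P1", start = c(0, 50), end = c(40, 78))
  ev3 <- evaluate_segmentation(pred, pos2)
  all_iou <- outer(seq_len(3), seq_len(2), function(i, j) {
    iou(pred$start[i], pred$end[i], pos2$start[j], pos2$end[j])
  })
  expect_equal(ev3$aiou_pred, mean(apply(all_iou, 1, max)))
  expect_equal(ev3$aiou_pos, mean(apply(all_iou, 2, max)))
  expect_equal(ev3$precision, mean(apply(all_iou, 1, max) >= 0.5))
  expect_equal(ev3$recall, mean(apply(all_iou, 2, max) >= 0.5))
})

test_that("empty predictions give undefined precision and zero recall", {
  pos <- segment_table("P1", start = 0, end = 40)
  ev <- evaluate_segmentation(pos[0, ], pos)
  expect_true(is.na(ev$precision))
  expect_equal(ev$recall, 0)
})

test_that("match counts are non-increasing in the IoU threshold", {
  set.seed(67)
  pred <- random_intervals(20, 200)
  pos <- random_intervals(10, 200)
  thresholds <- seq(0, 1, by = 0.1)
  tp_pred <- vapply(thresholds, function(th) {
    ev <- evaluate_segmentation(pred, pos, th)
    ev$precision * ev$n_pred
  }, numeric(1))
  expect_true(all(diff(tp_pred) <= 0))
})

test_that("boundary-distance accounting counts unpaired as two misses", {
  pred <- segment_table("P1", start = 10, end = 50)
  pos <- segment_table("P1", start = 12, end = 48)
  bd <- boundary_distance_eval(pred, pos)
  expect_equal(bd$fraction_within, 1)            # distances 2 and 2

  pos2 <- segment_table("P1", start = c(12, 200), end = c(48, 260))
  bd2 <- boundary_distance_eval(pred, pos2)
  expect_equal(bd2$n_unpaired, 1)
  expect_equal(bd2$fraction_within, 2 / 4)

  exact <- boundary_distance_eval(pos, pos)
  expect_equal(exact$pct_within, 100)
})

test_that("the <10 rule is strict and distances come from the best-IoU pair", {
  pred <- segment_table("P1", start = c(0, 15), end = c(30, 45))
  pos <- segment_table("P1", start = 10, end = 40)   # best IoU partner: (15,45)
  bd <- boundary_distance_eval(pred, pos, tol = 10)
  expect_equal(bd$n_within, 2)                        # distances 5 and 5
  off <- segment_table("P1", start = 0, end = 30)
  pos10 <- segment_table("P1", start = 10, end = 40)  # distances exactly 10
  expect_equal(boundary_distance_eval(off, pos10, tol = 10)$n_within, 0)
})

test_that("dedupe keeps the better-scoring member of overlapping pairs", {
  two <- segment_table("P1", start = c(0, 0), end = c(40, 40),
                       score = c(5, 3))
  out <- dedupe_overlapping_predictions(two, direction = "higher_better")
  expect_equal(out$score, 5)

  low <- segment_table("P1", start = c(0, 25), end = c(40, 65),
                       score = c(1e-9, 1e-3))
  # IoU = 15/65 < 0.5: both kept
  expect_equal(nrow(dedupe_overlapping_predictions(low, direction = "lower_better")), 2)

  # chain of three mutually overlapping predictions: greedy keeps the best
  chain <- segment_table("P1", start = c(0, 5, 10), end = c(40, 45, 50),
                         score = c(2, 9, 4))
  out3 <- dedupe_overlapping_predictions(chain, direction = "higher_better")
  # greedy rule by hand: keep 9; (5,45) kills (0,40) (IoU 35/45) and
  # (10,50) (IoU 35/45); survivors = the middle one only
  expect_equal(out3$score, 9)
  expect_error(dedupe_overlapping_predictions(segment_table("P1", 0, 10)),
               "score")
})

test_that("pr_at_k is consistent with the global evaluation at k = n", {
  pos <- segment_table("P1", start = c(0, 50, 120), end = c(40, 100, 160))
  pred <- pos
  pred$score <- c(3, 2, 1)
  curve <- pr_at_k(pred, pos)
  expect_equal(curve$precision, c(1, 1, 1))      # perfect predictor
  expect_equal(curve$recall, c(1 / 3, 2 / 3, 1))

  set.seed(71)
  pred2 <- random_intervals(12, 300)
  pred2$score <- runif(nrow(pred2))
  pos2 <- random_intervals(6, 300)
  curve2 <- pr_at_k(pred2, pos2)
  global <- evaluate_segmentation(pred2, pos2)
  expect_identical(curve2$precision[nrow(curve2)], global$precision)
  expect_identical(curve2$recall[nrow(curve2)], global$recall)
})
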