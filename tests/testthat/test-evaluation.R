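test_that("iou handles identity, disjointness and partial overlap", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(50, 50, 5, 5)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 1 / 3)
  expect_equal(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), 0)  # zero-area box
})

test_that("greedy one-to-one matching produces the expected counts", {
  ann1 <- data.frame(frame = "f1", x = 10, y = 10, w = 40, h = 20,
                     label = "lying")
  det1 <- data.frame(frame = "f1", x = 10, y = 10, w = 40, h = 20)
  c1 <- match_and_count(det1, ann1, 0.5)
  expect_equal(unlist(c1[c("TP", "FP", "FN", "TN")]),
               c(TP = 1L, FP = 0L, FN = 0L, TN = 0L))

  # detection with no annotation: false positive
  c2 <- match_and_count(det1, ann1[0, ], 0.5, frames = "f1")
  expect_equal(c2$FP, 1L)

  # two detections on one annotation: one TP, one FP
  det3 <- rbind(det1, data.frame(frame = "f1", x = 12, y = 10, w = 40, h = 20))
  c3 <- match_and_count(det3, ann1, 0.5)
  expect_equal(c(c3$TP, c3$FP, c3$FN), c(1L, 1L, 0L))

  # threshold 1.0 accepts only pixel-identical boxes
  det4 <- data.frame(frame = "f1", x = 11, y = 10, w = 40, h = 20)
  c4 <- match_and_count(det4, ann1, 1.0)
  expect_equal(c(c4$TP, c4$FP, c4$FN), c(0L, 1L, 1L))
  c5 <- match_and_count(det1, ann1, 1.0)
  expect_equal(c5$TP, 1L)

  # empty frames counted as true negatives when enumerated
  c6 <- match_and_count(det1, ann1, 0.5, frames = c("f1", "f2", "f3"))
  expect_equal(c6$TN, 2L)
})

test_that("metric ratios and the two F1 forms agree", {
  s <- metrics(list(TP = 8, TN = 8, FP = 2, FN = 2))
  expect_equal(unlist(s[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.8, precision = 0.8, recall = 0.8, f1 = 0.8))

  expect_warning(s2 <- metrics(list(TP = 0, TN = 0, FP = 0, FN = 5)),
                 "precision")
  expect_equal(c(s2$precision, s2$recall, s2$f1), c(0, 0, 0))

  s3 <- metrics(list(TP = 1, TN = 0, FP = 0, FN = 1))  # P=1, R=0.5
  expect_equal(s3$f1, 2 / 3)

  expect_error(metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")

  set.seed(8)
  for (i in 1:200) {
    cc <- as.list(setNames(sample(0:50, 4, TRUE), c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cc)) == 0) next
    s <- suppressWarnings(metrics(cc))
    alt <- if (2 * cc$TP + cc$FP + cc$FN > 0)
      2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN) else 0
    expect_equal(s$f1, alt, tolerance = 1e-12)
  }
})

test_that("F1 never increases as the IoU threshold rises", {
  set.seed(9)
  ann <- data.frame(frame = rep(paste0("f", 1:10), each = 2),
                    x = runif(20, 0, 500), y = runif(20, 0, 300),
                    w = runif(20, 40, 90), h = runif(20, 20, 50),
                    label = "lying")
  det <- ann
  det$x <- det$x + runif(20, -15, 15)
  det$w <- det$w * runif(20, 0.8, 1.2)
  f1s <- sapply(seq(0.1, 0.9, by = 0.1), function(thr)
    suppressWarnings(
      evaluate_detections(det, ann, thr, frames = unique(ann$frame)))$f1)
  expect_true(all(diff(f1s) <= 1e-12))
})

test_that("status rule flags prolonged lying at the printed boundary", {
  r1 <- daily_status(c(rep(TRUE, 6), rep(FALSE, 4)), id = "cage-7")
  expect_equal(r1$lying_fraction, 0.6)
  expect_equal(r1$status, "abnormal")

  expect_equal(daily_status(rep(FALSE, 10))$status, "normal")
  # exactly half the photographed time: abnormal branch
  expect_equal(daily_status(rep(c(TRUE, FALSE), 5))$status, "abnormal")
  expect_equal(daily_status(data.frame(lying = c(0, 0, 1)))$lying_fraction,
               1 / 3)
  expect_error(daily_status(logical(0)), "no observations")
})

test_that("a one-point grid returns that point", {
  dir <- withr::local_tempdir()
  generate_dataset(2, scene_config(seed = 81), dir)
  gs <- grid_search(dir, list(k2 = 65, k3 = 250))
  expect_equal(gs$best$k2, 65)
  expect_equal(gs$best$k3, 250)
  expect_equal(nrow(gs$table), 1)
  expect_gte(gs$best_f1, 0.5)
  expect_error(grid_search(dir, list()), "non-empty")
  expect_error(grid_search(dir, list(k9 = 1)), "unknown")
})
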