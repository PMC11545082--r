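test_that("dynamic threshold applies strict per-column bounds", {
  depth <- matrix(600L, 40, 30)        # trough rows 0..19, key rows 20..39
  tr <- cagepose:::trough_location(0, 20, 0, 30)
  key <- structure(list(x = 0L, y = 20L, w = 30L, h = 20L),
                   class = "key_area")
  depth[21:40, ] <- 1000L
  depth[25, 1] <- 700L    # inside (665, 850): foreground
  depth[25, 2] <- 660L    # at/below lower bound: background
  depth[25, 3] <- 665L    # exactly d_c + k2: excluded (strict)
  depth[25, 4] <- 850L    # exactly d_c + k3: excluded (strict)
  depth[25, 5] <- 0L      # dropout: background
  depth[11, 6] <- 0L      # reference row dropout: whole column skipped
  depth[25, 6] <- 700L
  mask <- segment_key_area(depth, tr, key, k2 = 65, k3 = 250)
  expect_true(mask[5, 1])
  expect_false(any(mask[5, 2:6]))
  expect_error(segment_key_area(depth, tr, key, k2 = 250, k3 = 65), "k2 < k3")
})

test_that("segmentation equals the brute-force double loop", {
  set.seed(5)
  for (rep in 1:30) {
    depth <- matrix(sample(0:1200, 48 * 64, replace = TRUE), 48, 64)
    tr <- cagepose:::trough_location(5, 15, 0, 64)
    key <- structure(list(x = 4L, y = 15L, w = 56L, h = 25L),
                     class = "key_area")
    expect_identical(segment_key_area(depth, tr, key, 65, 250),
                     brute_segment_key_area(depth, tr, key, 65, 250))
  }
})

test_that("widening the depth band never shrinks the foreground", {
  sc <- generate_scene(scene_config(seed = 41))
  tr <- locate_trough_variance(sc$frame$depth)
  key <- compute_key_area(tr, c(640, 480))
  m1 <- segment_key_area(sc$frame$depth, tr, key, 80, 200)
  m2 <- segment_key_area(sc$frame$depth, tr, key, 65, 250)
  expect_true(all(m2[m1]))
})

test_that("denoising removes speckle but preserves large structures", {
  set.seed(6)
  mask <- matrix(FALSE, 60, 100)
  mask[cbind(sample(60, 40, TRUE), sample(100, 40, TRUE))] <- TRUE
  salt_only <- denoise_mask(mask)
  expect_lt(sum(salt_only), 5)

  rect <- matrix(FALSE, 60, 100)
  rect[11:40, 21:70] <- TRUE          # 30 x 50 solid block
  den <- denoise_mask(rect)
  expect_true(all(den[13:38, 23:68]))
  expect_true(all(!den[c(1:9, 42:60), ]))

  empty <- matrix(FALSE, 10, 10)
  expect_identical(denoise_mask(empty), empty)
})

test_that("column filter keeps columns strictly above H/k4", {
  mask <- matrix(FALSE, 100, 3)
  mask[1:51, 1] <- TRUE   # 51 > 100/2: kept
  mask[1:50, 2] <- TRUE   # 50 = 100/2 exactly: erased (strict)
  mask[1:49, 3] <- TRUE
  out <- filter_columns(mask, H_roi = 100, k4 = 2.0)
  expect_equal(colSums(out), c(51, 0, 0))

  allw <- matrix(TRUE, 20, 5)
  expect_identical(filter_columns(allw, 20, 2.0), allw)
})

test_that("contour merging fuses nearby blobs by contour distance", {
  m <- matrix(FALSE, 60, 100)
  m[11:30, 11:30] <- TRUE
  m[11:30, 46:65] <- TRUE   # 15-px horizontal gap: below threshold
  merged <- merge_contours(m, gap = 20)
  expect_equal(max(EBImage::bwlabel(merged * 1)), 1)

  m2 <- matrix(FALSE, 60, 100)
  m2[11:30, 11:30] <- TRUE
  m2[11:30, 56:75] <- TRUE  # 25-px gap: stays split
  expect_equal(max(EBImage::bwlabel(merge_contours(m2, gap = 20) * 1)), 2)

  # large adjacent blobs: centroids 100 px apart, contours 3 px apart
  m3 <- matrix(FALSE, 60, 220)
  m3[11:50, 11:105] <- TRUE
  m3[11:50, 109:203] <- TRUE
  expect_equal(max(EBImage::bwlabel(merge_contours(m3, gap = 20) * 1)), 1)

  # idempotence
  once <- merge_contours(m, gap = 20)
  expect_identical(merge_contours(once, gap = 20), once)
})

test_that("box extraction enforces area and strict aspect-ratio rules", {
  m <- matrix(FALSE, 200, 300)
  m[11:50, 11:90] <- TRUE      # 80 x 40: ratio 2.0, kept
  m[61:150, 101:130] <- TRUE   # 30 x 90: pillar-like, dropped
  m[161:175, 141:148] <- TRUE  # small blob
  det <- extract_boxes(m, min_area = 200, k5 = 1.7)
  expect_equal(nrow(det), 1)
  expect_equal(det$w / det$h, 2.0)

  # ratio exactly k5 is excluded
  m2 <- matrix(FALSE, 100, 120)
  m2[11:60, 11:95] <- TRUE     # 85 x 50 = 1.7 exactly
  expect_equal(nrow(extract_boxes(m2, min_area = 50, k5 = 1.7)), 0)
})

test_that("full pipeline detects lying birds and rejects distractors", {
  sc <- generate_scene(scene_config(seed = 51), frame_id = "s51")
  det <- detect_lying(sc$frame, frame_id = "s51")
  truth <- sc$annotation$boxes
  lying <- truth[truth$label == "lying", ]
  expect_equal(nrow(det), 2)
  expect_true(all(det$w / det$h > 1.7))
  for (i in seq_len(nrow(det))) {
    best <- max(apply(lying, 1, function(b)
      iou(det[i, ], c(x = as.numeric(b["x"]), y = as.numeric(b["y"]),
                      w = as.numeric(b["w"]), h = as.numeric(b["h"])))))
    expect_gte(best, 0.5)
  }

  # standing birds only: leg strokes fail the column-fill rule
  sc2 <- generate_scene(scene_config(n_lying = 0, n_standing = 2,
                                     n_pillars = 1, seed = 52))
  expect_equal(nrow(detect_lying(sc2$frame)), 0)

  # empty cage
  sc3 <- generate_scene(scene_config(n_lying = 0, n_standing = 0,
                                     n_pillars = 0, seed = 53))
  expect_equal(nrow(detect_lying(sc3$frame)), 0)
})

test_that("a frame without a trough is skipped, not an error", {
  set.seed(7)
  noise <- merged_frame(array(sample(0:40, 480 * 640 * 3, TRUE),
                              c(480, 640, 3)),
                        matrix(sample(400:1600, 480 * 640, TRUE), 480, 640))
  expect_message(det <- detect_lying(noise, frame_id = "noise"), "skipped")
  expect_equal(nrow(det), 0)
  expect_true(isTRUE(attr(det, "skipped")))
})

test_that("detection parameter validation enforces the invariants", {
  expect_error(detection_params(k2 = 250, k3 = 65), "k2 < k3")
  expect_error(detection_params(k1 = -1), "positive")
  expect_error(detection_params(k4 = 0), "positive")
  expect_error(detection_params(merge_gap_px = -2), ">= 0")
})
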