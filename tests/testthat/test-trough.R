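test_that("row-variance locator finds the flat band", {
  sc <- generate_scene(scene_config(seed = 21))
  tr <- locate_trough_variance(sc$frame$depth)
  expect_lte(abs(tr$row_top - sc$truth$trough_rows[1]), 3)
  expect_lte(abs(tr$row_bottom - sc$truth$trough_rows[2]), 3)

  # a uniformly flat image marks every row: trough spans all of them
  flat <- matrix(700L, 480, 640)
  tr2 <- locate_trough_variance(flat)
  expect_lte(tr2$row_top, 1)
  expect_gte(tr2$row_bottom, 479)

  # pure high-variance noise: no row qualifies
  set.seed(1)
  noise <- matrix(sample(400:1600, 480 * 640, TRUE), 480, 640)
  expect_error(locate_trough_variance(noise), class = "trough_not_found")
})

test_that("dropout pixels never contribute to the row variance", {
  depth <- matrix(1000L, 480, 640)
  depth[, seq(60, 580, by = 3)] <- 0L  # heavy dropout, readings constant
  tr <- locate_trough_variance(depth)
  expect_lte(tr$row_top, 1)
  expect_gte(tr$row_bottom, 479)
})

test_that("keypoint-sparsity locator finds the keypoint-free band", {
  sc <- generate_scene(scene_config(seed = 22))
  tr <- locate_trough_features(sc$frame$depth)
  expect_lte(abs(tr$row_top - sc$truth$trough_rows[1]), 5)
  expect_lte(abs(tr$row_bottom - sc$truth$trough_rows[2]), 5)

  # detector returning no keypoints: every row is free -> full span
  none <- function(img8) data.frame(x = integer(0), y = integer(0))
  tr2 <- locate_trough_features(sc$frame$depth, detector = none)
  expect_lte(tr2$row_top, 1)
  expect_gte(tr2$row_bottom, 479)

  # keypoints on every row: nothing is free
  all_rows <- function(img8) data.frame(x = 10L, y = 0:(nrow(img8) - 1))
  expect_error(locate_trough_features(sc$frame$depth, detector = all_rows),
               class = "trough_not_found")
})

test_that("both locator methods agree on clean scenes", {
  for (seed in c(31, 32, 33)) {
    sc <- generate_scene(scene_config(seed = seed))
    tv <- locate_trough_variance(sc$frame$depth)
    tf <- locate_trough_features(sc$frame$depth)
    expect_lte(abs(tv$row_top - tf$row_top), 5)
    expect_lte(abs(tv$row_bottom - tf$row_bottom), 5)
  }
})

test_that("key area geometry follows the trough height", {
  tr <- make_trough(100, 200)        # height 100
  ka <- compute_key_area(tr, c(640, 480), k1 = 0.6)
  expect_equal(ka$h, 60)
  expect_equal(ka$w, 590)
  expect_equal(ka$y, 200)
  expect_equal(ka$x, 25)

  # degenerate 1-row trough still yields a key area
  expect_equal(compute_key_area(make_trough(100, 101), c(640, 480))$h, 1)

  # clipping at the image bottom
  tr2 <- make_trough(317, 450)       # ends 30 px above the bottom
  ka2 <- compute_key_area(tr2, c(640, 480), k1 = 0.6)  # 0.6*133 = 80 -> 30
  expect_equal(ka2$h, 30)

  expect_error(compute_key_area(tr, c(640, 480), k1 = 0), "positive")
})

test_that("key-area height is monotone in the trough height", {
  heights <- sapply(seq(10, 150, by = 10), function(hh)
    compute_key_area(make_trough(100, 100 + hh), c(640, 480), k1 = 0.6)$h)
  expect_true(all(diff(heights) >= 0))
})
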