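test_that("scene generation is deterministic given the seed", {
  a <- generate_scene(scene_config(seed = 61))
  b <- generate_scene(scene_config(seed = 61))
  expect_identical(a$frame$color, b$frame$color)
  expect_identical(a$frame$depth, b$frame$depth)
  expect_identical(a$annotation, b$annotation)
  c <- generate_scene(scene_config(seed = 62))
  expect_false(identical(a$frame$depth, c$frame$depth))
})

test_that("object counts are reflected in the annotation", {
  sc <- generate_scene(scene_config(n_lying = 0, n_standing = 1,
                                    n_pillars = 2, seed = 63))
  expect_equal(sum(sc$annotation$boxes$label == "lying"), 0)
  expect_equal(sum(sc$annotation$boxes$label == "pillar"), 2)
  sc2 <- generate_scene(scene_config(n_lying = 3, seed = 64))
  expect_equal(sum(sc2$annotation$boxes$label == "lying"), 3)
  bx <- sc2$annotation$boxes
  expect_true(all(bx$x >= 0 & bx$y >= 0 & bx$x + bx$w <= 640 &
                    bx$y + bx$h <= 480))
})

test_that("injected roll closes the loop with tilt estimation", {
  sc <- generate_scene(scene_config(roll_angle_deg = 2.0, seed = 65))
  te <- estimate_tilt(sc$frame)
  expect_true(te$found)
  expect_equal(te$angle_deg, 2.0, tolerance = 0.2)
})

test_that("noise-free scenes satisfy the stated depth invariants", {
  cfg <- scene_config(depth_noise_sd_mm = 0, dropout_fraction = 0, seed = 66)
  sc <- generate_scene(cfg)
  d <- sc$frame$depth
  cols <- 51:590
  rv <- apply(d[, cols], 1, var)
  tr <- cfg$trough_rows
  expect_true(all(rv[(tr[1] + 1):tr[2]] < 400))
  bg_rows <- c(30:150, 300:420)
  expect_true(all(rv[bg_rows] > 400))

  # every lying blob pixel is recoverable by the default (k2, k3) band
  band <- d > cfg$trough_depth_mm + 65 & d < cfg$trough_depth_mm + 250
  bx <- sc$annotation$boxes
  for (i in which(bx$label == "lying")) {
    sub <- band[(bx$y[i] + 1):(bx$y[i] + bx$h[i]),
                (bx$x[i] + 1):(bx$x[i] + bx$w[i])]
    expect_gt(mean(sub), 0.8)  # blob fills most of its own bounding box
  }
})

test_that("segmentation recovers generated blobs with few stray pixels", {
  cfg <- scene_config(depth_noise_sd_mm = 0, dropout_fraction = 0, seed = 67)
  sc <- generate_scene(cfg)
  tr <- locate_trough_variance(sc$frame$depth)
  key <- compute_key_area(tr, c(640, 480))
  mask <- segment_key_area(sc$frame$depth, tr, key, 65, 250)
  bx <- sc$annotation$boxes
  covered <- stray <- 0; blob_px <- bg_px <- 0
  inside_blob <- matrix(FALSE, key$h, key$w)
  for (i in which(bx$label %in% c("lying", "pillar", "standing"))) {
    rows <- pmax(bx$y[i] + 1, key$y + 1):pmin(bx$y[i] + bx$h[i], key$y + key$h)
    cols <- pmax(bx$x[i] + 1, key$x + 1):pmin(bx$x[i] + bx$w[i], key$x + key$w)
    inside_blob[rows - key$y, cols - key$x] <- TRUE
  }
  lying_mask <- matrix(FALSE, key$h, key$w)
  for (i in which(bx$label == "lying")) {
    rows <- pmax(bx$y[i] + 1, key$y + 1):pmin(bx$y[i] + bx$h[i], key$y + key$h)
    cols <- pmax(bx$x[i] + 1, key$x + 1):pmin(bx$x[i] + bx$w[i], key$x + key$w)
    lying_mask[rows - key$y, cols - key$x] <- TRUE
  }
  # mask covers at least 90% of lying-box interiors that are truly blob
  expect_gt(sum(mask & lying_mask) / sum(lying_mask), 0.7)
  # and almost none of the plain background
  expect_lt(sum(mask & !inside_blob) / sum(!inside_blob), 0.02)
})

test_that("dropout fraction matches the configuration", {
  cfg <- scene_config(dropout_fraction = 0.05, depth_noise_sd_mm = 0,
                      seed = 68)
  sc <- generate_scene(cfg)
  inner <- sc$frame$depth[, 51:590]
  expect_equal(mean(inner == 0), 0.05, tolerance = 0.01)
})

test_that("blob sizes scale with the configured profile", {
  w_at <- function(scale, seeds) {
    widths <- unlist(lapply(seeds, function(s) {
      bx <- generate_scene(scene_config(blob_scale = scale, n_lying = 2,
                                        n_standing = 0, n_pillars = 0,
                                        seed = s))$annotation$boxes
      bx$w[bx$label == "lying"]
    }))
    mean(widths)
  }
  seeds <- 101:115
  ratio <- w_at(0.8, seeds) / w_at(1.0, seeds)
  expect_equal(ratio, 0.8, tolerance = 0.05)
})

test_that("datasets regenerate bit-identically and carry annotations", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- scene_config(seed = 77)
  m1 <- generate_dataset(4, cfg, d1)
  m2 <- generate_dataset(4, cfg, d2)
  expect_equal(length(m1$frames), 4)
  expect_identical(list.files(d1, pattern = "png$"),
                   list.files(d2, pattern = "png$"))
  for (f in list.files(d1, pattern = "png$"))
    expect_identical(readBin(file.path(d1, f), "raw", 3e6),
                     readBin(file.path(d2, f), "raw", 3e6))
  man <- read_manifest(d1)
  expect_equal(length(man$frames), 4)
  expect_true(all(vapply(man$frames,
                         function(fr) is.data.frame(fr$boxes), logical(1))))

  expect_error(scene_config(trough_depth_mm = 1200), "nearer")
  expect_error(scene_config(lying_offset_range_mm = c(0, 100)), "inside")
})
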