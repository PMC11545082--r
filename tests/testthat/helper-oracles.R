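# Fixtures and independent oracles used across the suite.

# Small random frame (valid color/depth pair).
tiny_random_frame <- function(seed, W = 32, H = 24) {
  set.seed(seed)
  merged_frame(
    color = array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3)),
    depth = matrix(sample(0:65535, H * W, replace = TRUE), H, W))
}

# Clean deterministic frame: dark background with one bright horizontal
# band whose edges are the only strong y-gradients; depth mirrors it.
flat_band_frame <- function(W = 640, H = 480, rows = c(170, 260),
                            bright = 75, dark = 15) {
  gray <- matrix(dark, H, W)
  gray[(rows[1] + 1):rows[2], ] <- bright
  depth <- matrix(1000L, H, W)
  depth[(rows[1] + 1):rows[2], ] <- 600L
  merged_frame(array(rep(gray, 3), c(H, W, 3)), depth)
}

# Brute-force rotation-about-a-point: translate(-center) o rotate(clockwise
# on screen) o translate(center), composed as 3x3 homogeneous matrices.
brute_rotation_matrix <- function(angle_deg, center) {
  a <- angle_deg * pi / 180
  T1 <- rbind(c(1, 0, -center[1]), c(0, 1, -center[2]), c(0, 0, 1))
  R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  T2 <- rbind(c(1, 0, center[1]), c(0, 1, center[2]), c(0, 0, 1))
  (T2 %*% R %*% T1)[1:2, ]
}

# Naive double-loop implementation of the per-column dynamic threshold.
brute_segment_key_area <- function(depth, trough, key, k2, k3) {
  mid_row <- round((trough$row_top + trough$row_bottom) / 2)
  mid_row <- min(mid_row, trough$row_bottom - 1)
  out <- matrix(FALSE, key$h, key$w)
  for (j in seq_len(key$w)) {
    col <- key$x + j              # 1-based column index
    dc <- depth[mid_row + 1, col]
    if (dc == 0) next
    for (i in seq_len(key$h)) {
      d <- depth[key$y + i, col]
      if (d > 0 && dc + k2 < d && d < dc + k3) out[i, j] <- TRUE
    }
  }
  out
}

# A trough_location for synthetic geometry (internal constructor).
make_trough <- function(top, bottom, W = 640) {
  cagepose:::trough_location(top, bottom, 50, W - 50)
}

# Stack detections/annotations for a list of generated scenes.
scene_eval_inputs <- function(scenes, detections) {
  ann <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    bx <- scenes[[i]]$annotation$boxes
    if (nrow(bx)) bx$frame <- scenes[[i]]$annotation$frame
    else bx$frame <- character(0)
    bx
  }))
  det <- do.call(rbind, detections)
  list(detections = det, annotations = ann,
       frames = vapply(scenes, function(s) s$annotation$frame, character(1)))
}
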