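# Trough location in the corrected depth image, and derivation of the key
# area beneath it. The trough is a flat band facing the camera: its rows
# have near-constant depth (low variance, no interest points), which both
# locator methods exploit. Because the registered depth image carries black
# borders on the left and right, only columns [border_cols, W - border_cols)
# enter the analysis.

trough_not_found <- function(msg) {
  structure(class = c("trough_not_found", "error", "condition"),
            list(message = msg, call = NULL))
}

trough_location <- function(row_top, row_bottom, col_left, col_right) {
  structure(list(row_top = as.integer(row_top),
                 row_bottom = as.integer(row_bottom),
                 col_left = as.integer(col_left),
                 col_right = as.integer(col_right),
                 height_px = as.integer(row_bottom - row_top)),
            class = "trough_location")
}

#' @export
print.trough_location <- function(x, ...) {
  cat(sprintf("<trough_location> rows [%d, %d) (height %d px), columns [%d, %d)\n",
              x$row_top, x$row_bottom, x$height_px, x$col_left, x$col_right))
  invisible(x)
}

# Shared tail of both locators: rows flagged as trough-like are marked by a
# white pixel at the horizontal center of the analysed column range, a Hough
# pass extracts near-vertical segments from that point column, and the row
# span of the longest segment is the trough band.
rows_to_band <- function(marked_rows, width, height, col_left, col_right,
                         hough) {
  if (!length(marked_rows))
    stop(trough_not_found("no rows passed the trough criterion"))
  mid_col <- floor((col_left + col_right) / 2)
  pts <- cbind(x = rep(mid_col, length(marked_rows)), y = marked_rows)
  segs <- hough_segments(pts, theta_range = c(-20, 20),
                         theta_res = hough$theta_res, rho_res = hough$rho_res,
                         votes_threshold = hough$votes_threshold,
                         min_length = hough$min_length,
                         max_gap = hough$max_gap)
  best <- longest_segment(segs)
  if (is.null(best))
    stop(trough_not_found("no straight segment found among marked rows"))
  row_top <- min(best$y1, best$y2)
  row_bottom <- max(best$y1, best$y2) + 1L  # half-open
  trough_location(row_top, row_bottom, col_left, col_right)
}

# Hough defaults for the marked-row point column: the band is typically
# 40-120 rows tall, so thresholds are far below the edge-line defaults; the
# small max_gap keeps scattered isolated rows from chaining into a band.
trough_hough_params <- function() {
  hough_params(votes_threshold = 15, min_length = 15, max_gap = 2)
}

#' Locate the trough by the row-variance method
#'
#' The trough plane is nearly equidistant from the camera, so the depth
#' values along each of its rows barely vary. Rows whose per-row depth
#' variance (over the analysed columns, ignoring zero/no-reading pixels)
#' falls below `variance_threshold` are marked; a Hough pass over the marked
#' rows' midpoint pixels extracts the longest contiguous vertical run, whose
#' row span is the trough band.
#'
#' @param depth depth matrix in millimetres (0 = no reading), already
#'   roll-corrected.
#' @param variance_threshold per-row variance cutoff in mm^2 (default 400).
#' @param border_cols number of columns excluded on each side (default 50,
#'   the width of the registration borders).
#' @param hough Hough parameters for the marked-row pass.
#' @return A `trough_location` with 0-based half-open row interval
#'   `[row_top, row_bottom)`. Signals a condition of class
#'   `trough_not_found` when no row qualifies or no segment is found;
#'   callers may `tryCatch` it and skip the frame.
#' @export
locate_trough_variance <- function(depth, variance_threshold = 400,
                                   border_cols = 50,
                                   hough = trough_hough_params()) {
  if (!is.matrix(depth)) stop("`depth` must be a matrix", call. = FALSE)
  W <- ncol(depth); H <- nrow(depth)
  cols <- (border_cols + 1L):(W - border_cols)
  sub <- depth[, cols, drop = FALSE]
  sub[sub == 0] <- NA  # dropout never contributes to the variance
  n <- rowSums(!is.na(sub))
  mu <- rowMeans(sub, na.rm = TRUE)
  ss <- rowSums(sub * sub, na.rm = TRUE)
  v <- ifelse(n > 1, (ss - n * mu^2) / (n - 1), Inf)
  marked <- which(is.finite(v) & v < variance_threshold) - 1L  # 0-based rows
  rows_to_band(marked, W, H, border_cols, W - border_cols, hough)
}

#' Locate the trough by the keypoint-sparsity method
#'
#' Interest-point detectors respond to texture and depth discontinuities but
#' not to flat regions, so the trough is the largest keypoint-free row band.
#' The depth image is rendered to 8-bit (min-max over nonzero readings),
#' keypoints are detected, each keypoint's row and its immediate upper and
#' lower neighbours are marked as occupied, and the midpoints of all
#' *unmarked* rows form the point column handed to the Hough pass.
#'
#' The detector is pluggable: any `function(img8)` returning a data frame
#' with 0-based `x`, `y` columns. The default is the package's
#' determinant-of-Hessian detector, the same response family as SURF's
#' interest-point test, with `hessian_threshold` as response cutoff.
#'
#' @inheritParams locate_trough_variance
#' @param detector keypoint detector `function(img8)`; `NULL` for the
#'   built-in Hessian detector.
#' @param hessian_threshold response threshold for the default detector
#'   (default 400).
#' @return A `trough_location`; signals `trough_not_found` as in
#'   [locate_trough_variance()].
#' @export
locate_trough_features <- function(depth, detector = NULL,
                                   hessian_threshold = 400,
                                   border_cols = 50,
                                   hough = trough_hough_params()) {
  if (!is.matrix(depth)) stop("`depth` must be a matrix", call. = FALSE)
  W <- ncol(depth); H <- nrow(depth)
  if (is.null(detector))
    detector <- function(img8) hessian_keypoints(img8, threshold = hessian_threshold)
  cols <- (border_cols + 1L):(W - border_cols)
  img8 <- depth_to_8bit(depth[, cols, drop = FALSE])
  kp <- detector(img8)
  occupied <- rep(FALSE, H)
  if (nrow(kp)) {
    rows <- unique(c(kp$y, kp$y - 1L, kp$y + 1L))
    rows <- rows[rows >= 0L & rows < H]
    occupied[rows + 1L] <- TRUE
  }
  marked <- which(!occupied) - 1L  # rows free of keypoints
  if (!length(marked))
    stop(trough_not_found("keypoints occupy every row"))
  rows_to_band(marked, W, H, border_cols, W - border_cols, hough)
}

#' Derive the key area beneath the trough
#'
#' The key area is the axis-aligned rectangle directly below the trough
#' where a lying bird's body profile is visible. Its height scales with the
#' trough height (`h = round(k1 * height_px)`, at least 1, clipped to the
#' image bottom), so that the analysis window grows and shrinks with the
#' camera-to-cage distance. Its width spans the frame minus a fixed margin
#' on each side: 590 px for a 640-wide frame with the default 25-px margin.
#'
#' @param trough a `trough_location`.
#' @param image_size `c(width, height)` of the corrected frame.
#' @param k1 height ratio between key area and trough band (default 0.6).
#' @param side_margin pixels excluded on each side (default 25).
#' @return A list of class `key_area` with 0-based `x`, `y`, `w`, `h`.
#' @examples
#' tr <- cagepose:::trough_location(100, 200, 50, 590)
#' compute_key_area(tr, c(640, 480))
#' @export
compute_key_area <- function(trough, image_size, k1 = 0.6, side_margin = 25) {
  if (!inherits(trough, "trough_location"))
    stop("`trough` must be a trough_location", call. = FALSE)
  if (k1 <= 0) stop("`k1` must be positive", call. = FALSE)
  W <- image_size[1]; H <- image_size[2]
  h <- max(1L, as.integer(round(k1 * trough$height_px)))
  y <- trough$row_bottom
  h <- min(h, max(0L, H - y))
  if (h < 1L)
    stop("key area falls entirely outside the image", call. = FALSE)
  structure(list(x = as.integer(side_margin), y = as.integer(y),
                 w = as.integer(W - 2L * side_margin), h = h),
            class = "key_area")
}

#' @export
print.key_area <- function(x, ...) {
  cat(sprintf("<key_area> x=%d y=%d w=%d h=%d\n", x$x, x$y, x$w, x$h))
  invisible(x)
}
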