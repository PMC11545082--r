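# Posture identification: per-column dynamic depth-threshold segmentation of
# the key area, followed by denoising, column-fill filtering, contour
# merging, and aspect-ratio screening of the surviving boxes.

#' Detection parameters
#'
#' The five core tunables plus the auxiliary thresholds of the posture
#' stage. `k1` scales the key-area height from the trough height; `k2`/`k3`
#' (mm) bound the depth offset, relative to the trough, at which a lying
#' bird's body can sit; `k4` sets the column-fill cutoff (a column survives
#' when its white-pixel count exceeds key-area height / `k4`); `k5` is the
#' minimum width/height ratio of an emitted box (lying birds are flat and
#' wide, cage pillars tall and thin).
#'
#' @param k1 key-area height ratio (> 0). Default 0.6.
#' @param k2,k3 depth offsets in millimetres, `0 < k2 < k3`. Defaults 65
#'   and 250.
#' @param k4 column-fill divisor (> 0). Default 2.0.
#' @param k5 aspect-ratio threshold (> 0). Default 1.7.
#' @param merge_gap_px contours closer than this many pixels (shortest
#'   contour-to-contour distance) are fused. Default 20.
#' @param min_contour_area_px minimum surviving contour area in pixels.
#'   Default 50.
#' @param morph_kernel structuring element for opening/closing; default a
#'   3x3 cross (elliptical kernel of size 3).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(k1 = 0.6, k2 = 65, k3 = 250, k4 = 2.0, k5 = 1.7,
                             merge_gap_px = 20, min_contour_area_px = 50,
                             morph_kernel = NULL) {
  if (k1 <= 0) stop("k1 must be positive", call. = FALSE)
  if (!(0 < k2 && k2 < k3)) stop("need 0 < k2 < k3", call. = FALSE)
  if (k4 <= 0) stop("k4 must be positive", call. = FALSE)
  if (k5 <= 0) stop("k5 must be positive", call. = FALSE)
  if (merge_gap_px < 0) stop("merge_gap_px must be >= 0", call. = FALSE)
  if (is.null(morph_kernel))
    morph_kernel <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                 merge_gap_px = merge_gap_px,
                 min_contour_area_px = min_contour_area_px,
                 morph_kernel = morph_kernel),
            class = "detection_params")
}

empty_detections <- function() {
  data.frame(x = integer(0), y = integer(0), w = integer(0), h = integer(0),
             posture = character(0), frame = character(0),
             stringsAsFactors = FALSE)
}

#' Segment the key area by the per-column dynamic depth threshold
#'
#' For each column `c` of the key area, the reference depth `d_c` is read at
#' the trough band's vertical-middle row in that column. A key-area pixel
#' with depth `d` is foreground iff `d_c + k2 < d < d_c + k3` (strict
#' inequalities). Anchoring the threshold to the same column's trough depth
#' compensates for the varying camera-to-cage distance across the image and
#' for any yaw between camera and cage. Zero-depth (no-reading) pixels are
#' background, and columns whose reference depth reads 0 are skipped
#' entirely.
#'
#' @param depth corrected depth matrix (mm).
#' @param trough a `trough_location`.
#' @param key a `key_area`.
#' @param k2,k3 depth offsets in millimetres (`k2 < k3`).
#' @return A logical matrix of dimensions `key$h` x `key$w` (foreground =
#'   `TRUE`).
#' @export
segment_key_area <- function(depth, trough, key, k2 = 65, k3 = 250) {
  if (k2 >= k3) stop("need k2 < k3", call. = FALSE)
  if (key$h < 1 || key$w < 1) stop("key area is empty", call. = FALSE)
  mid_row <- as.integer(round((trough$row_top + trough$row_bottom) / 2))
  mid_row <- min(mid_row, trough$row_bottom - 1L)
  cols <- (key$x + 1L):(key$x + key$w)       # 1-based column indices
  rows <- (key$y + 1L):(key$y + key$h)
  d_ref <- depth[mid_row + 1L, cols]
  sub <- depth[rows, cols, drop = FALSE]
  lo <- matrix(d_ref + k2, nrow = key$h, ncol = key$w, byrow = TRUE)
  hi <- matrix(d_ref + k3, nrow = key$h, ncol = key$w, byrow = TRUE)
  valid_col <- matrix(d_ref > 0, nrow = key$h, ncol = key$w, byrow = TRUE)
  sub > lo & sub < hi & sub > 0 & valid_col
}

#' Morphological denoising of a segmentation mask
#'
#' Opening then closing with a 3x3 cross-shaped structuring element,
#' followed by a scale-3 binary median (majority) filter: isolated noise
#' pixels disappear, large structures keep their shape to within one pixel
#' of boundary erosion.
#'
#' @param mask logical matrix.
#' @param params a [detection_params()].
#' @return A logical matrix.
#' @export
denoise_mask <- function(mask, params = detection_params()) {
  if (!any(mask)) return(mask)
  m <- EBImage::closing(EBImage::opening(mask * 1, params$morph_kernel),
                        params$morph_kernel)
  median3x3_binary(m > 0)
}

#' Erase columns with too few foreground pixels
#'
#' A lying bird fills most of the key-area height in the columns it covers;
#' stray edges, leg strokes and segmentation noise do not. Each column's
#' white-pixel count `N_c` is compared against `H_roi / k4`; columns with
#' `N_c > H_roi / k4` are kept unchanged, all others are set entirely to
#' background (strict inequality).
#'
#' @param mask logical matrix.
#' @param H_roi key-area height in pixels (defaults to `nrow(mask)`).
#' @param k4 column-fill divisor.
#' @return A logical matrix.
#' @export
filter_columns <- function(mask, H_roi = nrow(mask), k4 = 2.0) {
  keep <- colSums(mask) > H_roi / k4
  mask & matrix(keep, nrow(mask), ncol(mask), byrow = TRUE)
}

# Boundary pixels of each labelled component (pixels with at least one
# 4-neighbour outside the component), as a list of 0-based (x, y) matrices.
component_contours <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- labels
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  edge <- ctr > 0 & (pad[1:H, 2:(W + 1)] != ctr |
                     pad[3:(H + 2), 2:(W + 1)] != ctr |
                     pad[2:(H + 1), 1:W] != ctr |
                     pad[2:(H + 1), 3:(W + 2)] != ctr)
  idx <- which(edge, arr.ind = TRUE)
  split.data.frame(cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L),
                   ctr[edge])
}

# Shortest point-to-point distance between two contour point sets, plus the
# closest pair of points.
closest_pair <- function(a, b) {
  d2 <- outer(a[, "x"], b[, "x"], "-")^2 + outer(a[, "y"], b[, "y"], "-")^2
  k <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(d2[k]), from = a[k[1], ], to = b[k[2], ])
}

#' Fuse connected components separated by small gaps
#'
#' Segmentation can split one bird into several blobs. Components whose
#' shortest *contour-to-contour* distance is below `gap` are fused by
#' drawing a one-pixel line between their closest contour points; pairs are
#' processed in ascending distance and components are re-extracted after
#' each fuse, until no pair qualifies. Contour distance, not centroid
#' distance, is used deliberately: two large blobs can be nearly touching
#' while their centroids are far apart.
#'
#' @param mask logical matrix.
#' @param gap distance threshold in pixels (strictly below fuses).
#' @return A logical matrix. Idempotent: a second application changes
#'   nothing.
#' @export
merge_contours <- function(mask, gap = 20) {
  if (gap < 0) stop("`gap` must be >= 0", call. = FALSE)
  m <- mask
  repeat {
    labels <- EBImage::bwlabel(m * 1)
    n <- max(labels)
    if (n < 2) break
    contours <- component_contours(labels)
    ids <- names(contours)
    best <- NULL
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      cp <- closest_pair(contours[[i]], contours[[j]])
      if (cp$dist < gap && (is.null(best) || cp$dist < best$dist)) best <- cp
    }
    if (is.null(best)) break
    n_pts <- max(2L, ceiling(2 * best$dist) + 1L)
    xs <- round(seq(best$from["x"], best$to["x"], length.out = n_pts))
    ys <- round(seq(best$from["y"], best$to["y"], length.out = n_pts))
    # component labelling is 4-connected: pad diagonal steps so the drawn
    # line actually fuses the two components
    dg <- which(diff(xs) != 0 & diff(ys) != 0)
    xs <- c(xs, xs[dg]); ys <- c(ys, ys[dg + 1L])
    m[cbind(ys + 1L, xs + 1L)] <- TRUE
  }
  m
}

#' Extract lying-bird boxes from the final mask
#'
#' Finds connected components, drops those whose area (pixel count) is
#' below `min_area`, takes each survivor's axis-aligned bounding rectangle,
#' and keeps only rectangles with `w / h > k5` (strict): lying birds are
#' flat and wide, whereas cage pillars produce tall thin rectangles.
#'
#' @param mask logical matrix (after [merge_contours()]).
#' @param min_area minimum component area in pixels.
#' @param k5 aspect-ratio threshold.
#' @param offset `c(x, y)` added to box coordinates (the key area's origin
#'   in the corrected frame).
#' @param frame_id identifier stored in the `frame` column.
#' @return A data frame of detections with 0-based half-open boxes
#'   (`x`, `y`, `w`, `h`), `posture = "lying"`, and `frame`.
#' @export
extract_boxes <- function(mask, min_area = 50, k5 = 1.7, offset = c(0, 0),
                          frame_id = "") {
  labels <- EBImage::bwlabel(mask * 1)
  n <- max(labels)
  if (n == 0) return(empty_detections())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- which(labels == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2])  # half-open, 0-based
    y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1])
    w <- x1 - x0; h <- y1 - y0
    if (w / h <= k5) next
    out[[i]] <- data.frame(x = x0 + offset[1], y = y0 + offset[2],
                           w = w, h = h, posture = "lying",
                           frame = frame_id, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_detections())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect lying broilers in a frame
#'
#' Runs the complete pipeline: roll correction from the trough edge lines,
#' trough location in the depth image, key-area derivation, per-column
#' dynamic depth-threshold segmentation, morphological denoising,
#' column-fill filtering, contour merging, and aspect-ratio screening.
#' When no trough is found the frame is skipped with a message and an empty
#' detection set is returned (not an error).
#'
#' @param frame a [merged_frame()].
#' @param params a [detection_params()].
#' @param trough_method `"variance"` (row-variance, the faster method) or
#'   `"features"` (keypoint sparsity).
#' @param config pipeline configuration as returned by
#'   [pipeline_config()]; controls the correction ROI, thresholds and
#'   margins.
#' @param frame_id identifier stored with each detection.
#' @return A data frame of detections (possibly 0 rows) with columns
#'   `x`, `y`, `w`, `h`, `posture`, `frame`, in corrected-image pixel
#'   coordinates. The corrected frame, trough and key area are attached as
#'   attributes `"corrected"`, `"trough"` and `"key_area"` for inspection.
#' @examples
#' sc <- generate_scene(scene_config(seed = 3))
#' detect_lying(sc$frame)
#' @export
detect_lying <- function(frame, params = detection_params(),
                         trough_method = c("variance", "features"),
                         config = pipeline_config(), frame_id = "") {
  trough_method <- match.arg(trough_method)
  corr <- correct_roll(frame, roi = config$correction$roi,
                       binarize_threshold = config$correction$binarize_threshold,
                       hough = config$correction$hough)
  fr <- corr$frame
  trough <- tryCatch(
    if (trough_method == "variance")
      locate_trough_variance(fr$depth,
                             variance_threshold = config$trough$variance_threshold,
                             border_cols = config$trough$border_cols)
    else
      locate_trough_features(fr$depth,
                             hessian_threshold = config$trough$hessian_threshold,
                             border_cols = config$trough$border_cols),
    trough_not_found = function(e) {
      message(sprintf("frame %s skipped: %s",
                      if (nzchar(frame_id)) frame_id else "<unnamed>",
                      conditionMessage(e)))
      NULL
    })
  if (is.null(trough)) {
    out <- empty_detections()
    attr(out, "skipped") <- TRUE
    return(out)
  }
  key <- compute_key_area(trough, c(fr$width, fr$height), k1 = params$k1,
                          side_margin = config$key_area$side_margin)
  mask <- segment_key_area(fr$depth, trough, key, k2 = params$k2,
                           k3 = params$k3)
  mask <- denoise_mask(mask, params)
  mask <- filter_columns(mask, H_roi = key$h, k4 = params$k4)
  mask <- merge_contours(mask, gap = params$merge_gap_px)
  out <- extract_boxes(mask, min_area = params$min_contour_area_px,
                       k5 = params$k5, offset = c(key$x, key$y),
                       frame_id = frame_id)
  attr(out, "corrected") <- fr
  attr(out, "trough") <- trough
  attr(out, "key_area") <- key
  out
}
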