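# Camera-roll correction. The carrying device shakes as it moves along the
# cage row, so frames arrive with a small roll angle; the trough's straight
# horizontal edges are the reference used to measure and undo it.

#' Estimate the camera roll angle from the trough edge lines
#'
#' Measures the inclination of the dominant near-horizontal straight edge in
#' the color image: grayscale conversion, 3x3 Sobel edge extraction in the
#' y direction, scale-3 median filtering, binarization, then two Hough
#' passes. The first pass extracts straight-line segments inside the region
#' of interest and re-draws them on an all-black image; the second pass runs
#' on that image so that fragments of the same physical edge fuse into one
#' long segment, of which the longest is taken. Two passes are needed
#' because a single pass tends to split one edge into several collinear
#' fragments, none of them individually longest.
#'
#' @param frame a [merged_frame()].
#' @param roi region of interest `c(x0, y0, x1, y1)` (0-based, half-open)
#'   restricting the first Hough pass. Default `c(25, 80, 615, 300)`, the
#'   band where the trough sits in 640x480 cage frames.
#' @param binarize_threshold intensity cutoff applied to the filtered edge
#'   image (default 100).
#' @param hough Hough parameters as returned by [hough_params()].
#' @return A list of class `tilt_estimate` with elements `angle_deg`
#'   (positive = scene tilted counterclockwise), `line` (endpoints
#'   `c(x1, y1, x2, y2)` of the longest segment) and `found`. When no
#'   segment is found, `found` is `FALSE` and no rotation should be applied.
#' @examples
#' sc <- generate_scene(scene_config(roll_angle_deg = 1.5, seed = 7))
#' estimate_tilt(sc$frame)$angle_deg
#' @export
estimate_tilt <- function(frame, roi = c(25, 80, 615, 300),
                          binarize_threshold = 100,
                          hough = hough_params()) {
  if (!is_merged_frame(frame))
    stop("`frame` must be a merged_frame", call. = FALSE)
  if (frame$width < 3 || frame$height < 3)
    stop("frame is too small for edge extraction", call. = FALSE)
  not_found <- structure(list(angle_deg = NA_real_, line = NULL, found = FALSE),
                         class = "tilt_estimate")

  edges <- sobel_y(rgb_to_gray(frame$color))
  edges <- median3x3(edges)
  bin <- edges > binarize_threshold

  pts <- mask_points(bin)
  inside <- pts[, 1] >= roi[1] & pts[, 1] < roi[3] &
    pts[, 2] >= roi[2] & pts[, 2] < roi[4]
  pts <- pts[inside, , drop = FALSE]
  # Near-horizontal lines have their normal near theta = 90 deg.
  segs1 <- hough_segments(pts, theta_range = c(45, 135),
                          theta_res = hough$theta_res,
                          rho_res = hough$rho_res,
                          votes_threshold = hough$votes_threshold,
                          min_length = hough$min_length,
                          max_gap = hough$max_gap)
  if (nrow(segs1) == 0L) return(not_found)
  canvas <- draw_segments(segs1, frame$width, frame$height)
  segs2 <- hough_segments(mask_points(canvas), theta_range = c(45, 135),
                          theta_res = hough$theta_res,
                          rho_res = hough$rho_res,
                          votes_threshold = hough$votes_threshold,
                          min_length = hough$min_length,
                          max_gap = hough$max_gap)
  best <- longest_segment(segs2)
  if (is.null(best)) return(not_found)
  angle <- segment_angle(best)
  if (abs(angle) >= 45) return(not_found)  # not a near-horizontal structure
  structure(list(angle_deg = angle,
                 line = c(x1 = best$x1, y1 = best$y1,
                          x2 = best$x2, y2 = best$y2),
                 found = TRUE),
            class = "tilt_estimate")
}

#' @export
print.tilt_estimate <- function(x, ...) {
  if (x$found)
    cat(sprintf("<tilt_estimate> %.3f deg (counterclockwise positive)\n",
                x$angle_deg))
  else cat("<tilt_estimate> no reference line found\n")
  invisible(x)
}

#' Default Hough-transform parameters
#'
#' @param rho_res distance resolution in pixels.
#' @param theta_res angle resolution in degrees.
#' @param votes_threshold accumulator threshold (minimum collinear points).
#' @param min_length minimum segment length in pixels.
#' @param max_gap maximum gap in pixels between collinear points of one
#'   segment.
#' @return A named list of parameters.
#' @export
hough_params <- function(rho_res = 1, theta_res = 1, votes_threshold = 50,
                         min_length = 100, max_gap = 10) {
  list(rho_res = rho_res, theta_res = theta_res,
       votes_threshold = votes_threshold, min_length = min_length,
       max_gap = max_gap)
}

#' Rotation matrix undoing a measured roll angle
#'
#' Builds the 2x3 affine matrix that rotates image content about `center`
#' so as to undo a counterclockwise scene tilt of `angle_deg`: content is
#' rotated clockwise by the same amount. In screen coordinates (y down) the
#' matrix is `[[cos a, -sin a, tx], [sin a, cos a, ty]]` with the
#' translation chosen so that `center` is a fixed point.
#'
#' @param angle_deg measured tilt in degrees (positive = counterclockwise).
#' @param center rotation center `c(x, y)`; default `c(320, 240)`, the
#'   center of a 640x480 frame.
#' @return A 2x3 numeric matrix.
#' @examples
#' round(rotation_matrix(0.978), 3)
#' @export
rotation_matrix <- function(angle_deg, center = c(320, 240)) {
  if (!is.finite(angle_deg)) stop("angle must be finite", call. = FALSE)
  a <- angle_deg * pi / 180
  cs <- cos(a); sn <- sin(a)
  cx <- center[1]; cy <- center[2]
  matrix(c(cs, -sn, (1 - cs) * cx + sn * cy,
           sn,  cs, (1 - cs) * cy - sn * cx),
         nrow = 2, byrow = TRUE)
}

#' Apply an affine correction to both channels of a frame
#'
#' Warps color and depth with the same matrix. Color uses bilinear
#' interpolation; depth uses nearest-neighbour so that no depth values are
#' invented at object boundaries. Out-of-frame regions are filled with 0
#' (the no-reading code for depth).
#'
#' @param frame a [merged_frame()].
#' @param m 2x3 affine matrix mapping input to output pixel coordinates,
#'   e.g. from [rotation_matrix()].
#' @return The corrected [merged_frame()].
#' @export
apply_correction <- function(frame, m) {
  if (!is_merged_frame(frame))
    stop("`frame` must be a merged_frame", call. = FALSE)
  if (!is.matrix(m) || !all(dim(m) == c(2, 3)))
    stop("`m` must be a 2x3 affine matrix", call. = FALSE)
  if (identical(unname(m), matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE)))
    return(frame)
  col_out <- array(0L, dim(frame$color))
  for (ch in 1:3)
    col_out[, , ch] <- round(warp_matrix(frame$color[, , ch], m,
                                         interp = "bilinear"))
  dep_out <- warp_matrix(frame$depth, m, interp = "nearest")
  merged_frame(col_out, dep_out)
}

#' Estimate and undo the camera roll in one step
#'
#' Convenience wrapper: [estimate_tilt()] then, if a reference line was
#' found, [rotation_matrix()] and [apply_correction()]. When no line is
#' found the frame is returned unrotated.
#'
#' @inheritParams estimate_tilt
#' @param center rotation center passed to [rotation_matrix()]; `NULL`
#'   (default) uses the image center.
#' @return A list with elements `frame` (corrected), `tilt`
#'   (the [estimate_tilt()] result).
#' @export
correct_roll <- function(frame, roi = c(25, 80, 615, 300),
                         binarize_threshold = 100, hough = hough_params(),
                         center = NULL) {
  tilt <- estimate_tilt(frame, roi = roi,
                        binarize_threshold = binarize_threshold,
                        hough = hough)
  if (!tilt$found) return(list(frame = frame, tilt = tilt))
  if (is.null(center)) center <- c(frame$width / 2, frame$height / 2)
  m <- rotation_matrix(tilt$angle_deg, center = center)
  list(frame = apply_correction(frame, m), tilt = tilt)
}
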