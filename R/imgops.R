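# Internal raster primitives.
#
# Images are numeric matrices indexed [row, col] = [y + 1, x + 1]; point
# coordinates are 0-based (x = column, y = row, origin top-left) everywhere
# in the public interface. Angles follow the screen convention: a positive
# tilt means the scene appears rotated counterclockwise (right-hand side up).

rgb_to_gray <- function(color) {
  0.299 * color[, , 1] + 0.587 * color[, , 2] + 0.114 * color[, , 3]
}

# Reflect-pad a matrix by one pixel on every side (mirror without repeating
# the edge row/column; degenerates to replication for 1-wide inputs).
pad_reflect1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(if (H > 1) 2L else 1L, seq_len(H), if (H > 1) H - 1L else H)
  ci <- c(if (W > 1) 2L else 1L, seq_len(W), if (W > 1) W - 1L else W)
  m[ri, ci, drop = FALSE]
}

# The eight neighbours + centre of every pixel as a list of matrices.
neighborhood9 <- function(m) {
  p <- pad_reflect1(m)
  H <- nrow(m); W <- ncol(m)
  out <- vector("list", 9L)
  k <- 1L
  for (dy in 0:2) for (dx in 0:2) {
    out[[k]] <- p[dy + seq_len(H), dx + seq_len(W), drop = FALSE]
    k <- k + 1L
  }
  out
}

# |gradient| of a 3x3 Sobel operator in the y direction, clamped to 0..255.
sobel_y <- function(gray) {
  n <- neighborhood9(gray)
  g <- (n[[7]] + 2 * n[[8]] + n[[9]]) - (n[[1]] + 2 * n[[2]] + n[[3]])
  pmin(abs(g), 255)
}

# Vectorised 3x3 median (Paeth's 19-exchange sorting network on the nine
# shifted copies); reflective border handling.
median3x3 <- function(m) {
  p <- neighborhood9(m)
  s2 <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); p[[j]] <<- pmax(p[[i]], p[[j]]); p[[i]] <<- lo
  }
  s2(2, 3); s2(5, 6); s2(8, 9); s2(1, 2); s2(4, 5); s2(7, 8)
  s2(2, 3); s2(5, 6); s2(8, 9); s2(1, 4); s2(6, 9); s2(5, 8)
  s2(4, 7); s2(2, 5); s2(3, 6); s2(5, 8); s2(5, 3); s2(7, 5); s2(5, 3)
  p[[5]]
}

# Majority vote over the 3x3 neighbourhood of a binary mask — the binary
# specialisation of a scale-3 median filter.
median3x3_binary <- function(mask) {
  n <- neighborhood9(mask * 1)
  Reduce(`+`, n) >= 5
}

# ---- Hough transform --------------------------------------------------------
#
# Lines are parameterised x cos(theta) + y sin(theta) = rho, theta in degrees
# (0 = vertical line, 90 = horizontal line). Segments are extracted
# deterministically: for every accumulator cell reaching `votes_threshold`
# (visited in decreasing-vote, then scan order), the contributing points are
# projected onto the line, split into runs at gaps wider than `max_gap`, and
# runs at least `min_length` long become segments.

hough_segments <- function(points, theta_range = c(0, 180),
                           theta_res = 1, rho_res = 1,
                           votes_threshold = 50, min_length = 100,
                           max_gap = 10, max_cells = 200L, rho_tol = 1) {
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0),
                      length = numeric(0), theta = numeric(0))
  if (is.null(points) || nrow(points) == 0L) return(empty)
  x <- points[, 1]; y <- points[, 2]
  thetas <- seq(theta_range[1], theta_range[2], by = theta_res)
  cand <- vector("list", length(thetas))
  for (i in seq_along(thetas)) {
    th <- thetas[i] * pi / 180
    rho <- x * cos(th) + y * sin(th)
    bin <- as.integer(round(rho / rho_res))
    tb <- table(bin)
    hits <- tb[tb >= votes_threshold]
    if (length(hits))
      cand[[i]] <- data.frame(ti = i, bin = as.integer(names(hits)),
                              votes = as.integer(hits))
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$votes, cand$ti, cand$bin), , drop = FALSE]
  if (nrow(cand) > max_cells) cand <- cand[seq_len(max_cells), , drop = FALSE]

  segs <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    th <- thetas[cand$ti[k]] * pi / 180
    rho <- x * cos(th) + y * sin(th)
    on_line <- abs(rho - cand$bin[k] * rho_res) <= rho_tol
    if (!any(on_line)) next
    t <- -x[on_line] * sin(th) + y[on_line] * cos(th)
    ord <- order(t, x[on_line], y[on_line])
    xs <- x[on_line][ord]; ys <- y[on_line][ord]; ts <- t[ord]
    run_id <- cumsum(c(0, diff(ts) > max_gap))
    found <- lapply(split(seq_along(ts), run_id), function(idx) {
      i1 <- idx[1]; i2 <- idx[length(idx)]
      len <- sqrt((xs[i2] - xs[i1])^2 + (ys[i2] - ys[i1])^2)
      if (len < min_length) return(NULL)
      data.frame(x1 = xs[i1], y1 = ys[i1], x2 = xs[i2], y2 = ys[i2],
                 length = len, theta = thetas[cand$ti[k]])
    })
    found <- found[!vapply(found, is.null, logical(1))]
    if (length(found)) segs[[k]] <- do.call(rbind, found)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

mask_points <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

# Longest segment; ties broken by generation order (first encountered).
longest_segment <- function(segs) {
  if (is.null(segs) || nrow(segs) == 0L) return(NULL)
  segs[which.max(segs$length), , drop = FALSE]
}

# Rasterise segments onto an all-black H x W mask (dense sampling, rounded).
draw_segments <- function(segs, width, height) {
  m <- matrix(FALSE, height, width)
  for (k in seq_len(nrow(segs))) {
    n <- max(2L, ceiling(2 * segs$length[k]))
    xs <- round(seq(segs$x1[k], segs$x2[k], length.out = n))
    ys <- round(seq(segs$y1[k], segs$y2[k], length.out = n))
    keep <- xs >= 0 & xs < width & ys >= 0 & ys < height
    m[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
  }
  m
}

# Inclination of a segment in degrees; positive = counterclockwise on screen
# (right endpoint higher). Result in (-90, 90].
segment_angle <- function(seg) {
  dx <- seg$x2 - seg$x1; dy <- seg$y2 - seg$y1
  if (dx < 0) { dx <- -dx; dy <- -dy }
  a <- atan2(-dy, dx) * 180 / pi
  if (a <= -90) a <- a + 180
  a
}

# ---- affine warping ---------------------------------------------------------

# Invert a 2x3 affine matrix (input -> output coordinate map).
affine_invert <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; tx <- m[1, 3]
  c_ <- m[2, 1]; d <- m[2, 2]; ty <- m[2, 3]
  det <- a * d - b * c_
  if (abs(det) < 1e-12) stop("affine matrix is singular", call. = FALSE)
  ia <- d / det; ib <- -b / det; ic <- -c_ / det; id <- a / det
  matrix(c(ia, ib, -(ia * tx + ib * ty),
           ic, id, -(ic * tx + id * ty)), 2, 3, byrow = TRUE)
}

# Warp a single-channel image by a 2x3 affine matrix mapping input pixel
# coordinates (0-based x, y) to output coordinates. Out-of-frame -> fill.
warp_matrix <- function(img, m, interp = c("nearest", "bilinear"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  inv <- affine_invert(m)
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  sx <- inv[1, 1] * X + inv[1, 2] * Y + inv[1, 3]
  sy <- inv[2, 1] * X + inv[2, 2] * Y + inv[2, 3]
  out <- matrix(fill, H, W)
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix < W & iy >= 0 & iy < H
    out[ok] <- img[cbind(iy[ok] + 1L, ix[ok] + 1L)]
  } else {
    ok <- sx >= 0 & sx <= W - 1 & sy >= 0 & sy <= H - 1
    x0 <- pmin(floor(sx), W - 2); y0 <- pmin(floor(sy), H - 2)
    fx <- sx - x0; fy <- sy - y0
    ry <- y0[ok] + 1L; cx <- x0[ok] + 1L
    v00 <- img[cbind(ry, cx)]
    v01 <- img[cbind(ry, cx + 1L)]
    v10 <- img[cbind(ry + 1L, cx)]
    v11 <- img[cbind(ry + 1L, cx + 1L)]
    wx <- fx[ok]; wy <- fy[ok]
    out[ok] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
  }
  out
}

# ---- Hessian interest-point detector ----------------------------------------
#
# Determinant-of-Hessian blob detector on an 8-bit image: Gaussian smoothing
# at scale `sigma`, central-difference second derivatives, response
# sigma^4 * det(H) (scale-normalised), thresholded and non-maximum suppressed
# over 3x3 neighbourhoods. Serves as the default pluggable interest-point
# detector for the keypoint-sparsity trough locator; flat regions produce no
# responses, which is the localisation signal.

hessian_keypoints <- function(img8, threshold = 400, sigma = 2,
                              response_scale = 4) {
  g <- EBImage::gblur(img8, sigma = sigma)
  H <- nrow(g); W <- ncol(g)
  p <- pad_reflect1(g)
  ctr <- p[1 + seq_len(H), 1 + seq_len(W)]
  up <- p[0 + seq_len(H), 1 + seq_len(W)]
  dn <- p[2 + seq_len(H), 1 + seq_len(W)]
  lf <- p[1 + seq_len(H), 0 + seq_len(W)]
  rt <- p[1 + seq_len(H), 2 + seq_len(W)]
  ul <- p[0 + seq_len(H), 0 + seq_len(W)]
  ur <- p[0 + seq_len(H), 2 + seq_len(W)]
  dl <- p[2 + seq_len(H), 0 + seq_len(W)]
  dr <- p[2 + seq_len(H), 2 + seq_len(W)]
  lxx <- lf - 2 * ctr + rt
  lyy <- up - 2 * ctr + dn
  lxy <- (dr + ul - ur - dl) / 4
  # response_scale aligns the response magnitude with the conventional
  # default threshold of 400 for Hessian-type detectors on 8-bit images
  resp <- response_scale * sigma^4 * (lxx * lyy - lxy^2)
  n <- neighborhood9(resp)
  is_max <- Reduce(`&`, lapply(n[-5], function(q) resp >= q))
  idx <- which(resp > threshold & is_max, arr.ind = TRUE)
  data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L,
             response = resp[idx])
}

# Render a depth map to 8-bit by min-max normalisation over nonzero
# (valid) readings; dropout pixels map to 0.
depth_to_8bit <- function(depth) {
  nz <- depth > 0
  out <- matrix(0, nrow(depth), ncol(depth))
  if (!any(nz)) return(out)
  lo <- min(depth[nz]); hi <- max(depth[nz])
  if (hi > lo) out[nz] <- round(255 * (depth[nz] - lo) / (hi - lo))
  else out[nz] <- 128
  out
}
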