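#' Construct a merged RGB-D frame
#'
#' A `merged_frame` bundles a registered 8-bit color image and a 16-bit
#' depth map sharing the same pixel grid, as produced by a structured-light
#' depth camera. Depth is stored in millimetres; the value 0 encodes "no
#' reading" (sensor dropout) and is excluded from all downstream statistics.
#'
#' @param color integer array `H x W x 3`, values in 0..255.
#' @param depth integer matrix `H x W`, values in 0..65535 (millimetres;
#'   0 = no reading).
#' @return An object of class `merged_frame` with elements `color`, `depth`,
#'   `width`, `height`.
#' @examples
#' fr <- merged_frame(array(0L, c(4, 6, 3)), matrix(500L, 4, 6))
#' fr$width
#' @export
merged_frame <- function(color, depth) {
  if (length(dim(color)) != 3L || dim(color)[3] != 3L)
    stop("`color` must be an H x W x 3 array", call. = FALSE)
  if (!is.matrix(depth))
    stop("`depth` must be an H x W matrix", call. = FALSE)
  if (!identical(dim(color)[1:2], dim(depth)))
    stop(sprintf("color (%d x %d) and depth (%d x %d) dimensions differ",
                 dim(color)[1], dim(color)[2], nrow(depth), ncol(depth)),
         call. = FALSE)
  color <- round(color)
  depth <- round(depth)
  if (any(color < 0 | color > 255))
    stop("color values must lie in 0..255", call. = FALSE)
  if (any(depth < 0 | depth > 65535))
    stop("depth values must lie in 0..65535", call. = FALSE)
  storage.mode(color) <- "integer"
  storage.mode(depth) <- "integer"
  structure(
    list(color = color, depth = depth,
         width = ncol(depth), height = nrow(depth)),
    class = "merged_frame")
}

#' @export
print.merged_frame <- function(x, ...) {
  nz <- x$depth[x$depth > 0L]
  cat(sprintf("<merged_frame> %d x %d px; depth %s mm (%.1f%% dropout)\n",
              x$width, x$height,
              if (length(nz)) sprintf("%d-%d", min(nz), max(nz)) else "none",
              100 * mean(x$depth == 0L)))
  invisible(x)
}

is_merged_frame <- function(x) inherits(x, "merged_frame")

# ---- minimal PNG encoder (16-bit RGBA) --------------------------------------
#
# png::writePNG only emits 8-bit files, so the merged format is written by a
# small encoder: IHDR (bit depth 16, color type 6 = RGBA), one zlib-compressed
# IDAT (filter type 0 on every scanline), IEND. memCompress() provides the
# zlib stream; chunk CRCs come from the package's C crc32 routine.

png_u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(png_u32be(length(data)), td, png_u32be(.Call(C_crc32, td)))
}

# 16-bit single-channel (grayscale) PNG, e.g. a bare depth map.
write_png_gray16 <- function(values, path) {
  H <- nrow(values); W <- ncol(values)
  v <- t(values)
  inter <- rbind(as.integer(v) %/% 256L, as.integer(v) %% 256L)
  scanlines <- rbind(0L, matrix(inter, 2L * W, H))
  idat <- memCompress(as.raw(as.vector(scanlines)), "gzip")
  ihdr <- c(png_u32be(W), png_u32be(H), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Write a merged frame as a 16-bit 4-channel PNG
#'
#' Stores color and depth losslessly in a single PNG: channels 1-3 hold the
#' color planes scaled from 8 to 16 bit by multiplication with 257 (so 0 maps
#' to 0 and 255 to 65535, invertible by division with rounding), channel 4
#' (alpha) holds the 16-bit depth verbatim. Channel order is R, G, B, depth.
#'
#' @param frame a [merged_frame()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_merged()] for the inverse.
#' @export
write_merged <- function(frame, path) {
  if (!is_merged_frame(frame))
    stop("`frame` must be a merged_frame", call. = FALSE)
  H <- frame$height; W <- frame$width
  vals <- array(0L, c(4L, W, H))
  for (ch in 1:3) vals[ch, , ] <- t(frame$color[, , ch]) * 257L
  vals[4L, , ] <- t(frame$depth)
  inter <- array(0L, c(8L, W, H))
  inter[c(1L, 3L, 5L, 7L), , ] <- vals %/% 256L
  inter[c(2L, 4L, 6L, 8L), , ] <- vals %% 256L
  scanlines <- rbind(0L, matrix(inter, 8L * W, H))  # leading filter byte 0
  idat <- memCompress(as.raw(as.vector(scanlines)), "gzip")
  ihdr <- c(png_u32be(W), png_u32be(H), as.raw(c(16L, 6L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf("cannot open '%s' for writing", path),
                                           call. = FALSE))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Read a merged 16-bit 4-channel PNG
#'
#' Inverse of [write_merged()]: color is recovered by dividing channels 1-3
#' by 257 with rounding, depth is channel 4 unchanged. The round-trip
#' `read_merged(write_merged(frame))` is bit-identical for valid frames.
#'
#' @param path path to a 16-bit 4-channel PNG file.
#' @return A [merged_frame()].
#' @export
read_merged <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 16L)
    stop(sprintf("'%s': expected bit depth 16, found %d", path, info$bit.depth),
         call. = FALSE)
  if (length(dim(img)) != 3L || dim(img)[3] != 4L)
    stop(sprintf("'%s': expected 4 channels, found %s", path,
                 if (length(dim(img)) == 3L) dim(img)[3] else 1L),
         call. = FALSE)
  v <- round(img * 65535)
  merged_frame(color = round(v[, , 1:3, drop = FALSE] / 257),
               depth = v[, , 4])
}

#' Combine separate color and depth PNG files into a merged frame
#'
#' @param color_path path to an 8-bit 3-channel PNG.
#' @param depth_path path to a 16-bit single-channel PNG.
#' @return A [merged_frame()].
#' @export
load_pair <- function(color_path, depth_path) {
  col <- png::readPNG(color_path, info = TRUE)
  dep <- png::readPNG(depth_path, info = TRUE)
  cinfo <- attr(col, "info"); dinfo <- attr(dep, "info")
  if (length(dim(col)) != 3L || dim(col)[3] < 3L)
    stop(sprintf("'%s': color image must have 3 channels", color_path),
         call. = FALSE)
  if (!is.null(cinfo$bit.depth) && cinfo$bit.depth != 8L)
    stop(sprintf("'%s': color image must be 8-bit, found %d-bit",
                 color_path, cinfo$bit.depth), call. = FALSE)
  if (!is.null(dinfo$bit.depth) && dinfo$bit.depth != 16L)
    stop(sprintf("'%s': depth image must be 16-bit, found %d-bit",
                 depth_path, dinfo$bit.depth), call. = FALSE)
  if (length(dim(dep)) == 3L) {
    if (dim(dep)[3] != 1L)
      stop(sprintf("'%s': depth image must be single-channel", depth_path),
           call. = FALSE)
    dep <- dep[, , 1]
  }
  attributes(dep)[setdiff(names(attributes(dep)), "dim")] <- NULL
  if (!identical(dim(col)[1:2], dim(dep)))
    stop(sprintf("dimension mismatch: color %d x %d vs depth %d x %d",
                 dim(col)[1], dim(col)[2], nrow(dep), ncol(dep)),
         call. = FALSE)
  merged_frame(color = round(col[, , 1:3, drop = FALSE] * 255),
               depth = round(dep * 65535))
}
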