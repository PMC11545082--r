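# Synthetic cage scenes with ground truth. The generator emulates the
# structure the pipeline relies on — a flat trough band with sharp
# horizontal depth edges, a key area beneath it containing flat-lying bird
# blobs at depth offsets between the segmentation bounds, thin vertical
# pillar distractors, short leg strokes for standing birds, injected camera
# roll, depth speckle and dropout, dim low-lux color, and the black
# registration borders of a structured-light sensor. It makes no attempt at
# photorealism: no feathers, no cage wire, no real sensor noise model.

run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of a synthetic cage scene
#'
#' Defaults reflect a typical frame from the cage-row rig: a 640x480 sensor,
#' trough plane about 600 mm from the camera with the cage background about
#' 400 mm behind it, two birds per cage, and mild structured-light noise
#' (5 mm speckle, 2% dropout).
#'
#' @param width,height frame size in pixels.
#' @param trough_rows 0-based half-open row interval of the trough band.
#' @param trough_depth_mm,background_depth_mm plane depths in millimetres;
#'   the trough must be nearer than the background.
#' @param n_lying,n_standing,n_pillars object counts.
#' @param lying_offset_range_mm depth offset of a lying bird's body relative
#'   to the trough, drawn uniformly per bird. The default (80, 220) mm lies
#'   strictly inside the default segmentation band (k2, k3) = (65, 250).
#' @param roll_angle_deg camera roll injected into the scene (positive =
#'   counterclockwise).
#' @param depth_noise_sd_mm additive Gaussian speckle on valid depth.
#' @param dropout_fraction fraction of non-border pixels set to 0
#'   (no reading).
#' @param border_cols width of the black registration border on each side.
#' @param blob_scale size multiplier for bird blobs (1 = large white
#'   broiler; ~0.8 emulates the smaller jute broiler).
#' @param standing_body_in_key if `TRUE`, standing birds' lower bodies
#'   protrude into the key area — the small-bird failure mode in which
#'   standing birds are misdetected as lying.
#' @param seed RNG seed making the scene fully deterministic.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 640, height = 480,
                         trough_rows = c(170, 260),
                         trough_depth_mm = 600, background_depth_mm = 1000,
                         n_lying = 2, n_standing = 1, n_pillars = 1,
                         lying_offset_range_mm = c(80, 220),
                         roll_angle_deg = 0, depth_noise_sd_mm = 5,
                         dropout_fraction = 0.02, border_cols = 50,
                         blob_scale = 1, standing_body_in_key = FALSE,
                         seed = 1) {
  if (trough_depth_mm >= background_depth_mm)
    stop("trough must be nearer than the background", call. = FALSE)
  if (lying_offset_range_mm[1] <= 0 ||
      lying_offset_range_mm[2] >= background_depth_mm - trough_depth_mm)
    stop("lying offsets must lie inside (0, background - trough)",
         call. = FALSE)
  if (trough_rows[1] >= trough_rows[2] || trough_rows[2] >= height)
    stop("invalid trough row interval", call. = FALSE)
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must be in [0, 1)", call. = FALSE)
  structure(list(width = width, height = height, trough_rows = trough_rows,
                 trough_depth_mm = trough_depth_mm,
                 background_depth_mm = background_depth_mm,
                 n_lying = n_lying, n_standing = n_standing,
                 n_pillars = n_pillars,
                 lying_offset_range_mm = lying_offset_range_mm,
                 roll_angle_deg = roll_angle_deg,
                 depth_noise_sd_mm = depth_noise_sd_mm,
                 dropout_fraction = dropout_fraction,
                 border_cols = border_cols, blob_scale = blob_scale,
                 standing_body_in_key = standing_body_in_key, seed = seed),
            class = "scene_config")
}

# Sample non-overlapping horizontal slots (centers) for scene objects so
# that object extents stay more than the contour-merge gap apart.
place_slots <- function(half_widths, x_min, x_max, min_sep = 25,
                        max_tries = 500) {
  centers <- numeric(0)
  placed_hw <- numeric(0)
  for (hw in half_widths) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      c0 <- runif(1, x_min + hw, x_max - hw)
      if (!length(centers) ||
          all(abs(c0 - centers) >= hw + placed_hw + min_sep)) {
        centers <- c(centers, c0); placed_hw <- c(placed_hw, hw)
        ok <- TRUE; break
      }
    }
    if (!ok) stop("cannot place scene objects without overlap; reduce counts",
                  call. = FALSE)
  }
  centers
}

#' Generate a synthetic cage scene with ground truth
#'
#' Renders the depth map (background plane with smooth structure and
#' scattered bumps, flat trough band, lying-bird ellipses, standing-bird leg
#' strokes, pillars), derives a dim shaded color image from it (the cage
#' interior is below 10 lux, so color alone must not suffice for detection),
#' injects the configured camera roll, adds depth speckle and dropout, and
#' blacks out the registration borders. Deterministic given the seed.
#'
#' @param config a [scene_config()].
#' @param frame_id identifier stored in the annotation.
#' @return A list with elements `frame` (a [merged_frame()]), `annotation`
#'   (list with `frame` and `boxes`, a data frame of 0-based boxes with
#'   labels `lying`/`standing`/`pillar`, in deskewed scene coordinates),
#'   and `truth` (trough rows, nominal key area, injected roll, per-bird
#'   depth offsets).
#' @export
generate_scene <- function(config = scene_config(), frame_id = "scene") {
  stopifnot(inherits(config, "scene_config"))
  run_seeded(config$seed, {
    W <- config$width; H <- config$height
    bc <- config$border_cols
    tr <- config$trough_rows
    x_idx <- matrix(rep(0:(W - 1), each = H), H, W)

    # background plane with smooth horizontal structure (keeps per-row
    # variance well above the trough criterion) ...
    ph <- runif(2, 0, 2 * pi)
    depth <- config$background_depth_mm +
      60 * sin(2 * pi * x_idx / 73 + ph[1]) +
      40 * sin(2 * pi * x_idx / 31 + ph[2])
    # ... plus scattered bumps on a jittered row grid outside the trough
    # band, giving the interest-point detector something to respond to on
    # every non-trough row band
    bump_rows <- seq(4, H - 5, by = 6)
    bump_rows <- bump_rows[bump_rows < tr[1] - 2 | bump_rows >= tr[2] + 2]
    for (by in bump_rows) {
      bx <- runif(1, bc + 6, W - bc - 6)
      amp <- sample(c(-1, 1), 1) * runif(1, 70, 110)
      r <- runif(1, 2.5, 5)
      ys <- max(0, floor(by - 3 * r)):min(H - 1, ceiling(by + 3 * r))
      xs <- max(0, floor(bx - 3 * r)):min(W - 1, ceiling(bx + 3 * r))
      g <- exp(-outer((ys - by)^2, (xs - bx)^2, "+") / (2 * r^2))
      depth[ys + 1, xs + 1] <- depth[ys + 1, xs + 1] + amp * g
    }

    # flat trough band (sharp depth step at both edges)
    depth[(tr[1] + 1):tr[2], ] <- config$trough_depth_mm

    # nominal key area (the deskewed geometry the detector should recover)
    trough_h <- tr[2] - tr[1]
    key_y <- tr[2]
    key_h <- max(1L, round(0.6 * trough_h))

    boxes <- list()
    offsets <- numeric(0)

    # horizontal slots for all objects
    s <- config$blob_scale
    ry_lying <- runif(config$n_lying, 0.33, 0.42) * key_h * min(s, 1)
    rx_lying <- 2.2 * ry_lying * max(s / min(s, 1), 1)
    hw <- c(rx_lying,
            rep(18 * s, config$n_standing),   # leg pair half-extent
            rep(8, config$n_pillars))
    centers <- place_slots(hw, x_min = bc + 12, x_max = W - bc - 12)

    # lying birds: flat ellipses at trough depth + offset
    for (i in seq_len(config$n_lying)) {
      off <- runif(1, config$lying_offset_range_mm[1],
                   config$lying_offset_range_mm[2])
      offsets <- c(offsets, off)
      cx <- centers[i]
      cy <- key_y + key_h / 2 + runif(1, -2, 2)
      ys <- max(0, floor(cy - ry_lying[i])):min(H - 1, ceiling(cy + ry_lying[i]))
      xs <- max(0, floor(cx - rx_lying[i])):min(W - 1, ceiling(cx + rx_lying[i]))
      # flattened ellipse (superellipse, exponent 4): a lying bird's body
      # profile keeps near-constant height along most of its width
      inside <- outer(((ys - cy) / ry_lying[i])^4,
                      ((xs - cx) / rx_lying[i])^4, "+") <= 1
      sel <- which(inside, arr.ind = TRUE)
      depth[cbind(ys[sel[, 1]] + 1, xs[sel[, 2]] + 1)] <-
        config$trough_depth_mm + off
      boxes[[length(boxes) + 1]] <- data.frame(
        x = min(xs[sel[, 2]]), y = min(ys[sel[, 1]]),
        w = diff(range(xs[sel[, 2]])) + 1L,
        h = diff(range(ys[sel[, 1]])) + 1L, label = "lying")
    }

    # standing birds: two short thin leg strokes below the trough; with
    # standing_body_in_key, additionally a shallow body segment protruding
    # into the top of the key area (the small-bird failure mode)
    for (i in seq_len(config$n_standing)) {
      cx <- centers[config$n_lying + i]
      off <- runif(1, config$lying_offset_range_mm[1],
                   config$lying_offset_range_mm[2])
      leg_w <- round(runif(2, 3, 5))
      leg_len <- round(runif(2, 0.30, 0.42) * key_h)
      leg_dx <- 9 * s
      lx <- round(c(cx - leg_dx, cx + leg_dx))
      for (l in 1:2) {
        ys <- key_y:min(H - 1, key_y + leg_len[l])
        xs <- max(0, lx[l] - leg_w[l] %/% 2):min(W - 1, lx[l] + leg_w[l] %/% 2)
        depth[ys + 1, xs + 1] <- config$trough_depth_mm + off
      }
      bx0 <- lx[1] - leg_w[1] %/% 2; bx1 <- lx[2] + leg_w[2] %/% 2
      by1 <- key_y + max(leg_len)
      if (config$standing_body_in_key) {
        ry <- 0.58 * key_h; rx <- 30 * s
        ys <- key_y:min(H - 1, key_y + floor(0.55 * key_h))
        xs <- max(0, floor(cx - rx)):min(W - 1, ceiling(cx + rx))
        inside <- outer(((ys - key_y) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
        sel <- which(inside, arr.ind = TRUE)
        depth[cbind(ys[sel[, 1]] + 1, xs[sel[, 2]] + 1)] <-
          config$trough_depth_mm + off
        bx0 <- min(bx0, min(xs[sel[, 2]])); bx1 <- max(bx1, max(xs[sel[, 2]]))
      }
      boxes[[length(boxes) + 1]] <- data.frame(
        x = bx0, y = key_y, w = bx1 - bx0 + 1L, h = by1 - key_y + 1L,
        label = "standing")
    }

    # pillars: thin full-height rectangles at lying-compatible depth,
    # occluded by the trough band itself
    for (i in seq_len(config$n_pillars)) {
      cx <- round(centers[config$n_lying + config$n_standing + i])
      pw <- round(runif(1, 12, 16))
      xs <- max(0, cx - pw %/% 2):min(W - 1, cx + pw %/% 2)
      p_off <- runif(1, config$lying_offset_range_mm[1],
                     config$lying_offset_range_mm[2])
      rows_all <- setdiff(0:(H - 1), tr[1]:(tr[2] - 1))
      depth[rows_all + 1, xs + 1] <- config$trough_depth_mm + p_off
      boxes[[length(boxes) + 1]] <- data.frame(
        x = min(xs), y = key_y, w = length(xs), h = key_h, label = "pillar")
    }

    # dim shaded color: the light-colored trough surface is the one bright
    # structure; everything else (birds, pillars, cage background) sits in a
    # narrow dark band, so that after Sobel filtering only the trough's
    # horizontal edges survive binarization — color alone cannot segment
    # the birds, as in the sub-10-lux cage interior
    gray <- 15 + 15 * pmax(pmin((1300 - depth) / 1000, 1), 0)
    gray[depth > 0 & depth <= config$trough_depth_mm + 40] <- 90
    color <- array(0, c(H, W, 3))
    for (ch in 1:3) color[, , ch] <- gray

    # camera roll: rotate scene content counterclockwise by roll_angle_deg
    if (config$roll_angle_deg != 0) {
      m <- rotation_matrix(-config$roll_angle_deg, center = c(W / 2, H / 2))
      depth <- warp_matrix(depth, m, interp = "nearest")
      for (ch in 1:3)
        color[, , ch] <- warp_matrix(color[, , ch], m, interp = "bilinear")
    }

    # optical blur: a real lens spreads a step edge over 2-3 pixels; without
    # it the rendered trough edge is unphysically sharp and aliases against
    # the scale-3 median filter of the correction stage
    for (ch in 1:3) color[, , ch] <- EBImage::gblur(color[, , ch], sigma = 1)

    # sensor noise: depth speckle, slight color noise, dropout, borders
    nz <- depth > 0
    if (config$depth_noise_sd_mm > 0)
      depth[nz] <- pmax(1, depth[nz] +
                          rnorm(sum(nz), 0, config$depth_noise_sd_mm))
    color <- color + rnorm(length(color), 0, 1.5)
    color <- pmax(pmin(color, 255), 0)
    if (config$dropout_fraction > 0) {
      inner <- which(matrix(TRUE, H, W) &
                       x_idx >= bc & x_idx < W - bc)
      k <- floor(config$dropout_fraction * length(inner))
      depth[sample(inner, k)] <- 0
    }
    depth[, c(seq_len(bc), (W - bc + 1):W)] <- 0
    color[, c(seq_len(bc), (W - bc + 1):W), ] <- 0

    ann_boxes <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(x = integer(0), y = integer(0), w = integer(0),
                 h = integer(0), label = character(0))
    rownames(ann_boxes) <- NULL
    list(frame = merged_frame(round(color), round(depth)),
         annotation = list(frame = frame_id, boxes = ann_boxes),
         truth = list(trough_rows = tr,
                      key_area = c(x = 25, y = key_y, w = W - 50, h = key_h),
                      roll_angle_deg = config$roll_angle_deg,
                      lying_offsets_mm = offsets))
  })
}

#' Generate a dataset of synthetic frames on disk
#'
#' Writes one merged 16-bit 4-channel PNG per frame plus a JSON manifest
#' with the annotations. Per-frame seeds are derived from the master seed,
#' so regeneration with the same configuration is bit-identical.
#'
#' @param n_frames number of frames (>= 1).
#' @param config a [scene_config()]; its `seed` is the master seed.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly: a list with `frames` (list of
#'   `list(file, boxes)`), `config`, and `seed`.
#' @export
generate_dataset <- function(n_frames, config = scene_config(), out_dir) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  frame_seeds <- run_seeded(config$seed,
                            sample.int(.Machine$integer.max, n_frames))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    cfg <- config
    cfg$seed <- frame_seeds[i]
    id <- sprintf("frame_%04d", i)
    sc <- generate_scene(cfg, frame_id = id)
    file <- paste0(id, ".png")
    write_merged(sc$frame, file.path(out_dir, file))
    frames[[i]] <- list(file = file, boxes = sc$annotation$boxes)
  }
  manifest <- list(frames = frames, config = unclass(config),
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return The manifest list; each frame's `boxes` is a data frame and the
#'   directory is recorded in `$dir`.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop(sprintf("no manifest.json under '%s'", dir), call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  man$frames <- lapply(seq_len(nrow(man$frames)), function(i) {
    bx <- man$frames$boxes[[i]]
    if (is.null(bx) || !length(bx))
      bx <- data.frame(x = integer(0), y = integer(0), w = integer(0),
                       h = integer(0), label = character(0))
    list(file = man$frames$file[i], boxes = bx)
  })
  man$dir <- dir
  man
}
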