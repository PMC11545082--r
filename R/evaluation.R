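# Detection scoring against ground-truth annotations, parameter grid
# search, and the daily lying-time status rule.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(x, y, w, h)` (or data-frame rows with those columns),
#' 0-based half-open. Disjoint or zero-area boxes give 0.
#'
#' @param boxA,boxB boxes.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 1/3
#' @export
iou <- function(boxA, boxB) {
  a <- as.numeric(boxA[c("x", "y", "w", "h")])
  b <- as.numeric(boxB[c("x", "y", "w", "h")])
  if (anyNA(a)) a <- as.numeric(boxA)[1:4]
  if (anyNA(b)) b <- as.numeric(boxB)[1:4]
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU matrix between two box data frames.
iou_matrix <- function(A, B) {
  m <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    m[i, j] <- iou(A[i, ], B[j, ])
  m
}

#' Match detections to annotations and count confusion outcomes
#'
#' Within each frame, detections are matched one-to-one to lying
#' annotations greedily by descending IoU. A match at IoU >= `iou_thr` is a
#' true positive; unmatched detections are false positives; unmatched lying
#' annotations are false negatives. A frame containing neither a lying
#' annotation nor a detection contributes one true negative — the
#' frame-level negative that makes the accuracy ratio well defined for a
#' detection task.
#'
#' @param detections data frame with columns `frame`, `x`, `y`, `w`, `h`.
#' @param annotations data frame with columns `frame`, `x`, `y`, `w`, `h`,
#'   `label`; only `label == "lying"` boxes are positives.
#' @param iou_thr IoU threshold in `[0, 1]`.
#' @param frames character vector enumerating the evaluated frames;
#'   defaults to the union of frames seen in either input. Pass the full
#'   frame list when empty frames should count as true negatives.
#' @return A list of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
match_and_count <- function(detections, annotations, iou_thr = 0.5,
                            frames = NULL) {
  if (is.null(frames))
    frames <- union(unique(as.character(detections$frame)),
                    unique(as.character(annotations$frame)))
  counts <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in frames) {
    det <- detections[as.character(detections$frame) == f, , drop = FALSE]
    ann <- annotations[as.character(annotations$frame) == f &
                         annotations$label == "lying", , drop = FALSE]
    if (nrow(det) == 0L && nrow(ann) == 0L) {
      counts["TN"] <- counts["TN"] + 1L
      next
    }
    tp_frame <- 0L
    if (nrow(det) && nrow(ann)) {
      m <- iou_matrix(det, ann)
      repeat {
        best <- which.max(m)
        if (!length(best) || m[best] < iou_thr) break
        k <- arrayInd(best, dim(m))
        tp_frame <- tp_frame + 1L
        m[k[1], ] <- -1; m[, k[2]] <- -1
      }
    }
    counts["TP"] <- counts["TP"] + tp_frame
    counts["FP"] <- counts["FP"] + nrow(det) - tp_frame
    counts["FN"] <- counts["FN"] + nrow(ann) - tp_frame
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `A = (TP+TN)/(TP+TN+FP+FN)`, `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)` (equivalently `2TP/(2TP+FP+FN)`). A ratio with a zero
#' denominator is reported as 0 with a warning.
#'
#' @param counts a `confusion_counts` list (or any list with `TP`, `TN`,
#'   `FP`, `FN`).
#' @return A list of class `eval_summary`: `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  P <- ratio(TP, TP + FP, "precision")
  R <- ratio(TP, TP + FN, "recall")
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(accuracy = (TP + TN) / total, precision = P, recall = R,
                 f1 = F1),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Score a detection set against annotations
#'
#' Convenience wrapper: [match_and_count()] then [metrics()].
#'
#' @inheritParams match_and_count
#' @return An `eval_summary` with the counts attached as attribute
#'   `"counts"`.
#' @export
evaluate_detections <- function(detections, annotations, iou_thr = 0.5,
                                frames = NULL) {
  counts <- match_and_count(detections, annotations, iou_thr, frames)
  out <- metrics(counts)
  attr(out, "counts") <- counts
  out
}

# Run detect_lying over a manifest dataset, returning stacked detections
# and annotations.
run_dataset <- function(manifest, params = detection_params(),
                        trough_method = "variance",
                        config = pipeline_config()) {
  det <- list(); ann <- list()
  for (i in seq_along(manifest$frames)) {
    fr_entry <- manifest$frames[[i]]
    frame <- read_merged(file.path(manifest$dir, fr_entry$file))
    id <- sub("\\.png$", "", fr_entry$file)
    d <- detect_lying(frame, params = params, trough_method = trough_method,
                      config = config, frame_id = id)
    det[[i]] <- d
    bx <- fr_entry$boxes
    if (nrow(bx)) {
      bx$frame <- id
      ann[[i]] <- bx
    } else {
      ann[[i]] <- data.frame(x = integer(0), y = integer(0), w = integer(0),
                             h = integer(0), label = character(0),
                             frame = character(0))
    }
  }
  list(detections = do.call(rbind, det), annotations = do.call(rbind, ann),
       frames = vapply(manifest$frames,
                       function(f) sub("\\.png$", "", f$file), character(1)))
}

#' Exhaustive parameter grid search maximising F1
#'
#' Runs the full detection pipeline for every combination of the supplied
#' parameter values on an annotated dataset and scores each combination at
#' the given IoU threshold. Enumeration is exhaustive (no optimiser), so the
#' returned table supports one-parameter-at-a-time control-variable curves.
#'
#' @param dataset a dataset directory or manifest from [read_manifest()].
#' @param grid named list of candidate values for any of `k1` ... `k5`;
#'   parameters not listed stay at their [detection_params()] defaults.
#' @param iou_thr IoU threshold for scoring.
#' @param trough_method trough locator passed to [detect_lying()].
#' @param config pipeline configuration.
#' @return A list with `best` (the winning [detection_params()]), `best_f1`,
#'   and `table` (one row per combination with its accuracy, precision,
#'   recall and F1). Ties keep the first combination in grid order.
#' @export
grid_search <- function(dataset, grid, iou_thr = 0.5,
                        trough_method = "variance",
                        config = pipeline_config()) {
  if (!is.list(grid) || !length(grid))
    stop("`grid` must be a non-empty named list", call. = FALSE)
  bad <- setdiff(names(grid), c("k1", "k2", "k3", "k4", "k5"))
  if (length(bad))
    stop(sprintf("unknown grid parameters: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (is.character(dataset)) dataset <- read_manifest(dataset)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  # enumeration can produce infeasible pairs (e.g. k2 >= k3); skip them
  feasible <- vapply(seq_len(nrow(combos)), function(i) {
    !inherits(try(do.call(detection_params,
                          as.list(combos[i, , drop = FALSE])),
                  silent = TRUE), "try-error")
  }, logical(1))
  combos <- combos[feasible, , drop = FALSE]
  if (!nrow(combos)) stop("no feasible parameter combination in the grid",
                          call. = FALSE)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- do.call(detection_params, as.list(combos[i, , drop = FALSE]))
    res <- run_dataset(dataset, params = p, trough_method = trough_method,
                       config = config)
    s <- suppressWarnings(
      evaluate_detections(res$detections, res$annotations, iou_thr,
                          frames = res$frames))
    rows[[i]] <- cbind(combos[i, , drop = FALSE],
                       data.frame(accuracy = s$accuracy,
                                  precision = s$precision,
                                  recall = s$recall, f1 = s$f1))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best_i <- which.max(tab$f1)
  best <- do.call(detection_params, as.list(combos[best_i, , drop = FALSE]))
  list(best = best, best_f1 = tab$f1[best_i], table = tab)
}

#' Daily lying-time status rule
#'
#' Under uniform sampling of a bird through one daytime window, the
#' fraction of observations in lying posture estimates the fraction of
#' photographed time spent lying. A bird lying for at least half of its
#' photographed time is flagged abnormal (possible atrophy or sickness);
#' under half is normal.
#'
#' @param observations logical vector of lying indicators, or a data frame
#'   with a `lying` column (0/1 or logical).
#' @param id bird or cage identifier for the report.
#' @return A list of class `status_report`: `id`, `lying_fraction`,
#'   `status` (`"normal"` or `"abnormal"`).
#' @examples
#' daily_status(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
#'                TRUE, TRUE))
#' @export
daily_status <- function(observations, id = "") {
  lying <- if (is.data.frame(observations)) observations$lying else observations
  if (!length(lying)) stop("no observations", call. = FALSE)
  lying <- as.logical(lying)
  if (anyNA(lying)) stop("lying indicators must be 0/1 or logical",
                         call. = FALSE)
  frac <- mean(lying)
  structure(list(id = id, lying_fraction = frac,
                 status = if (frac >= 0.5) "abnormal" else "normal"),
            class = "status_report")
}

#' @export
print.status_report <- function(x, ...) {
  cat(sprintf("<status_report> %s: lying %.1f%% of photographed time -> %s\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              100 * x$lying_fraction, x$status))
  invisible(x)
}
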