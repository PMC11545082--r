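# Pipeline configuration and batch orchestration.

#' Pipeline configuration
#'
#' Collects every stage's tunables in one nested list, mirroring the YAML
#' configuration namespaces used by the command-line interface
#' (`correction.*`, `trough.*`, `key_area.*`, `posture.*`).
#'
#' @param correction list: `roi` (`c(x0, y0, x1, y1)`), `binarize_threshold`,
#'   `hough` ([hough_params()]).
#' @param trough list: `method` (`"variance"` or `"features"`),
#'   `variance_threshold` (mm^2), `hessian_threshold`, `border_cols`.
#' @param key_area list: `side_margin` (px).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(correction = list(), trough = list(),
                            key_area = list()) {
  defaults <- list(
    correction = list(roi = c(25, 80, 615, 300), binarize_threshold = 100,
                      hough = hough_params()),
    trough = list(method = "variance", variance_threshold = 400,
                  hessian_threshold = 400, border_cols = 50),
    key_area = list(side_margin = 25))
  out <- defaults
  out$correction[names(correction)] <- correction
  out$trough[names(trough)] <- trough
  out$key_area[names(key_area)] <- key_area
  structure(out, class = "pipeline_config")
}

#' Read a pipeline configuration (and detection parameters) from YAML
#'
#' The file may contain any of the namespaces `correction`, `trough`,
#' `key_area` and `posture`; the `posture` block maps onto
#' [detection_params()] fields. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A list with `config` (a [pipeline_config()]) and `params`
#'   (a [detection_params()]).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    correction = if (!is.null(y$correction)) {
      cc <- y$correction
      if (!is.null(cc$roi)) cc$roi <- as.numeric(unlist(cc$roi))
      if (!is.null(cc$hough)) cc$hough <- do.call(hough_params, cc$hough)
      cc
    } else list(),
    trough = if (!is.null(y$trough)) y$trough else list(),
    key_area = if (!is.null(y$key_area)) y$key_area else list())
  params <- if (!is.null(y$posture)) do.call(detection_params, y$posture)
            else detection_params()
  list(config = cfg, params = params)
}

#' Process a batch of merged frames
#'
#' Runs [detect_lying()] on every input frame, collecting detections,
#' skipped frames (no trough found) and per-frame failures (unreadable
#' files are logged and the run continues). When `output_dir` is given,
#' writes `detections.json` (records `{frame, x, y, w, h, posture}`),
#' `skipped.json` and `summary.json` there.
#'
#' @param inputs character vector of merged PNG paths (globs accepted).
#' @param output_dir optional output directory.
#' @param params a [detection_params()].
#' @param trough_method `"variance"` or `"features"`.
#' @param config a [pipeline_config()].
#' @param verbose print a line per frame.
#' @return A list: `summary` (frames processed, detections, skips,
#'   failures), `detections` (data frame), `skipped`, `failed`.
#' @export
run_batch <- function(inputs, output_dir = NULL, params = detection_params(),
                      trough_method = c("variance", "features"),
                      config = pipeline_config(), verbose = FALSE) {
  trough_method <- match.arg(trough_method)
  files <- unlist(lapply(inputs, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  }), use.names = FALSE)
  files <- unique(files)
  if (!length(files)) stop("no input frames", call. = FALSE)
  det <- list(); skipped <- character(0); failed <- character(0)
  for (f in files) {
    id <- sub("\\.png$", "", basename(f))
    if (verbose) message(sprintf("[%s] correcting/locating/detecting", id))
    d <- tryCatch(
      detect_lying(read_merged(f), params = params,
                   trough_method = trough_method, config = config,
                   frame_id = id),
      error = function(e) {
        warning(sprintf("frame %s failed: %s", id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(d)) { failed <- c(failed, id); next }
    if (isTRUE(attr(d, "skipped"))) skipped <- c(skipped, id)
    attributes(d)[c("corrected", "trough", "key_area", "skipped")] <- NULL
    det[[length(det) + 1]] <- d
  }
  detections <- if (length(det)) do.call(rbind, det) else empty_detections()
  summary <- list(frames_total = length(files),
                  frames_processed = length(files) - length(failed),
                  detections = nrow(detections),
                  frames_skipped_no_trough = length(skipped),
                  frames_failed = length(failed))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(detections, file.path(output_dir, "detections.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(skipped, file.path(output_dir, "skipped.json"))
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE)
  }
  list(summary = summary, detections = detections, skipped = skipped,
       failed = failed)
}
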