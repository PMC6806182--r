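# Video tracking: landmark fitting frame-to-frame with pluggable
# frame-update strategies, mirroring the classic tracker variants
# (bounds/shape updates; dynamic/fixed boxes).

#' Tracker configuration
#'
#' @param update_strategy How the next frame is initialized from the current
#'   result: "bounds_update" (tight landmark bounding box), "shape_update"
#'   (the landmark shape itself, warm-starting the fitter), "dynamic_box"
#'   (detector-style face box recentered AND rescaled to the current shape)
#'   or "fixed_box" (box size frozen at frame 0, only the center follows the
#'   face).
#' @param redetect_on_failure Rerun the face detector when the fitting cost
#'   exceeds `failure_cost_threshold`.
#' @param failure_cost_threshold Cost above which a fit counts as failed
#'   (default: the fitter model's calibrated threshold, if any).
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(update_strategy = c("dynamic_box", "bounds_update",
                                               "shape_update", "fixed_box"),
                           redetect_on_failure = TRUE,
                           failure_cost_threshold = NULL) {
  structure(list(update_strategy = match.arg(update_strategy),
                 redetect_on_failure = isTRUE(redetect_on_failure),
                 failure_cost_threshold = failure_cost_threshold),
            class = "tracker_config")
}

fitter_fit <- function(fitter_model, frame, init_box, init_shape = NULL) {
  if (inherits(fitter_model, "aam_model")) {
    if (!is.null(init_shape))
      init_box <- shape_face_box(init_shape)
    fit_aam(frame, init_box, fitter_model)
  } else if (inherits(fitter_model, "shape_regressor")) {
    if (!is.null(init_shape)) init_box <- shape_bbox(init_shape)
    fit_regressor(frame, init_box, fitter_model)
  } else stop_input("track_video: unknown fitter model class")
}

fitter_failure_threshold <- function(fitter_model, config) {
  if (!is.null(config$failure_cost_threshold))
    return(config$failure_cost_threshold)
  if (inherits(fitter_model, "aam_model"))
    return(fitter_model$failure_cost_threshold)
  Inf
}

#' Track a face through a video
#'
#' Frame 0 is initialized from the highest-scoring face detection (or an
#' explicit `init_box`); every subsequent frame is initialized from the
#' current result according to the configured update strategy. If a fit's
#' cost exceeds the failure threshold and `redetect_on_failure` is set, the
#' detector is rerun on that frame.
#'
#' @param frames List of `thermal_frame` or `annotated_frame` (>= 1).
#' @param fitter_model An `aam_model` or `shape_regressor`.
#' @param detector A `detector_model` (optional if `init_box` given).
#' @param config A [tracker_config()].
#' @param init_box Optional explicit frame-0 initialization box.
#' @return List of [fit_result()], one per frame.
#' @export
track_video <- function(frames, fitter_model, detector = NULL,
                        config = tracker_config(), init_box = NULL) {
  if (length(frames) < 1) stop_input("track_video: empty frame list")
  get_frame <- function(x) if (inherits(x, "annotated_frame")) x$frame else x
  detect_box <- function(frame) {
    dets <- detect_faces(frame, detector)
    if (length(dets) == 0) NULL else dets[[1]]$box
  }
  f0 <- get_frame(frames[[1]])
  box0 <- if (!is.null(init_box)) init_box else {
    if (is.null(detector)) stop_input("track_video: need detector or init_box")
    b <- detect_box(f0)
    if (is.null(b))
      stop(errorCondition("track_video: no face found in frame 0",
                          class = c("thermoface_tracking_error",
                                    "thermoface_error")))
    b
  }
  thr <- fitter_failure_threshold(fitter_model, config)
  results <- vector("list", length(frames))
  res <- fitter_fit(fitter_model, f0, box0)
  results[[1]] <- res
  frame0_size <- c(shape_face_box(res$shape)$width,
                   shape_face_box(res$shape)$height)
  if (!is.null(init_box) || is.null(detector)) {
    frame0_size <- c(box0$width, box0$height)
  }
  for (i in seq_along(frames)[-1]) {
    fr <- get_frame(frames[[i]])
    cur <- results[[i - 1]]$shape
    strat <- config$update_strategy
    if (strat == "shape_update") {
      res <- fitter_fit(fitter_model, fr, NULL, init_shape = cur)
    } else {
      nb <- switch(strat,
        bounds_update = shape_bbox(cur),
        dynamic_box = shape_face_box(cur),
        fixed_box = {
          fb <- shape_face_box(cur)
          cx <- fb$x0 + fb$width / 2; cy <- fb$y0 + fb$height / 2
          bounding_box(cx - frame0_size[1] / 2, cy - frame0_size[2] / 2,
                       frame0_size[1], frame0_size[2])
        })
      res <- fitter_fit(fitter_model, fr, nb)
    }
    if (config$redetect_on_failure && !is.null(detector) &&
        res$final_cost > thr) {
      b <- detect_box(fr)
      if (!is.null(b)) res <- fitter_fit(fitter_model, fr, b)
    }
    results[[i]] <- res
  }
  results
}
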