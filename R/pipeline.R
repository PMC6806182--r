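# In-process modular pipeline: an ordered chain of pluggable stages
# (source -> detector -> landmarker -> [frontalizer] -> analyzer(s) -> sink)
# with per-frame failure isolation: a stage exception marks that frame's
# downstream outputs skipped and never aborts the run.

.stage_registry <- new.env(parent = emptyenv())

#' Register a pipeline stage implementation
#'
#' @param kind One of "detector", "landmarker", "frontalizer", "analyzer",
#'   "sink".
#' @param id Registry key.
#' @param factory `function(config)` returning `function(frame, upstream,
#'   state)`; the returned function is called per frame with the accumulated
#'   upstream outputs and a persistent per-run `state` environment, and must
#'   return a named list of outputs.
#' @return `id`, invisibly.
#' @export
register_stage <- function(kind, id, factory) {
  kind <- match.arg(kind, c("detector", "landmarker", "frontalizer",
                            "analyzer", "sink"))
  assign(paste(kind, id, sep = "/"), factory, envir = .stage_registry)
  invisible(id)
}

resolve_stage <- function(kind, id) {
  key <- paste(kind, id, sep = "/")
  if (!exists(key, envir = .stage_registry))
    stop_config("run_pipeline: unknown stage implementation '", key, "'")
  get(key, envir = .stage_registry)
}

#' Pipeline stage specification
#'
#' @param name Stage instance name (used in results and logs).
#' @param kind Stage kind; pipelines must be ordered
#'   detector -> landmarker -> [frontalizer] -> analyzer(s) -> sink.
#' @param id Registry key of the implementation.
#' @param config Named list of stage parameters (models, ROIs, ...).
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(name, kind, id, config = list()) {
  structure(list(name = name, kind = kind, id = id, config = config),
            class = "stage_spec")
}

kind_rank <- c(detector = 1, landmarker = 2, frontalizer = 3, analyzer = 4,
               sink = 5)

#' Run the modular analysis pipeline over a frame sequence
#'
#' Stages are resolved against the registry before any frame is processed
#' (unknown ids are a configuration error). Frames are processed in order;
#' a stage exception on one frame records that stage as failed and skips its
#' downstream stages for that frame only. One structured log record is
#' emitted per stage per frame.
#'
#' @param stages List of [stage_spec()] in valid kind order.
#' @param frames List of `thermal_frame` (or `annotated_frame`).
#' @return List with `results` (per-frame: `frame_index`, `outputs`,
#'   `status`) and `log` (data.frame frame/stage/status/detail).
#' @export
run_pipeline <- function(stages, frames) {
  ranks <- kind_rank[vapply(stages, `[[`, character(1), "kind")]
  if (anyNA(ranks) || any(diff(ranks) < 0))
    stop_config("run_pipeline: stages must follow detector -> landmarker -> ",
                "frontalizer -> analyzer -> sink order")
  impls <- lapply(stages, function(sp)
    resolve_stage(sp$kind, sp$id)(sp$config))
  state <- new.env(parent = emptyenv())
  results <- vector("list", length(frames))
  log_rows <- list()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (inherits(fr, "annotated_frame")) fr <- fr$frame
    upstream <- list()
    status <- stats::setNames(rep("ok", length(stages)),
                              vapply(stages, `[[`, character(1), "name"))
    failed_at <- NA_integer_
    for (s in seq_along(stages)) {
      nm <- stages[[s]]$name
      if (!is.na(failed_at)) {
        status[nm] <- "skipped"
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(frame = i - 1L, stage = nm, status = "skipped",
                     detail = "")
        next
      }
      out <- tryCatch(impls[[s]](fr, upstream, state),
                      error = function(e) e)
      if (inherits(out, "error")) {
        status[nm] <- paste0("failed: ", conditionMessage(out))
        failed_at <- s
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(frame = i - 1L, stage = nm, status = "failed",
                     detail = conditionMessage(out))
      } else {
        upstream[names(out)] <- out
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(frame = i - 1L, stage = nm, status = "ok", detail = "")
      }
    }
    results[[i]] <- list(frame_index = i - 1L, outputs = upstream,
                         status = status)
  }
  list(results = results, log = do.call(rbind, log_rows))
}

# ---- built-in stage implementations -------------------------------------

register_builtin_stages <- function() {
  register_stage("detector", "hog_svm", function(config) {
    model <- config$model
    function(frame, upstream, state) {
      dets <- detect_faces(frame, model)
      if (length(dets) == 0) stop("no face detected")
      list(detection = dets[[1]], all_detections = dets)
    }
  })
  landmarker_factory <- function(fit_fun) function(config) {
    model <- config$model
    track <- isTRUE(config$track)
    function(frame, upstream, state) {
      init <- upstream$detection$box
      if (track && !is.null(state$last_shape))
        init <- shape_face_box(state$last_shape)
      res <- fit_fun(frame, init, model)
      if (track) state$last_shape <- res$shape
      list(fit = res, shape = res$shape)
    }
  }
  register_stage("landmarker", "shape_regressor",
                 landmarker_factory(fit_regressor))
  register_stage("landmarker", "aam_hq", landmarker_factory(fit_aam))
  register_stage("landmarker", "aam_fast", landmarker_factory(fit_aam))
  register_stage("frontalizer", "piecewise_affine", function(config) {
    canonical <- config$canonical
    function(frame, upstream, state) {
      list(frontalized = frontalize(frame, upstream$shape, canonical))
    }
  })
  register_stage("analyzer", "respiration", function(config) {
    roi <- config$roi
    function(frame, upstream, state) {
      r <- extract_roi(upstream$frontalized, roi, config$calibration)
      list(roi_mean = r$mean_value, roi_valid_fraction = r$valid_fraction)
    }
  })
  register_stage("analyzer", "emotion", function(config) {
    model <- config$model
    function(frame, upstream, state) {
      cl <- classify_emotion(model, frame, upstream$shape)
      list(emotion = cl$label, emotion_probabilities = cl$probabilities)
    }
  })
  register_stage("sink", "memory", function(config) {
    function(frame, upstream, state) list()
  })
}

.onLoad <- function(libname, pkgname) {
  register_builtin_stages()
}

# ---- evaluation harness --------------------------------------------------

#' Evaluate detections against ground-truth boxes
#'
#' @param detections_per_frame List (one element per frame) of lists of
#'   `detection` (empty list = no detection).
#' @param gt_boxes List of ground-truth `bounding_box`, same length.
#' @param threshold IoU correctness threshold (default 0.5).
#' @return List with `iou` (per-frame best-detection IoU, 0 if none) and
#'   `recall` (fraction of frames at or above the threshold).
#' @export
evaluate_detection <- function(detections_per_frame, gt_boxes,
                               threshold = 0.5) {
  stopifnot(length(detections_per_frame) == length(gt_boxes))
  ious <- vapply(seq_along(gt_boxes), function(i) {
    dets <- detections_per_frame[[i]]
    if (length(dets) == 0) return(0)
    max(vapply(dets, function(d) iou(d$box, gt_boxes[[i]]), numeric(1)))
  }, numeric(1))
  list(iou = ious, recall = mean(ious >= threshold))
}

#' Evaluate landmark predictions against ground truth
#'
#' Missing predictions (NULL) are excluded from the averages and counted as
#' failures.
#'
#' @param predicted List of `shape68` or NULL.
#' @param truth List of ground-truth `shape68`, same length.
#' @return List with `nrmse` (per-frame, NA where missing), `mean`, `median`,
#'   `n_failures`.
#' @export
evaluate_landmarks <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_input("evaluate_landmarks: length mismatch")
  errs <- vapply(seq_along(truth), function(i) {
    if (is.null(predicted[[i]])) return(NA_real_)
    nrmse(predicted[[i]], truth[[i]])
  }, numeric(1))
  list(nrmse = errs, mean = mean(errs, na.rm = TRUE),
       median = stats::median(errs, na.rm = TRUE),
       n_failures = sum(is.na(errs)))
}

#' Confusion matrix and accuracy for emotion labels
#'
#' @param true_labels,predicted_labels Character vectors drawn from
#'   `classes`.
#' @param classes Label set (default [emotion_classes()]).
#' @return List with `matrix` (rows = true, columns = predicted),
#'   `per_class_accuracy`, `accuracy`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             classes = emotion_classes()) {
  if (length(true_labels) == 0) stop_input("confusion_matrix: empty input")
  if (length(true_labels) != length(predicted_labels))
    stop_input("confusion_matrix: length mismatch")
  if (!all(c(true_labels, predicted_labels) %in% classes))
    stop_input("confusion_matrix: unknown label")
  m <- table(factor(true_labels, levels = classes),
             factor(predicted_labels, levels = classes))
  m <- unclass(m)
  names(dimnames(m)) <- c("true", "predicted")
  acc <- sum(diag(m)) / sum(m)
  per_class <- diag(m) / pmax(rowSums(m), 1)
  list(matrix = m, per_class_accuracy = per_class, accuracy = acc)
}

#' Plot a sorted per-frame metric curve (IoU or NRMSE)
#' @param values Numeric vector.
#' @param ylab Axis label.
#' @param threshold Optional horizontal reference line.
#' @return Invisibly, the sorted values.
#' @export
plot_metric_curve <- function(values, ylab = "IoU", threshold = NULL) {
  s <- sort(values)
  graphics::plot(seq_along(s), s, type = "s", xlab = "frame (sorted)",
                 ylab = ylab)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(s)
}
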