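#' Prediction rate of a marker over a video
#'
#' PM is the number of images with a predicted marker; PM/TI divides it by
#' the total image count of the video.
#'
#' @param track A [marker_track()].
#' @param meta A [video_meta()]; `meta$n_frames` is TI.
#' @return List with `PM` and `pm_ti`.
#' @export
prediction_rates <- function(track, meta) {
  ti <- meta$n_frames
  if (is.null(ti) || ti == 0) stop_st("total image count TI must be positive")
  if (nrow(track) && max(track$frame) > ti) {
    stop_st("track has frames beyond TI = %d", ti)
  }
  pm <- sum(track$predicted)
  list(PM = pm, pm_ti = pm / ti)
}

#' Classify per-frame detections against ground truth
#'
#' Scores one marker's predictions over an evaluation window, frame by
#' frame. A frame with an annotated position (visible or partly occluded —
#' the annotation supplies positions for occluded markers, so their
#' non-prediction is a miss) is a true positive when a prediction lies
#' within `match_radius_px` of the true position, a false negative when
#' unpredicted, and a false positive when the prediction is farther than the
#' match radius. A hidden frame (`not_visible`) is a true negative when
#' unpredicted and a false positive when predicted.
#'
#' @param predicted A [marker_track()].
#' @param truth Annotation data.frame (`frame, marker, x, y, visibility`);
#'   rows for other markers are ignored.
#' @param match_radius_px True-positive match radius in pixels; default 100
#'   (about 3.7% of a 2704-px frame, generous for coarse body-region
#'   markers, far tighter than distractor mislabels).
#' @param window Integer vector of frames to evaluate, e.g. `1:1000` or the
#'   last 1000 frames.
#' @param label Window label stored on the result (`"first1000"`, ...).
#' @return List of class `confusion_counts`: `TP, TN, FP, FN, marker, window`.
#' @export
classify_confusion <- function(predicted, truth, match_radius_px = 100,
                               window = NULL, label = "custom") {
  m <- attr(predicted, "marker") %||% "unknown"
  if ("marker" %in% names(truth)) truth <- truth[truth$marker == m, , drop = FALSE]
  if (is.null(window)) window <- truth$frame
  miss_t <- setdiff(window, truth$frame)
  miss_p <- setdiff(window, predicted$frame)
  missing_both <- intersect(miss_t, miss_p)
  if (length(missing_both)) {
    stop_st("frame %d in the window is present in neither table", missing_both[1])
  }
  if (length(miss_t)) {
    stop_st("frame %d in the window has no ground-truth annotation", miss_t[1])
  }
  ti <- truth[match(window, truth$frame), ]
  pi_ <- predicted[match(window, predicted$frame), ]
  has_pred <- !is.na(pi_$predicted) & pi_$predicted
  hidden <- ti$visibility == "not_visible"
  d <- euclid(pi_$x, pi_$y, ti$x, ti$y)
  tp <- !hidden & has_pred & !is.na(d) & d <= match_radius_px
  fp <- has_pred & (hidden | (!is.na(d) & d > match_radius_px))
  tn <- hidden & !has_pred
  fn <- !hidden & !has_pred
  structure(list(TP = sum(tp), TN = sum(tn), FP = sum(fp), FN = sum(fn),
                 marker = m, window = label),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion (%s, %s): TP %d  TN %d  FP %d  FN %d\n",
              x$marker, x$window, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Detection performance metrics
#'
#' Sensitivity `TP / (TP + FN)`, error rate `FP / (TP + FP)` and accuracy
#' `(TP + TN) / (TP + FP + TN + FN)`. A metric whose denominator is zero is
#' returned as `NA` (undefined) and is excluded by [aggregate_mean_sd()].
#'
#' @param counts A `confusion_counts` object or list with `TP, TN, FP, FN`.
#' @return List with `sensitivity`, `error_rate`, `accuracy`.
#' @examples
#' performance_metrics(list(TP = 88, TN = 0, FP = 0, FN = 12))$sensitivity  # 0.88
#' @export
performance_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop_st("confusion counts must be >= 0")
    div <- function(num, den) if (den == 0) NA_real_ else num / den
    list(sensitivity = div(TP, TP + FN),
         error_rate = div(FP, TP + FP),
         accuracy = div(TP + TN, TP + FP + TN + FN))
  })
}

#' Mean and SD of a per-video metric
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) over
#' per-video values, the form in which robustness quantities are summarised.
#' Undefined (`NA`) values are excluded and counted; a single defined value
#' reports `sd = 0` with `n = 1`.
#'
#' @param values Numeric vector, possibly containing `NA`.
#' @return List with `mean`, `sd`, `n` (defined values) and `n_undefined`.
#' @export
aggregate_mean_sd <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop_st("all values are undefined")
  v <- values[ok]
  list(mean = mean(v),
       sd = if (length(v) == 1) 0 else stats::sd(v),
       n = length(v), n_undefined = sum(!ok))
}

#' Per-video robustness metrics for a set of marker tracks
#'
#' Convenience wrapper combining [prediction_rates()] and [qc_report()] into
#' the per-video, per-marker robustness table: PM, TI, PM/TI, WP and %WP
#' (100 * WP / PM).
#'
#' @param tracks Named list of [marker_track()] objects.
#' @param meta A [video_meta()].
#' @param ground_truth Optional annotation table for missing-run masking.
#' @param jump_threshold_px,min_missing_run QC thresholds.
#' @return data.frame `video_id, marker, PM, TI, pm_ti, WP, pct_wp`.
#' @export
per_video_metrics <- function(tracks, meta, ground_truth = NULL,
                              jump_threshold_px = 200, min_missing_run = 30) {
  qc <- qc_report(tracks, ground_truth, jump_threshold_px, min_missing_run,
                  video_id = meta$video_id)
  rows <- lapply(names(tracks), function(m) {
    pr <- prediction_rates(tracks[[m]], meta)
    wp <- qc$wp$WP[qc$wp$marker == m]
    data.frame(video_id = meta$video_id, marker = m, PM = pr$PM,
               TI = meta$n_frames, pm_ti = pr$pm_ti, WP = wp,
               pct_wp = if (pr$PM > 0) 100 * wp / pr$PM else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
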