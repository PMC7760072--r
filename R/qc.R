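#' Squared-displacement jump statistic between two frames
#'
#' The screening statistic used to surface teleport mislabels:
#' `((x2 - x1) * (frame2 - frame1))^2 + ((y2 - y1) * (frame2 - frame1))^2`,
#' in squared pixels. For adjacent frames (gap 1) it reduces to the squared
#' Euclidean displacement. The plain Euclidean displacement is returned
#' alongside, since thresholding is done on displacement.
#'
#' @param x1,y1,frame1 Position and frame index of the earlier observation.
#' @param x2,y2,frame2 Position and frame index of the later observation.
#' @return List with `statistic` (squared px) and `displacement_px`.
#' @examples
#' jump_statistic(100, 100, 1, 400, 100, 2)  # statistic 90000, displacement 300
#' @export
jump_statistic <- function(x1, y1, frame1, x2, y2, frame2) {
  if (any(frame2 <= frame1)) stop_st("frame2 must be greater than frame1")
  if (!all(is.finite(c(x1, y1, x2, y2)))) stop_st("positions must be finite")
  gap <- frame2 - frame1
  list(
    statistic = ((x2 - x1) * gap)^2 + ((y2 - y1) * gap)^2,
    displacement_px = euclid(x1, y1, x2, y2)
  )
}

#' Detect marker-position jumps (teleport mislabels)
#'
#' Scans successive predicted frames of one track and flags pairs whose
#' Euclidean displacement exceeds the pixel threshold — more than
#' `threshold_px` between two consecutive frames. Across prediction gaps of
#' g frames the threshold scales to `g * threshold_px` (`gap_rule =
#' "scaled"`), so plausible continuous motion over a gap is not flagged;
#' `gap_rule = "adjacent_only"` restricts screening to gap-1 pairs. Each
#' flagged pair yields one QC segment carrying both the squared
#' [jump_statistic()] value and the displacement.
#'
#' @param track A [marker_track()].
#' @param threshold_px Displacement threshold in pixels; strictly exceeded
#'   to flag (default 200).
#' @param gap_rule `"scaled"` (default) or `"adjacent_only"`.
#' @param video_id Identifier recorded in the segments.
#' @return data.frame `video_id, marker, start_frame, end_frame, reason,
#'   statistic_value, displacement_px`, ordered by start frame.
#' @export
detect_jumps <- function(track, threshold_px = 200,
                         gap_rule = c("scaled", "adjacent_only"),
                         video_id = "video") {
  gap_rule <- match.arg(gap_rule)
  pr <- track[track$predicted, , drop = FALSE]
  empty <- qc_segment_frame()
  if (nrow(pr) < 2) return(empty)
  n <- nrow(pr)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  gap <- pr$frame[i2] - pr$frame[i1]
  disp <- euclid(pr$x[i1], pr$y[i1], pr$x[i2], pr$y[i2])
  stat <- (disp * gap)^2
  thr <- switch(gap_rule, scaled = gap * threshold_px, adjacent_only = threshold_px)
  hit <- disp > thr
  if (gap_rule == "adjacent_only") hit <- hit & gap == 1
  if (!any(hit)) return(empty)
  data.frame(video_id = video_id, marker = attr(track, "marker") %||% "unknown",
             start_frame = pr$frame[i1][hit], end_frame = pr$frame[i2][hit],
             reason = "jump", statistic_value = stat[hit],
             displacement_px = disp[hit], stringsAsFactors = FALSE)
}

#' Detect long missing-prediction runs
#'
#' Flags maximal runs of consecutive frames where a marker is expected to be
#' visible but carries no prediction, with run length strictly greater than
#' `min_run` (more than `min_run` consecutive images). With no ground truth
#' every frame is treated as expected-visible — a conservative screening
#' mode; with ground truth, frames annotated `not_visible` are excluded from
#' the expectation, so a correctly unpredicted hidden marker never triggers
#' a flag.
#'
#' @param track A [marker_track()].
#' @param ground_truth Optional annotation data.frame
#'   (`frame, marker, x, y, visibility`) for this track's marker or all markers.
#' @param min_run Flag runs longer than this many frames (default 30).
#' @param video_id Identifier recorded in the segments.
#' @return data.frame in the same shape as [detect_jumps()] with reason
#'   `missing_run` (statistic columns `NA`).
#' @export
detect_missing_runs <- function(track, ground_truth = NULL, min_run = 30,
                                video_id = "video") {
  m <- attr(track, "marker") %||% "unknown"
  expected <- rep(TRUE, nrow(track))
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    if ("marker" %in% names(gt)) gt <- gt[gt$marker == m, , drop = FALSE]
    hidden_frames <- gt$frame[gt$visibility == "not_visible"]
    expected[track$frame %in% hidden_frames] <- FALSE
  }
  miss <- expected & !track$predicted
  runs <- true_runs(miss)
  runs <- runs[runs$end - runs$start + 1 > min_run, , drop = FALSE]
  if (!nrow(runs)) return(qc_segment_frame())
  data.frame(video_id = video_id, marker = m,
             start_frame = track$frame[runs$start],
             end_frame = track$frame[runs$end],
             reason = "missing_run", statistic_value = NA_real_,
             displacement_px = NA_real_, stringsAsFactors = FALSE)
}

#' Strike teleported frames from a track
#'
#' Marks as unpredicted the frames that [detect_jumps()] identifies as
#' teleport landings: a mislabelled frame sits at the end of one jump
#' segment and the start of the next (the marker jumps out and back), so
#' frames participating in two jump segments are struck (a clean frame
#' sandwiched between two teleports shares that signature and is struck
#' conservatively). Neighbour frames
#' that merely border a jump keep their positions. This is the automated
#' counterpart of striking mislabelled sections before behaviour analysis.
#'
#' @param track A [marker_track()].
#' @param threshold_px Displacement threshold passed to [detect_jumps()].
#' @return The cleaned [marker_track()].
#' @export
remove_flagged_jumps <- function(track, threshold_px = 200) {
  jumps <- detect_jumps(track, threshold_px = threshold_px)
  if (!nrow(jumps)) return(track)
  hit <- c(jumps$start_frame, jumps$end_frame)
  bad <- unique(hit[duplicated(hit)])
  if (!length(bad)) return(track)
  keep <- !track$frame %in% bad
  marker_track(frame = track$frame,
               x = ifelse(keep, track$x, NA_real_),
               y = ifelse(keep, track$y, NA_real_),
               predicted = track$predicted & keep,
               marker = attr(track, "marker"),
               width_px = attr(track, "width_px"),
               height_px = attr(track, "height_px"))
}

qc_segment_frame <- function() {
  data.frame(video_id = character(), marker = character(),
             start_frame = integer(), end_frame = integer(),
             reason = character(), statistic_value = double(),
             displacement_px = double(), stringsAsFactors = FALSE)
}

#' Screening report: wrongly predicted frames and QC segments
#'
#' Runs [detect_jumps()] and [detect_missing_runs()] over a set of marker
#' tracks and tallies the wrongly predicted image count (WP) per marker: the
#' number of distinct predicted frames participating in at least one jump
#' segment (a frame shared by two segments counts once).
#'
#' @param tracks Named list of [marker_track()] objects.
#' @param ground_truth Optional annotation table passed to
#'   [detect_missing_runs()].
#' @param jump_threshold_px Displacement threshold (default 200).
#' @param min_missing_run Missing-run threshold (default 30).
#' @param video_id Identifier recorded in the report.
#' @return List with `wp` (data.frame `marker, WP`) and `segments` (all QC
#'   segments sorted by start frame).
#' @export
qc_report <- function(tracks, ground_truth = NULL, jump_threshold_px = 200,
                      min_missing_run = 30, video_id = "video") {
  seg_list <- list(); wp <- integer()
  for (m in names(tracks)) {
    tr <- tracks[[m]]
    jumps <- detect_jumps(tr, threshold_px = jump_threshold_px, video_id = video_id)
    missing <- detect_missing_runs(tr, ground_truth, min_run = min_missing_run,
                                   video_id = video_id)
    seg_list[[m]] <- rbind(jumps, missing)
    wp[m] <- length(unique(c(jumps$start_frame, jumps$end_frame)))
  }
  segments <- do.call(rbind, c(seg_list, list(qc_segment_frame())))
  segments <- segments[order(segments$start_frame, segments$marker), , drop = FALSE]
  rownames(segments) <- NULL
  list(wp = data.frame(marker = names(wp), WP = as.integer(wp),
                       stringsAsFactors = FALSE),
       segments = segments)
}
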