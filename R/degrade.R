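#' Degrade ground truth into detector-like predicted tracks
#'
#' Applies the scenario's artifact model to true marker positions, emulating
#' the failure modes of a keypoint detector on stall footage: Gaussian
#' localisation jitter on every prediction, dropout runs where a visible
#' marker goes unpredicted for several consecutive frames (poor lighting,
#' people in the stall, blankets), and teleport mislabels where the marker
#' latches onto a static distractor object (waterer, manure pile, shoes) or
#' a uniform random position at least `jump_min_magnitude` pixels from the
#' truth. Markers annotated `not_visible` are never predicted.
#'
#' Every injected event is recorded in an artifact log so downstream QC can
#' be scored against known truth.
#'
#' @param ground_truth data.frame `frame, marker, x, y, visibility` as
#'   produced by [simulate_tracks()]; frames must be contiguous from 1.
#' @param artifacts An [artifact_spec()].
#' @param geometry A [stall_geometry()] supplying the image rectangle and
#'   distractor positions.
#' @param seed Integer seed for the degradation stream (independent of the
#'   simulation stream so the same truth can be degraded many ways).
#'
#' @return A list with
#'   \describe{
#'     \item{tracks}{named list of [marker_track()] data.frames, one per marker.}
#'     \item{artifact_log}{data.frame `frame, marker, type, run_length,
#'       magnitude_px, x_true, y_true, x_pred, y_pred` with one row per
#'       dropout run and per teleport.}
#'   }
#' @examples
#' sc <- build_scenario(n_frames = 400, seed = 3)
#' sim <- simulate_tracks(sc)
#' deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry, seed = 4)
#' table(deg$artifact_log$type)
#' @export
degrade_to_predictions <- function(ground_truth, artifacts, geometry, seed = 1) {
  stopifnot(inherits(artifacts, "artifact_spec"), inherits(geometry, "stall_geometry"))
  frames <- sort(unique(ground_truth$frame))
  if (length(frames) == 0) stop_st("ground truth is empty")
  if (!identical(frames, seq(frames[1], frames[length(frames)]))) {
    stop_st("ground truth frames must be contiguous")
  }
  diag_px <- sqrt(geometry$width_px^2 + geometry$height_px^2)
  if (artifacts$jump_min_magnitude > diag_px) {
    stop_st("jump_min_magnitude (%.0f px) exceeds the image diagonal (%.0f px)",
            artifacts$jump_min_magnitude, diag_px)
  }
  set.seed(seed)
  log_rows <- list()
  tracks <- list()
  for (m in markers()) {
    gt_m <- ground_truth[ground_truth$marker == m, ]
    gt_m <- gt_m[order(gt_m$frame), ]
    n <- nrow(gt_m)
    has_pos <- !is.na(gt_m$x) & !is.na(gt_m$y)
    predicted <- has_pos
    x <- gt_m$x; y <- gt_m$y

    ## jitter on all predicted positions
    if (artifacts$noise_sigma > 0) {
      x[predicted] <- x[predicted] + stats::rnorm(sum(predicted), 0, artifacts$noise_sigma)
      y[predicted] <- y[predicted] + stats::rnorm(sum(predicted), 0, artifacts$noise_sigma)
    }

    ## dropout runs
    rl <- artifacts$dropout_run_length
    mean_len <- if (identical(rl$type, "fixed")) rl$length else rl$mean %||% 5
    if (artifacts$dropout_rate > 0 && mean_len > 0) {
      start_p <- min(1, artifacts$dropout_rate / mean_len)
      starts <- which(stats::runif(n) < start_p & predicted)
      for (s in starts) {
        len <- if (identical(rl$type, "fixed")) rl$length
               else 1 + stats::rgeom(1, 1 / mean_len)
        idx <- s:min(s + len - 1, n)
        idx <- idx[predicted[idx]]
        if (!length(idx)) next
        predicted[idx] <- FALSE
        log_rows[[length(log_rows) + 1]] <- data.frame(
          frame = gt_m$frame[idx[1]], marker = m, type = "dropout",
          run_length = length(idx), magnitude_px = NA_real_,
          x_true = NA_real_, y_true = NA_real_,
          x_pred = NA_real_, y_pred = NA_real_, stringsAsFactors = FALSE)
      }
    }

    ## teleport mislabels, at isolated frames where the true position exists
    n_jumps <- if (!is.null(artifacts$jump_count)) artifacts$jump_count
               else stats::rpois(1, artifacts$jump_rate * n / 1000)
    if (n_jumps > 0) {
      candidates <- which(predicted & has_pos)
      jump_at <- pick_spaced(candidates, n_jumps, min_gap = 3)
      for (j in jump_at) {
        tgt <- jump_target_point(gt_m$x[j], gt_m$y[j], artifacts, geometry)
        if (is.null(tgt)) next
        mag <- euclid(gt_m$x[j], gt_m$y[j], tgt[1], tgt[2])
        log_rows[[length(log_rows) + 1]] <- data.frame(
          frame = gt_m$frame[j], marker = m, type = "jump",
          run_length = 1L, magnitude_px = mag,
          x_true = gt_m$x[j], y_true = gt_m$y[j],
          x_pred = tgt[1], y_pred = tgt[2], stringsAsFactors = FALSE)
        x[j] <- tgt[1]; y[j] <- tgt[2]
      }
    }

    x[!predicted] <- NA_real_
    y[!predicted] <- NA_real_
    x[predicted] <- clamp(x[predicted], 0, geometry$width_px)
    y[predicted] <- clamp(y[predicted], 0, geometry$height_px)
    tracks[[m]] <- marker_track(frame = gt_m$frame, x = x, y = y,
                                predicted = predicted, marker = m,
                                width_px = geometry$width_px,
                                height_px = geometry$height_px)
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows)
         else data.frame(frame = integer(), marker = character(),
                         type = character(), run_length = integer(),
                         magnitude_px = double(), x_true = double(),
                         y_true = double(), x_pred = double(),
                         y_pred = double(), stringsAsFactors = FALSE)
  log <- log[order(log$frame, log$marker), , drop = FALSE]
  rownames(log) <- NULL
  list(tracks = tracks, artifact_log = log)
}

#' Write / read an artifact log as JSON
#'
#' The artifact log of [degrade_to_predictions()] round-trips through a
#' plain JSON array of row objects, the interchange format of the
#' simulation bundles.
#'
#' @param artifact_log data.frame as returned by [degrade_to_predictions()].
#' @param path File path.
#' @return `write_artifact_log_json` returns `path` invisibly;
#'   `read_artifact_log_json` returns the data.frame.
#' @export
write_artifact_log_json <- function(artifact_log, path) {
  jsonlite::write_json(artifact_log, path, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_artifact_log_json
#' @export
read_artifact_log_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# choose k indices from candidates with pairwise spacing >= min_gap;
# teleports are isolated single-frame events
pick_spaced <- function(candidates, k, min_gap = 3) {
  if (!length(candidates) || k == 0) return(integer())
  chosen <- integer()
  pool <- candidates
  while (length(chosen) < k && length(pool)) {
    pick <- pool[ceiling(stats::runif(1) * length(pool))]
    chosen <- c(chosen, pick)
    pool <- pool[abs(pool - pick) >= min_gap]
  }
  sort(chosen)
}

# a teleport target at least jump_min_magnitude px from the true position
jump_target_point <- function(x0, y0, artifacts, geometry) {
  minmag <- artifacts$jump_min_magnitude
  if (artifacts$jump_target == "distractor" && length(geometry$distractors)) {
    pts <- do.call(rbind, geometry$distractors)
    far <- which(euclid(x0, y0, pts[, 1], pts[, 2]) >= minmag + 25)
    if (length(far)) {
      d <- pts[far[ceiling(stats::runif(1) * length(far))], ]
      cand <- clamp(d + stats::rnorm(2, 0, 5), c(0, 0),
                    c(geometry$width_px, geometry$height_px))
      if (euclid(x0, y0, cand[1], cand[2]) >= minmag) return(cand)
    }
  }
  for (i in 1:200) {
    cand <- c(stats::runif(1, 0, geometry$width_px),
              stats::runif(1, 0, geometry$height_px))
    if (euclid(x0, y0, cand[1], cand[2]) >= minmag) return(cand)
  }
  NULL
}
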