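#' Rule-based behaviour classification from marker tracks
#'
#' Assigns one of the four ethogram classes to every frame with a fixed rule
#' cascade evaluated on smoothed marker kinematics:
#' \enumerate{
#'   \item \strong{moving} — smoothed per-frame displacement of the withers
#'     exceeds `move_threshold`;
#'   \item else \strong{feeding} — the nose is low in the image, below the
#'     horizontal `feeding_line` (y larger than the line; image y points down);
#'   \item else \strong{rest} — the rolling mean nose displacement stays
#'     under `rest_threshold` for at least `rest_min_frames` consecutive
#'     frames;
#'   \item else \strong{standing_observation}.
#' }
#' Positions are lightly smoothed before differencing to suppress detector
#' jitter; per-frame displacement across prediction gaps is the gap-averaged
#' rate. Finally, segments shorter than `min_segment_frames` are merged into
#' the preceding segment (the earlier-assigned class wins ties), which
#' removes single-frame blips caused by teleport mislabels.
#'
#' Thresholds are configuration with synthetic-calibrated defaults; they are
#' in pixels of 2.7K footage per time-lapse frame and should be rescaled for
#' other resolutions or frame rates.
#'
#' @param tracks Named list of [marker_track()] objects with at least `nose`
#'   and `withers`; the nose must be predicted on at least half the frames.
#' @param move_threshold Withers speed (px/frame) above which the frame is
#'   moving (default 12).
#' @param feeding_line Image y-coordinate of the feeding zone boundary
#'   (default 1000 at 1520-px height).
#' @param rest_threshold Rolling mean nose speed (px/frame) below which
#'   sustained frames are rest (default 5).
#' @param rest_min_frames Minimum consecutive low-motion frames for rest
#'   (default 30, i.e. 15 s at 2 img/s).
#' @param smooth_window Position-smoothing window in frames (default 5).
#' @param min_segment_frames Minimum surviving segment length (default 10).
#' @return data.frame `frame, behaviour` covering frames 1..max(frame).
#' @export
classify_behaviour <- function(tracks,
                               move_threshold = 12,
                               feeding_line = 1000,
                               rest_threshold = 5,
                               rest_min_frames = 30,
                               smooth_window = 5,
                               min_segment_frames = 10) {
  if (!all(c("nose", "withers") %in% names(tracks))) {
    stop_st("tracks must include 'nose' and 'withers'")
  }
  nose <- tracks$nose; withers <- tracks$withers
  n <- max(nose$frame, withers$frame)
  if (sum(nose$predicted) < 0.5 * n) {
    stop_st("nose predicted on %.0f%% of frames; >= 50%% required",
            100 * sum(nose$predicted) / n)
  }
  speed_w <- smoothed_speed(withers, n, smooth_window)
  speed_n <- smoothed_speed(nose, n, smooth_window)
  nose_y <- series_on_grid(nose, "y", n)
  nose_y <- locf(nose_y)

  moving <- !is.na(speed_w) & speed_w > move_threshold
  feeding <- !moving & nose_y > feeding_line
  calm <- roll_mean(speed_n, rest_min_frames, min_n = 2) < rest_threshold
  calm[is.na(calm)] <- FALSE
  runs <- true_runs(calm)
  sustained <- rep(FALSE, n)
  for (i in seq_len(nrow(runs))) {
    if (runs$end[i] - runs$start[i] + 1 >= rest_min_frames) {
      sustained[runs$start[i]:runs$end[i]] <- TRUE
    }
  }
  rest <- !moving & !feeding & sustained
  cls <- ifelse(moving, "moving",
         ifelse(feeding, "feeding",
         ifelse(rest, "rest", "standing_observation")))
  cls <- merge_short_segments(cls, min_segment_frames)
  data.frame(frame = seq_len(n), behaviour = cls, stringsAsFactors = FALSE)
}

# per-frame displacement rate on the full frame grid, from smoothed
# positions of predicted frames; gaps get the gap-averaged rate
smoothed_speed <- function(track, n, smooth_window) {
  pr <- track[track$predicted, , drop = FALSE]
  speed <- rep(NA_real_, n)
  if (nrow(pr) < 2) return(speed)
  sx <- roll_mean(pr$x, smooth_window)
  sy <- roll_mean(pr$y, smooth_window)
  gap <- diff(pr$frame)
  rate <- euclid(sx[-length(sx)], sy[-length(sy)], sx[-1], sy[-1]) / gap
  # assign the rate to every frame covered by the step f_i+1 .. f_{i+1}
  for (i in seq_along(rate)) {
    speed[(pr$frame[i] + 1):pr$frame[i + 1]] <- rate[i]
  }
  speed[pr$frame[1]] <- rate[1]
  speed
}

series_on_grid <- function(track, col, n) {
  out <- rep(NA_real_, n)
  pr <- track[track$predicted, , drop = FALSE]
  out[pr$frame] <- pr[[col]]
  out
}

# merge runs shorter than min_len into the preceding run's label
merge_short_segments <- function(cls, min_len) {
  if (min_len <= 1) return(cls)
  repeat {
    r <- rle(cls)
    if (length(r$lengths) <= 1) return(cls)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(cls)
    i <- short[1]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    cls <- inverse.rle(r)
  }
}
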