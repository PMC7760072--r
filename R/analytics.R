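#' Position heat map of a marker track
#'
#' Counts predicted positions into axis-aligned square bins covering the
#' image rectangle. Bins are half-open `[k*s, (k+1)*s)` so a position on an
#' interior bin boundary goes to the higher-index bin; positions on the far
#' image edge fall into the last bin. Total mass equals the number of
#' predicted frames binned.
#'
#' @param track A [marker_track()].
#' @param bin_size_px Square bin edge length in pixels (default 50).
#' @return Object of class `position_heatmap`: list with `grid` (rows = y
#'   bins, cols = x bins), `bin_size_px`, `total_mass`, `width_px`,
#'   `height_px`.
#' @export
position_heatmap <- function(track, bin_size_px = 50) {
  if (bin_size_px <= 0) stop_st("bin_size_px must be > 0")
  w <- attr(track, "width_px") %||% 2704
  h <- attr(track, "height_px") %||% 1520
  nx <- ceiling(w / bin_size_px)
  ny <- ceiling(h / bin_size_px)
  pr <- track[track$predicted, , drop = FALSE]
  ix <- pmin(floor(pr$x / bin_size_px), nx - 1) + 1
  iy <- pmin(floor(pr$y / bin_size_px), ny - 1) + 1
  grid <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(pr)) {
    tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
    grid <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  structure(list(grid = grid, bin_size_px = bin_size_px,
                 total_mass = nrow(pr), width_px = w, height_px = h),
            class = "position_heatmap")
}

#' @export
print.position_heatmap <- function(x, ...) {
  cat(sprintf("Position heat map: %d x %d bins of %d px, mass %d\n",
              ncol(x$grid), nrow(x$grid), x$bin_size_px, x$total_mass))
  invisible(x)
}

#' Plot a position heat map
#'
#' @param x A [position_heatmap()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.position_heatmap <- function(x, ...) {
  nx <- ncol(x$grid); ny <- nrow(x$grid)
  graphics::image(x = (seq_len(nx) - 0.5) * x$bin_size_px,
                  y = (seq_len(ny) - 0.5) * x$bin_size_px,
                  z = t(x$grid), ylim = c(x$height_px, 0),
                  xlab = "x (px)", ylab = "y (px)",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Time spent in named stall regions
#'
#' Assigns each predicted frame to every region whose polygon contains the
#' point (boundary inclusive); a frame inside no region accrues to the
#' implicit `elsewhere` key, which makes the partition exhaustive when
#' regions do not overlap. Frames counted in more than one region are
#' reported in `overlap_frames`.
#'
#' @param track A [marker_track()].
#' @param regions Named list of polygons, e.g. `stall_geometry()$regions`.
#' @param fps_tlv Time-lapse images per second for the minutes conversion.
#' @return Object of class `time_budget`: data.frame `key, frames, minutes,
#'   percent` plus attributes `n_evaluated` and `overlap_frames`.
#' @export
time_in_region <- function(track, regions, fps_tlv = 2) {
  for (nm in names(regions)) {
    p <- as.matrix(as.data.frame(regions[[nm]]))
    if (polygon_self_intersects(p)) {
      stop_st("region '%s' is self-intersecting", nm)
    }
  }
  pr <- track[track$predicted, , drop = FALSE]
  n <- nrow(pr)
  inside <- vapply(regions, function(p) {
    point_in_polygon(pr$x, pr$y, p)
  }, logical(n))
  if (n == 1) inside <- matrix(inside, nrow = 1, dimnames = list(NULL, names(regions)))
  hits <- if (n) rowSums(inside) else integer()
  frames <- c(colSums(inside), elsewhere = sum(hits == 0))
  budget <- data.frame(
    key = c(names(regions), "elsewhere"),
    frames = as.integer(frames),
    minutes = frames / (fps_tlv * 60),
    percent = if (n) 100 * frames / n else rep(0, length(frames)),
    stringsAsFactors = FALSE)
  structure(budget, n_evaluated = n,
            overlap_frames = if (n) pr$frame[hits > 1] else integer(),
            class = c("time_budget", "data.frame"))
}

#' Align a marker track with behaviour labels
#'
#' Inner join on frame: returns one row per frame present in both inputs,
#' with `NA` coordinates on unpredicted frames.
#'
#' @param track A [marker_track()].
#' @param labels data.frame `frame, behaviour`.
#' @return data.frame `frame, x, y, behaviour`.
#' @export
xy_series_with_behaviour <- function(track, labels) {
  common <- intersect(track$frame, labels$frame)
  if (!length(common)) stop_st("track and labels share no frames")
  common <- sort(common)
  ti <- track[match(common, track$frame), ]
  data.frame(frame = common, x = ti$x, y = ti$y,
             behaviour = labels$behaviour[match(common, labels$frame)],
             stringsAsFactors = FALSE)
}

#' Rolling positional variance of one coordinate
#'
#' Centred rolling sample variance of the x or y coordinate over a window
#' of frames, computed from predicted frames only. Frames supported by
#' fewer than `window_frames / 2` predicted values are `NA`. Elevated
#' short-window y-variance during rest is the weight-shifting signature.
#'
#' @param track A [marker_track()].
#' @param axis `"x"` or `"y"`.
#' @param window_frames Window length in frames (>= 2).
#' @return data.frame `frame, variance` over the track's frame range.
#' @export
rolling_dispersion <- function(track, axis = c("y", "x"), window_frames = 60) {
  axis <- match.arg(axis)
  if (window_frames < 2) stop_st("window_frames must be >= 2")
  rng <- range(track$frame)
  frames <- seq(rng[1], rng[2])
  v <- rep(NA_real_, length(frames))
  idx <- match(track$frame[track$predicted], frames)
  v[idx] <- track[[axis]][track$predicted]
  data.frame(frame = frames,
             variance = roll_var(v, window_frames,
                                 min_n = max(2, floor(window_frames / 2))))
}

#' Flag rest segments with elevated vertical variance (weight shifting)
#'
#' Scores each maximal rest segment by the mean rolling variance of the
#' marker's y-coordinate, computed over rest frames only (frames in other
#' behaviours are masked out, so walking into or out of a rest bout does not
#' inflate the segment), and flags segments whose ratio over a baseline
#' exceeds `variance_ratio_threshold`.
#'
#' Baselines: `"noise_floor"` (default) estimates the frame-to-frame noise
#' variance of the rest y-signal as `var(diff(y)) / 2` over adjacent rest
#' frames — a high-frequency floor that tracks localisation jitter but is
#' blind to the slow weight-shifting oscillation, so the ratio is close to
#' 1 for quiet rest and large when the horse sways; `"rest_median"` uses
#' the median rolling y-variance over all rest frames, which contrasts one
#' restless bout against the horse's other rest periods but cannot flag a
#' uniformly restless recording; `"absolute"` compares against
#' `absolute_baseline` squared pixels directly.
#'
#' @param track A [marker_track()] (normally the nose).
#' @param labels data.frame `frame, behaviour` covering the track's frames.
#' @param window_frames Rolling-variance window (default 60 frames = 30 s
#'   at 2 img/s).
#' @param variance_ratio_threshold Flag when segment mean variance exceeds
#'   this multiple of the baseline (default 3: quiet-rest ratios concentrate near 1, genuine weight shifting sits an order of magnitude higher).
#' @param baseline `"noise_floor"`, `"rest_median"` or `"absolute"`.
#' @param absolute_baseline Baseline in squared pixels for
#'   `baseline = "absolute"`, and the fallback floor when an estimated
#'   baseline degenerates to zero.
#' @param settle_frames Frames trimmed from the start of each rest bout
#'   before scoring (default = `window_frames`): the walk to the resting
#'   spot is part of the bout but not of resting posture.
#' @return data.frame `start_frame, end_frame, mean_variance, baseline,
#'   ratio, flagged`; zero rows (with a message) when there are no rest
#'   frames.
#' @export
detect_weight_shifting <- function(track, labels, window_frames = 60,
                                   variance_ratio_threshold = 3,
                                   baseline = c("noise_floor", "rest_median", "absolute"),
                                   absolute_baseline = 25,
                                   settle_frames = window_frames) {
  baseline <- match.arg(baseline)
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      mean_variance = double(), baseline = double(),
                      ratio = double(), flagged = logical())
  rng <- range(track$frame)
  frames <- seq(rng[1], rng[2])
  y <- rep(NA_real_, length(frames))
  idx <- match(track$frame[track$predicted], frames)
  y[idx] <- track$y[track$predicted]
  beh <- labels$behaviour[match(frames, labels$frame)]
  rest <- !is.na(beh) & beh == "rest"
  if (!any(rest)) {
    message("no rest frames in labels; nothing to flag")
    return(empty)
  }
  runs <- true_runs(rest)
  settled <- rest
  for (i in seq_len(nrow(runs))) {
    trim_end <- min(runs$start[i] + settle_frames - 1, runs$end[i])
    settled[runs$start[i]:trim_end] <- FALSE
  }
  y_rest <- ifelse(settled, y, NA_real_)
  rv <- roll_var(y_rest, window_frames, min_n = max(2, floor(window_frames / 2)))
  base_val <- switch(baseline,
    noise_floor = {
      d <- diff(y_rest)
      d <- d[!is.na(d)]
      # robust sd via MAD: blind to residual transit outliers
      stats::mad(d)^2 / 2
    },
    rest_median = stats::median(rv[settled], na.rm = TRUE),
    absolute = absolute_baseline)
  if (!is.finite(base_val) || base_val <= 0) base_val <- absolute_baseline
  segs <- lapply(seq_len(nrow(runs)), function(i) {
    sel <- runs$start[i]:runs$end[i]
    mv <- mean(rv[sel], na.rm = TRUE)
    data.frame(start_frame = frames[runs$start[i]],
               end_frame = frames[runs$end[i]],
               mean_variance = mv, baseline = base_val,
               ratio = mv / base_val,
               flagged = is.finite(mv) && mv / base_val > variance_ratio_threshold)
  })
  do.call(rbind, segs)
}

#' Behaviour time budget
#'
#' Frames, minutes and percent of evaluated frames per ethogram class.
#' Classes absent from the labels get zero rows; percents sum to 100.
#'
#' @param labels data.frame `frame, behaviour` (non-empty).
#' @param fps_tlv Time-lapse images per second.
#' @return A `time_budget` data.frame `key, frames, minutes, percent`.
#' @examples
#' lab <- data.frame(frame = 1:480, behaviour = "feeding")
#' behaviour_time_budget(lab, fps_tlv = 2)  # 4 minutes feeding, 100%
#' @export
behaviour_time_budget <- function(labels, fps_tlv = 2) {
  if (!nrow(labels)) stop_st("labels are empty")
  unknown <- setdiff(unique(labels$behaviour), ethogram_classes())
  if (length(unknown)) stop_st("unknown behaviour class '%s'", unknown[1])
  n <- nrow(labels)
  frames <- table(factor(labels$behaviour, levels = ethogram_classes()))
  budget <- data.frame(key = ethogram_classes(),
                       frames = as.integer(frames),
                       minutes = as.numeric(frames) / (fps_tlv * 60),
                       percent = 100 * as.numeric(frames) / n,
                       stringsAsFactors = FALSE)
  structure(budget, n_evaluated = n, overlap_frames = integer(),
            class = c("time_budget", "data.frame"))
}
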