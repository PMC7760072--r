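#' Video metadata
#'
#' Minimal description of one time-lapse video: its identifier, total image
#' count (TI), nominal images per second, and frame size.
#'
#' @param video_id Character identifier.
#' @param n_frames Total number of images (TI) in the video.
#' @param fps_tlv Time-lapse images per second; default 2.
#' @param width_px,height_px Frame size in pixels.
#' @return An object of class `video_meta`.
#' @export
video_meta <- function(video_id, n_frames, fps_tlv = 2,
                       width_px = 2704, height_px = 1520) {
  if (n_frames <= 0 || n_frames != round(n_frames)) stop_st("n_frames must be a positive integer")
  if (fps_tlv <= 0) stop_st("fps_tlv must be > 0")
  structure(list(video_id = as.character(video_id), n_frames = as.integer(n_frames),
                 fps_tlv = fps_tlv, width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "video_meta")
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("Video %s: %d images at %g img/s, %d x %d px\n",
              x$video_id, x$n_frames, x$fps_tlv, x$width_px, x$height_px))
  invisible(x)
}

#' Marker track container
#'
#' A frame-indexed track of one anatomical keypoint: pixel positions per
#' frame plus a per-frame `predicted` flag. Unpredicted frames carry `NA`
#' coordinates. Frames must be unique and strictly increasing.
#'
#' @param frame Integer frame indices (1-based).
#' @param x,y Pixel coordinates (`NA` where unpredicted).
#' @param predicted Logical per frame.
#' @param marker One of `nose`, `withers`, `tail` (other names allowed but
#'   flagged by downstream marker-specific operations).
#' @param width_px,height_px Image bounds used to validate coordinates.
#' @return A data.frame of class `marker_track` with attributes `marker`,
#'   `width_px`, `height_px`.
#' @export
marker_track <- function(frame, x, y, predicted = !is.na(x) & !is.na(y),
                         marker = "nose", width_px = 2704, height_px = 1520) {
  frame <- as.integer(frame)
  if (anyDuplicated(frame)) stop_st("duplicate frame indices in marker track")
  o <- order(frame)
  frame <- frame[o]; x <- as.numeric(x)[o]; y <- as.numeric(y)[o]
  predicted <- as.logical(predicted)[o]
  bad <- predicted & (is.na(x) | is.na(y))
  if (any(bad)) stop_st("predicted frame %d has missing coordinates", frame[which(bad)[1]])
  oob <- predicted & (x < 0 | x > width_px | y < 0 | y > height_px)
  if (any(oob)) {
    stop_st("frame %d position (%.1f, %.1f) outside the %d x %d image",
            frame[which(oob)[1]], x[which(oob)[1]], y[which(oob)[1]],
            width_px, height_px)
  }
  structure(data.frame(frame = frame, x = x, y = y, predicted = predicted),
            marker = marker, width_px = width_px, height_px = height_px,
            class = c("marker_track", "data.frame"))
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("Marker track '%s': %d frames, %d predicted (%.1f%%)\n",
              attr(x, "marker"), nrow(x), sum(x$predicted),
              100 * mean(x$predicted)))
  invisible(x)
}

track_csv_columns <- c("frame", "marker", "x", "y", "predicted")

# read a CSV skipping '#' comment lines, with located parse errors
read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_st("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(body)
  if (!length(line_no)) {
    return(list(df = NULL, line_no = integer()))
  }
  df <- tryCatch(
    utils::read.csv(text = lines[body], stringsAsFactors = FALSE,
                    colClasses = NA),
    error = function(e) stop_st("malformed CSV in %s: %s", path, conditionMessage(e))
  )
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop_st("%s: missing required column(s) %s", path,
            paste(missing_cols, collapse = ", "))
  }
  list(df = df, line_no = line_no[-1])  # data line numbers, header dropped
}

#' Read a marker-track CSV
#'
#' Reads the package's track dialect (`frame,marker,x,y,predicted`; UTF-8,
#' comma separated, `.` decimal; `#`-prefixed comment lines ignored) into
#' one [marker_track()] per marker. Rows with empty coordinates become
#' unpredicted frames. Metadata comes from a YAML sidecar `<path>.yaml` when
#' present, else is inferred from the data.
#'
#' @param path CSV file path.
#' @param meta Optional [video_meta()] overriding the sidecar.
#' @return List with `tracks` (named list of [marker_track()]) and `meta`.
#' @export
read_track_csv <- function(path, meta = NULL) {
  parsed <- read_table_checked(path, track_csv_columns)
  df <- parsed$df
  if (is.null(meta)) {
    sidecar <- paste0(path, ".yaml")
    meta <- if (file.exists(sidecar)) do.call(video_meta, yaml::read_yaml(sidecar))
  }
  if (is.null(df) || nrow(df) == 0) {
    meta <- meta %||% video_meta("unknown", 1)
    return(list(tracks = list(), meta = meta))
  }
  for (col in c("frame", "x", "y")) {
    vals <- df[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(num))
    if (length(bad)) {
      stop_st("%s line %d: non-numeric value '%s' in column %s",
              path, parsed$line_no[bad[1]], vals[bad[1]], col)
    }
    df[[col]] <- num
  }
  dup <- duplicated(df[c("frame", "marker")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_st("%s line %d: duplicate (frame=%d, marker=%s)",
            path, parsed$line_no[i], df$frame[i], df$marker[i])
  }
  if (is.null(meta)) {
    meta <- video_meta(video_id = basename(path), n_frames = max(df$frame),
                       width_px = max(2704, ceiling(max(df$x, na.rm = TRUE))),
                       height_px = max(1520, ceiling(max(df$y, na.rm = TRUE))))
  }
  pred <- if (is.logical(df$predicted)) df$predicted
          else tolower(as.character(df$predicted)) %in% c("true", "1", "t")
  pred <- pred & !is.na(df$x) & !is.na(df$y)
  tracks <- lapply(split(seq_len(nrow(df)), df$marker), function(i) {
    marker_track(frame = df$frame[i], x = df$x[i], y = df$y[i],
                 predicted = pred[i], marker = df$marker[i][1],
                 width_px = meta$width_px, height_px = meta$height_px)
  })
  list(tracks = tracks, meta = meta)
}

#' Write marker tracks to CSV
#'
#' Deterministic output: rows ordered frame-major then marker alphabetical,
#' coordinates rendered with fixed 3-decimal precision, unpredicted frames
#' written with empty coordinate fields. Metadata goes to a YAML sidecar
#' `<path>.yaml`; optional `header_comments` are written as `#` lines.
#'
#' @param tracks Named list of [marker_track()] objects.
#' @param meta A [video_meta()].
#' @param path Output CSV path.
#' @param header_comments Character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(tracks, meta, path, header_comments = NULL) {
  nms <- if (length(tracks)) sort(names(tracks)) else character()
  rows <- lapply(nms, function(m) {
    tr <- tracks[[m]]
    data.frame(frame = tr$frame, marker = m,
               x = ifelse(tr$predicted, sprintf("%.3f", tr$x), ""),
               y = ifelse(tr$predicted, sprintf("%.3f", tr$y), ""),
               predicted = ifelse(tr$predicted, "true", "false"),
               stringsAsFactors = FALSE)
  })
  all_rows <- if (length(rows)) do.call(rbind, rows)
              else data.frame(frame = integer(), marker = character(),
                              x = character(), y = character(),
                              predicted = character())
  all_rows <- all_rows[order(all_rows$frame, all_rows$marker), , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste("#", header_comments), con)
  writeLines(paste(track_csv_columns, collapse = ","), con)
  if (nrow(all_rows)) {
    writeLines(do.call(paste, c(unname(as.list(all_rows)), sep = ",")), con)
  }
  yaml::write_yaml(unclass(meta), paste0(path, ".yaml"))
  invisible(path)
}

#' Read / write ground-truth annotation CSV
#'
#' Dialect `frame,marker,x,y,visibility` with the five visibility classes
#' of [visibility_classes()]; `not_visible` rows have empty coordinates.
#'
#' @param path CSV file path.
#' @return `read_ground_truth_csv`: data.frame `frame, marker, x, y, visibility`.
#' @export
read_ground_truth_csv <- function(path) {
  parsed <- read_table_checked(path, c("frame", "marker", "x", "y", "visibility"))
  df <- parsed$df
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(frame = integer(), marker = character(), x = double(),
                      y = double(), visibility = character()))
  }
  bad <- which(!df$visibility %in% visibility_classes())
  if (length(bad)) {
    stop_st("%s line %d: unknown visibility '%s' (permitted: %s)",
            path, parsed$line_no[bad[1]], df$visibility[bad[1]],
            paste(visibility_classes(), collapse = ", "))
  }
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  has_pos <- !is.na(df$x) & !is.na(df$y)
  inconsistent <- which(has_pos == (df$visibility == "not_visible"))
  if (length(inconsistent)) {
    stop_st("%s line %d: position must be present iff visibility != not_visible",
            path, parsed$line_no[inconsistent[1]])
  }
  df[order(df$frame, df$marker), , drop = FALSE]
}

#' @rdname read_ground_truth_csv
#' @param ground_truth data.frame `frame, marker, x, y, visibility`.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  gt <- ground_truth[order(ground_truth$frame, ground_truth$marker), ]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("frame,marker,x,y,visibility", con)
  writeLines(paste(gt$frame, gt$marker,
                   ifelse(is.na(gt$x), "", sprintf("%.3f", gt$x)),
                   ifelse(is.na(gt$y), "", sprintf("%.3f", gt$y)),
                   gt$visibility, sep = ","), con)
  invisible(path)
}

#' Read / write behaviour-label CSV
#'
#' Dialect `frame,behaviour`. Behaviour may be given as class names or as
#' the conventional integer codes 1-4 in ethogram order (1 standing
#' observation, 2 rest, 3 feeding, 4 moving). Unknown classes are rejected
#' with the permitted vocabulary in the message.
#'
#' @param path CSV file path.
#' @return `read_behaviour_csv`: data.frame `frame, behaviour`.
#' @export
read_behaviour_csv <- function(path) {
  parsed <- read_table_checked(path, c("frame", "behaviour"))
  df <- parsed$df
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(frame = integer(), behaviour = character()))
  }
  beh <- as.character(df$behaviour)
  codes <- suppressWarnings(as.integer(beh))
  is_code <- !is.na(codes)
  out <- character(length(beh))
  bad_code <- is_code & (codes < 1 | codes > 4)
  out[is_code & !bad_code] <- ethogram_classes()[codes[is_code & !bad_code]]
  out[!is_code] <- beh[!is_code]
  bad <- which(bad_code | (!is_code & !beh %in% ethogram_classes()))
  if (length(bad)) {
    stop_st("%s line %d: unknown behaviour '%s' (permitted: %s or codes 1-4)",
            path, parsed$line_no[bad[1]], beh[bad[1]],
            paste(ethogram_classes(), collapse = ", "))
  }
  if (anyDuplicated(df$frame)) {
    i <- which(duplicated(df$frame))[1]
    stop_st("%s line %d: duplicate frame %d", path, parsed$line_no[i], df$frame[i])
  }
  res <- data.frame(frame = as.integer(df$frame), behaviour = out,
                    stringsAsFactors = FALSE)
  res[order(res$frame), , drop = FALSE]
}

#' @rdname read_behaviour_csv
#' @param labels data.frame `frame, behaviour`.
#' @export
write_behaviour_csv <- function(labels, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("frame,behaviour", con)
  writeLines(paste(labels$frame, labels$behaviour, sep = ","), con)
  invisible(path)
}

#' Training-frame subsampling rule
#'
#' Selects annotation frames the way the training videos were thinned:
#' every `stride`-th frame among the first `limit` frames. Indices are
#' 1-based multiples of the stride strictly below the limit, so the default
#' stride 10 / limit 2500 yields 10, 20, ..., 2490 — 249 frames on any
#' video with at least 2490 frames.
#'
#' @param n_available Number of frames in the video.
#' @param stride Keep every `stride`-th frame (default 10).
#' @param limit Only consider frames strictly below this index (default 2500).
#' @return Integer vector of selected frame indices (possibly empty).
#' @examples
#' length(subsample_training_frames(3000))  # 249
#' @export
subsample_training_frames <- function(n_available, stride = 10, limit = 2500) {
  if (n_available < 1 || stride < 1 || limit < 1) {
    stop_st("n_available, stride and limit must all be >= 1")
  }
  upper <- min(limit - 1, n_available)
  if (upper < stride) return(integer())
  as.integer(seq.int(stride, upper, by = stride))
}
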