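#' Run the validation workflow end to end
#'
#' Orchestrates simulate -> degrade -> QC -> metrics from a single run
#' configuration and writes a reproducible report bundle: per-video
#' robustness metrics, the QC segment report, confusion/performance metrics
#' for the first/last evaluation windows, and (when a second artifact
#' specification is supplied) the version-comparison statistics. Every
#' output CSV carries a header comment with the seed and a configuration
#' hash; identical configurations rewrite byte-identical bundles.
#'
#' @param config Named list. Either `scenario` (a [build_scenario()] config
#'   list or object) for synthetic runs, or `tracks_csv` +
#'   `ground_truth_csv` paths for file input — exactly one of the two.
#'   Optional elements: `artifacts_b` (second [artifact_spec()] for a
#'   version comparison, synthetic runs only), `n_videos` (number of
#'   simulated videos, default 8), `jump_threshold_px` (200),
#'   `min_missing_run` (30), `match_radius_px` (100), `window` (1000),
#'   `seed`, `out_dir`.
#' @return Invisibly, a list with the computed tables (`per_video`,
#'   `qc_segments`, `confusion`, `comparison`) and `files` written.
#' @export
run_validation <- function(config) {
  cfg <- validate_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  hdr <- c(sprintf("stalltrack validation run, seed %d, config %s", cfg$seed, hash))

  videos <- load_or_simulate_videos(cfg, cfg$artifacts_a)
  per_video <- do.call(rbind, lapply(videos, function(v) {
    per_video_metrics(v$tracks, v$meta, v$ground_truth,
                      cfg$jump_threshold_px, cfg$min_missing_run)
  }))
  segments <- do.call(rbind, lapply(videos, function(v) {
    qc_report(v$tracks, v$ground_truth, cfg$jump_threshold_px,
              cfg$min_missing_run, video_id = v$meta$video_id)$segments
  }))
  confusion <- do.call(rbind, lapply(videos, function(v) {
    if (is.null(v$ground_truth)) return(NULL)
    do.call(rbind, lapply(names(v$tracks), function(m) {
      do.call(rbind, lapply(c("first", "last"), function(side) {
        win <- evaluation_window(v$meta$n_frames, cfg$window, side)
        cc <- classify_confusion(v$tracks[[m]], v$ground_truth,
                                 cfg$match_radius_px, win,
                                 label = paste0(side, cfg$window))
        pm <- performance_metrics(cc)
        data.frame(video_id = v$meta$video_id, marker = m, window = cc$window,
                   TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
                   sensitivity = pm$sensitivity, error_rate = pm$error_rate,
                   accuracy = pm$accuracy, stringsAsFactors = FALSE)
      }))
    }))
  }))
  comparison <- NULL
  if (!is.null(cfg$artifacts_b)) {
    videos_b <- load_or_simulate_videos(cfg, cfg$artifacts_b)
    per_video_b <- do.call(rbind, lapply(videos_b, function(v) {
      per_video_metrics(v$tracks, v$meta, v$ground_truth,
                        cfg$jump_threshold_px, cfg$min_missing_run)
    }))
    comparison <- compare_versions(per_video, per_video_b)
    write_report_csv(per_video_b, file.path(out_dir, "per_video_metrics_b.csv"), hdr)
    write_report_csv(comparison, file.path(out_dir, "version_comparison.csv"), hdr)
  }
  write_report_csv(per_video, file.path(out_dir, "per_video_metrics.csv"), hdr)
  write_report_csv(segments, file.path(out_dir, "qc_segments.csv"), hdr)
  if (!is.null(confusion)) {
    write_report_csv(confusion, file.path(out_dir, "confusion_metrics.csv"), hdr)
  }
  log_lines <- c(hdr,
                 sprintf("videos: %d", length(videos)),
                 sprintf("qc segments: %d", nrow(segments)),
                 sprintf("thresholds: jump %g px, missing run %d, match radius %g px",
                         cfg$jump_threshold_px, cfg$min_missing_run, cfg$match_radius_px))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(per_video = per_video, qc_segments = segments,
                 confusion = confusion, comparison = comparison,
                 files = list.files(out_dir, full.names = TRUE)))
}

#' Run the case-study analytics workflow
#'
#' Produces the behaviour case-study bundle for one track set: position
#' scatter export, heat-map grid, time-in-region budget, the aligned x/y +
#' behaviour series, weight-shifting flags, and the behaviour time budget.
#' When no behaviour labels are supplied, labels are derived with
#' [classify_behaviour()] and the provenance is recorded in the outputs.
#'
#' @param config Named list: `scenario` (config list or object) or
#'   `tracks_csv` (+ optional `behaviour_csv`); optional `bin_size_px` (50),
#'   `window_frames` (60), `variance_ratio_threshold` (3), `behaviour_params`
#'   (list passed to [classify_behaviour()]), `seed`, `out_dir`.
#' @return Invisibly, a list with `heatmap`, `region_budget`, `series`,
#'   `weight_shift`, `behaviour_budget`, `labels_provenance`, `files`.
#' @export
run_case_study <- function(config) {
  cfg <- validate_run_config(config, case_study = TRUE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])

  if (!is.null(cfg$scenario)) {
    sc <- as_scenario(cfg$scenario, cfg$seed)
    sim <- simulate_tracks(sc)
    deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry,
                                  seed = sc$seed + 1)
    tracks <- deg$tracks
    meta <- sim$meta
    labels <- sim$labels
    provenance <- "generator"
    regions <- sc$geometry$regions
  } else {
    inp <- read_track_csv(cfg$tracks_csv)
    tracks <- inp$tracks
    meta <- inp$meta
    regions <- cfg$regions %||% default_regions(meta$width_px, meta$height_px)
    if (!is.null(cfg$behaviour_csv)) {
      labels <- read_behaviour_csv(cfg$behaviour_csv)
      provenance <- "scored"
    } else {
      labels <- do.call(classify_behaviour,
                        c(list(tracks), cfg$behaviour_params %||% list()))
      provenance <- "classifier"
    }
  }
  hdr <- c(sprintf("stalltrack case study, seed %d, config %s", cfg$seed, hash),
           sprintf("behaviour labels: %s", provenance))

  # strike teleport mislabels before any analytics
  nose <- remove_flagged_jumps(tracks$nose, cfg$jump_threshold_px)
  hm <- position_heatmap(nose, cfg$bin_size_px)
  region_budget <- time_in_region(nose, regions, meta$fps_tlv)
  series <- xy_series_with_behaviour(nose, labels)
  ws <- detect_weight_shifting(nose, labels, cfg$window_frames,
                               cfg$variance_ratio_threshold)
  beh_budget <- behaviour_time_budget(labels, meta$fps_tlv)

  scatter <- nose[nose$predicted, c("frame", "x", "y")]
  write_report_csv(scatter, file.path(out_dir, "position_scatter.csv"), hdr)
  grid_df <- as.data.frame(hm$grid)
  names(grid_df) <- sprintf("x%d", seq_len(ncol(grid_df)))
  write_report_csv(grid_df, file.path(out_dir, "heatmap_grid.csv"), hdr)
  write_report_csv(as.data.frame(region_budget),
                   file.path(out_dir, "time_in_region.csv"), hdr)
  write_report_csv(series, file.path(out_dir, "xy_behaviour_series.csv"), hdr)
  write_report_csv(ws, file.path(out_dir, "weight_shift_flags.csv"), hdr)
  write_report_csv(as.data.frame(beh_budget),
                   file.path(out_dir, "behaviour_time_budget.csv"), hdr)
  invisible(list(heatmap = hm, region_budget = region_budget, series = series,
                 weight_shift = ws, behaviour_budget = beh_budget,
                 labels_provenance = provenance,
                 files = list.files(out_dir, full.names = TRUE)))
}

validate_run_config <- function(config, case_study = FALSE) {
  if (!is.list(config)) stop_st("config must be a list")
  has_scenario <- !is.null(config$scenario)
  has_files <- !is.null(config$tracks_csv)
  if (has_scenario == has_files) {
    stop_st("supply exactly one of 'scenario' or 'tracks_csv' in the config")
  }
  if (has_files && !file.exists(config$tracks_csv)) {
    stop_st("input not found: %s", config$tracks_csv)
  }
  if (has_files && !is.null(config$ground_truth_csv) &&
      !file.exists(config$ground_truth_csv)) {
    stop_st("input not found: %s", config$ground_truth_csv)
  }
  defaults <- list(seed = 1, out_dir = file.path(tempdir(), "stalltrack-run"),
                   jump_threshold_px = 200, min_missing_run = 30,
                   match_radius_px = 100, window = 1000, n_videos = 8,
                   bin_size_px = 50, window_frames = 60,
                   variance_ratio_threshold = 3)
  cfg <- utils::modifyList(defaults, config)
  if (has_scenario && !case_study) {
    sc <- as_scenario(cfg$scenario, cfg$seed)
    cfg$artifacts_a <- sc$artifacts
    if (!is.null(cfg$artifacts_b) && !inherits(cfg$artifacts_b, "artifact_spec")) {
      cfg$artifacts_b <- do.call(artifact_spec, cfg$artifacts_b)
    }
  }
  cfg
}

as_scenario <- function(scenario, seed) {
  if (inherits(scenario, "stall_scenario")) return(scenario)
  build_scenario(config = utils::modifyList(list(seed = seed), scenario))
}

# simulate cfg$n_videos videos (or read the one configured file set)
load_or_simulate_videos <- function(cfg, artifacts) {
  if (!is.null(cfg$scenario)) {
    sc <- as_scenario(cfg$scenario, cfg$seed)
    lapply(seq_len(cfg$n_videos), function(i) {
      sci <- sc
      sci$seed <- sc$seed + (i - 1L)
      sim <- simulate_tracks(sci)
      sim$meta$video_id <- sprintf("sim%02d", i)
      deg <- degrade_to_predictions(sim$ground_truth, artifacts, sc$geometry,
                                    seed = sci$seed + 10000L)
      list(tracks = deg$tracks, ground_truth = sim$ground_truth,
           meta = sim$meta, artifact_log = deg$artifact_log)
    })
  } else {
    inp <- read_track_csv(cfg$tracks_csv)
    gt <- if (!is.null(cfg$ground_truth_csv)) read_ground_truth_csv(cfg$ground_truth_csv)
    list(list(tracks = inp$tracks, ground_truth = gt, meta = inp$meta,
              artifact_log = NULL))
  }
}

evaluation_window <- function(n_frames, width, side = c("first", "last")) {
  side <- match.arg(side)
  width <- min(width, n_frames)
  if (side == "first") seq_len(width) else seq(n_frames - width + 1, n_frames)
}

write_report_csv <- function(df, path, header_comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste("#", header_comments), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
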