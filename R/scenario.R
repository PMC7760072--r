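#' Behaviour model for the synthetic stall scenario
#'
#' A first-order Markov chain over the four ethogram states, plus per-state
#' kinematics driving the simulated marker positions. Displacements are in
#' pixels per time-lapse frame (nominally half a second of real time).
#'
#' Kinematic defaults are synthetic defaults chosen to look like a horse in
#' a 2.7K stall view: slow head scanning while standing, a nearly still head
#' during rest with a sinusoidal vertical weight-shifting oscillation,
#' head-down feeding at the trough, and sustained walking displacement while
#' moving. They are configuration, not measured values.
#'
#' @param transition_matrix 4 x 4 row-stochastic matrix in the state order
#'   of [ethogram_classes()]; rows must sum to 1 within 1e-9.
#' @param mean_step Named numeric: mean displacement of the body (withers)
#'   per frame, by state.
#' @param dispersion Named numeric: per-frame jitter standard deviation of
#'   the nose around its state posture, by state (pixels, >= 0).
#' @param preferred_region Named character: region each non-moving state is
#'   anchored to; must name regions of the scenario's [stall_geometry()].
#' @param rest_y_oscillation_amplitude Amplitude (px) of the vertical nose
#'   oscillation during rest — the weight-shifting signature. 0 disables it.
#' @param rest_y_oscillation_period Oscillation period in frames.
#' @param initial_state Starting state of the chain.
#'
#' @return An object of class `behaviour_model`.
#' @export
behaviour_model <- function(transition_matrix = default_transition_matrix(),
                            mean_step = c(standing_observation = 2, rest = 0.5,
                                          feeding = 2, moving = 25),
                            dispersion = c(standing_observation = 8, rest = 0.5,
                                           feeding = 4, moving = 6),
                            preferred_region = c(standing_observation = "front",
                                                 rest = "sidewall",
                                                 feeding = "feeding",
                                                 moving = NA_character_),
                            rest_y_oscillation_amplitude = 25,
                            rest_y_oscillation_period = 60,
                            initial_state = "standing_observation") {
  states <- ethogram_classes()
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(4, 4))) stop_st("transition_matrix must be 4 x 4")
  if (any(tm < 0)) stop_st("transition probabilities must be non-negative")
  rs <- rowSums(tm)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad)) {
    stop_st("transition row %d (%s) does not sum to 1 (sum = %.6f)",
            bad[1], states[bad[1]], rs[bad[1]])
  }
  dimnames(tm) <- list(states, states)
  for (v in list(mean_step, dispersion)) {
    if (!all(states %in% names(v))) stop_st("kinematics must name all four states")
  }
  if (any(dispersion < 0)) stop_st("dispersions must be >= 0")
  if (rest_y_oscillation_amplitude < 0) stop_st("oscillation amplitude must be >= 0")
  if (rest_y_oscillation_period <= 0) stop_st("oscillation period must be > 0")
  initial_state <- match.arg(initial_state, states)
  structure(
    list(states = states, transition_matrix = tm,
         mean_step = mean_step[states], dispersion = dispersion[states],
         preferred_region = preferred_region[states],
         rest_y_oscillation_amplitude = rest_y_oscillation_amplitude,
         rest_y_oscillation_period = rest_y_oscillation_period,
         initial_state = initial_state),
    class = "behaviour_model"
  )
}

#' @rdname behaviour_model
#' @param stay Common self-transition probability of the default chain.
#' @export
default_transition_matrix <- function(stay = 0.998) {
  states <- ethogram_classes()
  off <- (1 - stay) / 3
  tm <- matrix(off, 4, 4, dimnames = list(states, states))
  diag(tm) <- stay
  tm
}

#' Artifact specification for degrading ground truth into predictions
#'
#' Describes the detector failure modes injected on top of the true marker
#' positions: Gaussian localisation jitter, dropout runs (missing
#' predictions), and teleport mislabels that relocate a marker onto a static
#' distractor object or a uniform random image position.
#'
#' @param dropout_rate Marginal probability per frame that a visible marker
#'   goes unpredicted (in `[0, 1]`). Dropouts arrive as runs.
#' @param dropout_run_length List describing the run-length distribution:
#'   `list(type = "geometric", mean = 5)` or `list(type = "fixed", length = n)`.
#' @param jump_rate Expected teleport mislabels per 1000 frames per marker.
#' @param jump_count Optional exact number of teleports per marker,
#'   overriding `jump_rate` (useful for controlled experiments).
#' @param jump_target `"distractor"` (relocate onto a named static object)
#'   or `"uniform"` (anywhere in the image).
#' @param jump_min_magnitude Minimum displacement (px) of an injected
#'   teleport from the true position; default 250.
#' @param occlude_tail_facing_door If `TRUE` (default) the tail marker is
#'   scheduled not visible while the horse faces the door (nose inside the
#'   `front` region).
#' @param occluded_class_rate Probability a visible marker is annotated as
#'   partly occluded (spread uniformly over 25/50/75%); positions remain.
#' @param noise_sigma Standard deviation (px) of Gaussian jitter added to
#'   every predicted position.
#'
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(dropout_rate = 0.05,
                          dropout_run_length = list(type = "geometric", mean = 5),
                          jump_rate = 1,
                          jump_count = NULL,
                          jump_target = c("distractor", "uniform"),
                          jump_min_magnitude = 250,
                          occlude_tail_facing_door = TRUE,
                          occluded_class_rate = 0.03,
                          noise_sigma = 2) {
  jump_target <- match.arg(jump_target)
  if (dropout_rate < 0 || dropout_rate > 1) stop_st("dropout_rate must be in [0, 1]")
  if (occluded_class_rate < 0 || occluded_class_rate > 1) {
    stop_st("occluded_class_rate must be in [0, 1]")
  }
  if (jump_rate < 0) stop_st("jump_rate must be >= 0")
  if (!is.null(jump_count) && (jump_count < 0 || jump_count != round(jump_count))) {
    stop_st("jump_count must be a non-negative integer")
  }
  if (jump_min_magnitude <= 0) stop_st("jump_min_magnitude must be > 0")
  if (noise_sigma < 0) stop_st("noise_sigma must be >= 0")
  type <- dropout_run_length$type %||% "geometric"
  if (!type %in% c("geometric", "fixed")) {
    stop_st("dropout_run_length$type must be 'geometric' or 'fixed'")
  }
  structure(
    list(dropout_rate = dropout_rate, dropout_run_length = dropout_run_length,
         jump_rate = jump_rate, jump_count = jump_count,
         jump_target = jump_target, jump_min_magnitude = jump_min_magnitude,
         occlude_tail_facing_door = occlude_tail_facing_door,
         occluded_class_rate = occluded_class_rate, noise_sigma = noise_sigma),
    class = "artifact_spec"
  )
}

#' Build a validated synthetic stall scenario
#'
#' Assembles geometry, behaviour model and artifact specification into a
#' reproducible scenario. The same scenario and seed always generate
#' bit-identical tracks, labels and artifact logs.
#'
#' @param config Optional named list overriding any of the arguments below
#'   (flat keys `n_frames`, `fps_tlv`, `seed`, plus `geometry`, `behaviour`,
#'   `artifacts` sublists passed to the respective constructors). A YAML file
#'   read with [yaml::read_yaml()] deparses to exactly this shape.
#' @param geometry A [stall_geometry()].
#' @param behaviour A [behaviour_model()].
#' @param artifacts An [artifact_spec()].
#' @param n_frames Number of time-lapse frames to simulate; default 28800
#'   (4 h at 2 images per second).
#' @param fps_tlv Time-lapse images per second (default 2).
#' @param seed Integer seed for the scenario's single pseudo-random stream.
#'
#' @return An object of class `stall_scenario`.
#' @examples
#' sc <- build_scenario(n_frames = 1000, seed = 1)
#' sc
#' @export
build_scenario <- function(config = NULL,
                           geometry = NULL, behaviour = NULL, artifacts = NULL,
                           n_frames = 28800, fps_tlv = 2, seed = 1) {
  if (!is.null(config)) {
    geometry <- geometry %||% (if (!is.null(config$geometry))
      do.call(stall_geometry, config$geometry))
    behaviour <- behaviour %||% (if (!is.null(config$behaviour))
      do.call(behaviour_model, normalize_behaviour_config(config$behaviour)))
    artifacts <- artifacts %||% (if (!is.null(config$artifacts))
      do.call(artifact_spec, config$artifacts))
    n_frames <- config$n_frames %||% n_frames
    fps_tlv <- config$fps_tlv %||% fps_tlv
    seed <- config$seed %||% seed
  }
  geometry <- geometry %||% stall_geometry()
  behaviour <- behaviour %||% behaviour_model()
  artifacts <- artifacts %||% artifact_spec()
  stopifnot(inherits(geometry, "stall_geometry"),
            inherits(behaviour, "behaviour_model"),
            inherits(artifacts, "artifact_spec"))
  if (n_frames <= 0 || n_frames != round(n_frames)) stop_st("n_frames must be a positive integer")
  if (fps_tlv <= 0) stop_st("fps_tlv must be > 0")
  # cross-validate: every preferred region must exist in the geometry
  pr <- behaviour$preferred_region
  unknown <- setdiff(stats::na.omit(pr), names(geometry$regions))
  if (length(unknown)) {
    stop_st("preferred region '%s' not present in the stall geometry", unknown[1])
  }
  diag_px <- sqrt(geometry$width_px^2 + geometry$height_px^2)
  if (artifacts$jump_min_magnitude > diag_px) {
    stop_st("jump_min_magnitude (%.0f px) exceeds the image diagonal (%.0f px)",
            artifacts$jump_min_magnitude, diag_px)
  }
  structure(
    list(geometry = geometry, behaviour = behaviour, artifacts = artifacts,
         n_frames = as.integer(n_frames), fps_tlv = fps_tlv,
         seed = as.integer(seed)),
    class = "stall_scenario"
  )
}

# yaml configs give transition_matrix as list of rows; coerce to matrix
normalize_behaviour_config <- function(cfg) {
  if (!is.null(cfg$transition_matrix) && is.list(cfg$transition_matrix)) {
    cfg$transition_matrix <- do.call(rbind, lapply(cfg$transition_matrix, unlist))
  }
  for (nm in c("mean_step", "dispersion", "preferred_region")) {
    if (!is.null(cfg[[nm]]) && is.list(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  cfg
}

#' @export
print.stall_scenario <- function(x, ...) {
  hours <- x$n_frames / (x$fps_tlv * 3600)
  cat(sprintf("Synthetic stall scenario: %d frames at %g img/s (%.2f h), seed %d\n",
              x$n_frames, x$fps_tlv, hours, x$seed))
  print(x$geometry)
  cat(sprintf("  states: %s\n", paste(x$behaviour$states, collapse = ", ")))
  cat(sprintf("  artifacts: dropout %.3f, jumps %s/1000 fr (>= %g px, %s), noise sd %g px\n",
              x$artifacts$dropout_rate,
              if (is.null(x$artifacts$jump_count)) format(x$artifacts$jump_rate)
              else sprintf("exactly %d", x$artifacts$jump_count),
              x$artifacts$jump_min_magnitude, x$artifacts$jump_target,
              x$artifacts$noise_sigma))
  invisible(x)
}
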