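#' Simulate ground-truth marker tracks and behaviour labels
#'
#' Draws a per-frame behaviour sequence from the scenario's Markov chain,
#' then integrates nose, withers and tail positions frame by frame. The nose
#' leads: in each non-moving state it is attracted to the centroid of the
#' state's preferred stall region and wanders around it with state-specific
#' dispersion; in the moving state it walks between random waypoints. The
#' withers and tail trail behind the nose along the body heading at roughly
#' fixed body-segment lengths, so nose-withers and withers-tail distances
#' stay within configured bounds. Rest frames add the sinusoidal vertical
#' nose oscillation that emulates weight shifting. All positions are clamped
#' to the image rectangle; frames are indexed from 1.
#'
#' The scenario seed drives a single pseudo-random stream consumed in a
#' fixed order (labels, then positions and visibility); identical scenarios
#' give bit-identical output.
#'
#' @param scenario A [build_scenario()] object.
#' @return A list with elements
#'   \describe{
#'     \item{ground_truth}{data.frame `frame, marker, x, y, visibility`; one
#'       row per frame and marker, `x`/`y` `NA` where `visibility` is
#'       `not_visible`.}
#'     \item{labels}{data.frame `frame, behaviour` over the 4 ethogram classes.}
#'     \item{meta}{A [video_meta()] describing the simulated video.}
#'   }
#' @examples
#' sc <- build_scenario(n_frames = 500, seed = 42)
#' sim <- simulate_tracks(sc)
#' table(sim$labels$behaviour)
#' @export
simulate_tracks <- function(scenario) {
  stopifnot(inherits(scenario, "stall_scenario"))
  geo <- scenario$geometry
  bm <- scenario$behaviour
  n <- scenario$n_frames
  set.seed(scenario$seed)

  ## stage 1: behaviour labels from the Markov chain
  states <- bm$states
  cum <- t(apply(bm$transition_matrix, 1, cumsum))
  lab <- integer(n)
  lab[1] <- match(bm$initial_state, states)
  u <- stats::runif(n)
  for (t in seq_len(n)[-1]) {
    lab[t] <- which(u[t] <= cum[lab[t - 1], ])[1]
  }

  ## stage 2: positions
  anchors <- state_anchors(geo, bm)
  w <- geo$width_px; h <- geo$height_px
  body_nw <- 300 * w / 2704  # nose-withers segment length, px
  body_wt <- 350 * w / 2704  # withers-tail segment length, px
  transit_speed <- 60 * w / 2704
  arrive_radius <- 30 * w / 2704
  rho <- 0.9                  # AR(1) memory of the jittery head wander
  max_sweep <- 150 * w / 2704 # neck-bounded head sweep radius
  standing_idx <- match("standing_observation", states)

  nose <- matrix(NA_real_, n, 2)
  withers <- matrix(NA_real_, n, 2)
  tail <- matrix(NA_real_, n, 2)

  pos <- anchors[[lab[1]]] %||% c(w / 2, h / 2)
  offset <- c(0, 0)
  vel <- c(0, 0)
  heading <- c(-1, -0.3); heading <- heading / sqrt(sum(heading^2))
  waypoint <- random_waypoint(w, h)
  amp <- bm$rest_y_oscillation_amplitude
  per <- bm$rest_y_oscillation_period
  rest_idx <- match("rest", states)
  moving_idx <- match("moving", states)

  for (t in seq_len(n)) {
    s <- lab[t]
    disp <- bm$dispersion[s]
    prev <- pos
    if (s == moving_idx) {
      if (sqrt(sum((pos - waypoint)^2)) < arrive_radius) {
        waypoint <- random_waypoint(w, h)
      }
      dir <- waypoint - pos
      dl <- sqrt(sum(dir^2))
      step <- bm$mean_step[s] * stats::rlnorm(1, 0, 0.2)
      pos <- pos + dir / max(dl, 1) * min(step, dl) + stats::rnorm(2, 0, 1)
      offset <- 0.5 * offset
    } else {
      anchor <- anchors[[s]]
      dir <- anchor - pos
      dl <- sqrt(sum(dir^2))
      if (dl > arrive_radius) {
        # in transit toward the state's preferred region
        pos <- pos + dir / dl * min(transit_speed, dl) + stats::rnorm(2, 0, 1)
        offset <- 0.5 * offset
      } else {
        pos <- anchor
        if (s == standing_idx) {
          # observation = smooth head sweeps: persistent velocity with a
          # weak spring pulling the head back to carriage; dispersion sets
          # the sweep speed scale; the neck bounds the sweep radius
          vel <- 0.9 * vel + stats::rnorm(2, 0, disp * 0.45)
          offset <- 0.98 * offset + vel
          osize <- sqrt(sum(offset^2))
          if (osize > max_sweep) {
            u <- offset / osize
            offset <- u * max_sweep
            vr <- sum(vel * u)
            if (vr > 0) vel <- vel - 2 * vr * u  # reflect: sweep turns back
          }
        } else {
          # jittery wander around the carried head position
          vel <- 0.5 * vel
          offset <- rho * offset + stats::rnorm(2, 0, disp)
        }
      }
    }
    # heading follows body motion when informative, drifts slowly when idle
    delta <- pos - prev
    dn <- sqrt(sum(delta^2))
    if (dn > 3) {
      heading <- 0.8 * heading + 0.2 * delta / dn
    } else {
      ang <- atan2(heading[2], heading[1]) + stats::rnorm(1, 0, 0.005)
      heading <- c(cos(ang), sin(ang))
    }
    heading <- heading / sqrt(sum(heading^2))
    # the anchor point `pos` is the head carriage; nose adds the head
    # wander (plus the rest oscillation), withers and tail trail the body
    p_nose <- pos + offset
    if (s == rest_idx && amp > 0) {
      p_nose[2] <- p_nose[2] + amp * sin(2 * pi * t / per)
    }
    p_nose <- clamp(p_nose, c(0, 0), c(w, h))
    p_w <- clamp(pos - body_nw * heading + stats::rnorm(2, 0, 1), c(0, 0), c(w, h))
    p_t <- clamp(pos - (body_nw + body_wt) * heading + stats::rnorm(2, 0, 1),
                 c(0, 0), c(w, h))
    nose[t, ] <- p_nose; withers[t, ] <- p_w; tail[t, ] <- p_t
  }

  ## stage 3: visibility classes
  vis <- matrix("visible", n, 3, dimnames = list(NULL, markers()))
  art <- scenario$artifacts
  if (isTRUE(art$occlude_tail_facing_door)) {
    facing <- point_in_polygon(nose[, 1], nose[, 2], geo$regions[["front"]])
    vis[facing, "tail"] <- "not_visible"
  }
  if (art$occluded_class_rate > 0) {
    occ_classes <- c("occluded25", "occluded50", "occluded75")
    for (m in markers()) {
      pick <- stats::runif(n) < art$occluded_class_rate & vis[, m] == "visible"
      vis[pick, m] <- occ_classes[ceiling(stats::runif(sum(pick)) * 3)]
    }
  }

  frame <- seq_len(n)
  gt <- data.frame(
    frame = rep(frame, 3),
    marker = rep(markers(), each = n),
    x = c(nose[, 1], withers[, 1], tail[, 1]),
    y = c(nose[, 2], withers[, 2], tail[, 2]),
    visibility = c(vis[, "nose"], vis[, "withers"], vis[, "tail"]),
    stringsAsFactors = FALSE
  )
  hidden <- gt$visibility == "not_visible"
  gt$x[hidden] <- NA_real_
  gt$y[hidden] <- NA_real_

  labels <- data.frame(frame = frame, behaviour = states[lab],
                       stringsAsFactors = FALSE)
  meta <- video_meta(video_id = sprintf("synthetic-seed%d", scenario$seed),
                     n_frames = n, fps_tlv = scenario$fps_tlv,
                     width_px = w, height_px = h)
  list(ground_truth = gt, labels = labels, meta = meta)
}

# centroid anchor of each state's preferred region (moving has none)
state_anchors <- function(geo, bm) {
  lapply(seq_along(bm$states), function(i) {
    rg <- bm$preferred_region[i]
    if (is.na(rg)) return(NULL)
    p <- geo$regions[[rg]]
    c(mean(p[, 1]), mean(p[, 2]))
  })
}

random_waypoint <- function(w, h) {
  c(stats::runif(1, 0.1 * w, 0.9 * w), stats::runif(1, 0.1 * h, 0.9 * h))
}
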