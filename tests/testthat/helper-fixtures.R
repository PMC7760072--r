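# Shared fixtures and independent oracles, all built in code.

small_scenario <- function(seed = 1, n_frames = 1200, ...) {
  build_scenario(n_frames = n_frames, seed = seed, ...)
}

# a clean hand-built track: constant position except where stated
flat_track <- function(n = 100, x = 500, y = 500, marker = "nose") {
  marker_track(frame = seq_len(n), x = rep(x, n), y = rep(y, n),
               predicted = rep(TRUE, n), marker = marker)
}

# Brute-force jump oracle: scan all successive predicted-frame pairs with a
# plain loop, flag displacement > gap-scaled threshold.
oracle_jumps <- function(track, threshold_px = 200) {
  pr <- track[track$predicted, ]
  out <- list()
  if (nrow(pr) >= 2) {
    for (i in seq_len(nrow(pr) - 1)) {
      gap <- pr$frame[i + 1] - pr$frame[i]
      disp <- sqrt((pr$x[i + 1] - pr$x[i])^2 + (pr$y[i + 1] - pr$y[i])^2)
      if (disp > gap * threshold_px) {
        out[[length(out) + 1]] <- c(pr$frame[i], pr$frame[i + 1])
      }
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(numeric(), ncol = 2)
}

# Brute-force per-frame confusion oracle.
oracle_confusion <- function(predicted, truth, match_radius_px, window) {
  m <- attr(predicted, "marker")
  truth <- truth[truth$marker == m, ]
  tp <- tn <- fp <- fn <- 0L
  for (f in window) {
    ti <- truth[truth$frame == f, ]
    pi <- predicted[predicted$frame == f, ]
    hidden <- ti$visibility == "not_visible"
    has_pred <- nrow(pi) == 1 && isTRUE(pi$predicted)
    if (hidden) {
      if (has_pred) fp <- fp + 1L else tn <- tn + 1L
    } else {
      if (!has_pred) fn <- fn + 1L
      else {
        d <- sqrt((pi$x - ti$x)^2 + (pi$y - ti$y)^2)
        if (d <= match_radius_px) tp <- tp + 1L else fp <- fp + 1L
      }
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# random truth + prediction pair for property tests
random_eval_pair <- function(n = 200, seed = 1) {
  set.seed(seed)
  frames <- seq_len(n)
  vis <- sample(c("visible", "occluded25", "not_visible"), n, replace = TRUE,
                prob = c(0.7, 0.1, 0.2))
  tx <- runif(n, 0, 2704); ty <- runif(n, 0, 1520)
  tx[vis == "not_visible"] <- NA; ty[vis == "not_visible"] <- NA
  truth <- data.frame(frame = frames, marker = "nose", x = tx, y = ty,
                      visibility = vis, stringsAsFactors = FALSE)
  pred_here <- runif(n) < 0.8
  err <- ifelse(runif(n) < 0.8, runif(n, 0, 80), runif(n, 120, 900))
  ang <- runif(n, 0, 2 * pi)
  px <- ifelse(is.na(tx), runif(n, 0, 2704), tx + err * cos(ang))
  py <- ifelse(is.na(ty), runif(n, 0, 1520), ty + err * sin(ang))
  px <- pmin(pmax(px, 0), 2704); py <- pmin(pmax(py, 0), 1520)
  px[!pred_here] <- NA; py[!pred_here] <- NA
  pred <- marker_track(frame = frames, x = px, y = py,
                       predicted = pred_here, marker = "nose")
  list(truth = truth, pred = pred)
}
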