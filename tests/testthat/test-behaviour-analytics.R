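test_that("heat map bins follow the half-open convention and conserve mass", {
  one <- marker_track(frame = 1, x = 120, y = 80, predicted = TRUE)
  hm <- position_heatmap(one, 50)
  expect_equal(hm$total_mass, 1)
  expect_equal(sum(hm$grid), 1)
  expect_equal(hm$grid[2, 3], 1L)  # y in [50,100) -> row 2; x in [100,150) -> col 3

  # a position exactly on an interior boundary goes to the higher bin
  edge <- marker_track(frame = 1, x = 100, y = 50, predicted = TRUE)
  hme <- position_heatmap(edge, 50)
  expect_equal(hme$grid[2, 3], 1L)
  # the far image edge belongs to the last bin
  corner <- marker_track(frame = 1, x = 2704, y = 1520, predicted = TRUE)
  hmc <- position_heatmap(corner, 50)
  expect_equal(hmc$grid[nrow(hmc$grid), ncol(hmc$grid)], 1L)

  expect_error(position_heatmap(one, 0), "> 0")
})

test_that("heat-map mass equals predicted frames; uniform positions fill bins uniformly", {
  set.seed(70)
  n <- 10000
  pred <- runif(n) < 0.9
  tr <- marker_track(frame = 1:n, x = ifelse(pred, runif(n, 0, 2704), NA),
                     y = ifelse(pred, runif(n, 0, 1520), NA), predicted = pred)
  hm <- position_heatmap(tr, 338)  # 8 x 5 bins; the last y row is partial
  expect_equal(hm$total_mass, sum(pred))
  expect_equal(sum(hm$grid), sum(pred))
  # expected counts proportional to bin areas (the bottom row is 168 px tall)
  row_h <- c(rep(338, 4), 1520 - 4 * 338)
  p_exp <- outer(row_h, rep(338, 8)) / (2704 * 1520)
  chi <- chisq.test(as.vector(hm$grid), p = as.vector(p_exp))
  expect_gt(chi$p.value, 0.001)
})

test_that("time in region is boundary-inclusive, overlap-aware and exhaustive", {
  geo <- stall_geometry()
  whole <- list(all = cbind(x = c(0, 2704, 2704, 0), y = c(0, 0, 1520, 1520)))
  tr <- flat_track(120)
  tb <- time_in_region(tr, whole, fps_tlv = 2)
  expect_equal(tb$percent[tb$key == "all"], 100)
  expect_equal(tb$frames[tb$key == "elsewhere"], 0)
  expect_equal(tb$minutes[tb$key == "all"], 1)  # 120 frames / (2*60)

  # shared edge: the point lands in both regions and is flagged
  left <- list(a = cbind(x = c(0, 500, 500, 0), y = c(0, 0, 1520, 1520)),
               b = cbind(x = c(500, 1000, 1000, 500), y = c(0, 0, 1520, 1520)))
  on_edge <- marker_track(frame = 1, x = 500, y = 700, predicted = TRUE)
  tbe <- time_in_region(on_edge, left)
  expect_equal(tbe$frames[tbe$key == "a"], 1)
  expect_equal(tbe$frames[tbe$key == "b"], 1)
  expect_equal(attr(tbe, "overlap_frames"), 1)

  bowtie <- list(bad = cbind(x = c(0, 100, 0, 100), y = c(0, 100, 100, 0)))
  expect_error(time_in_region(tr, bowtie), "self-intersecting")

  # disjoint exhaustive budgets: percents sum to exactly 100
  sc <- small_scenario(seed = 71)
  sim <- simulate_tracks(sc)
  deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry, seed = 72)
  tbr <- time_in_region(deg$tracks$nose, geo$regions)
  expect_equal(sum(tbr$percent), 100, tolerance = 1e-9)
  expect_equal(sum(tbr$frames), attr(tbr, "n_evaluated"))
})

test_that("region containment agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  geo <- stall_geometry()
  set.seed(73)
  x <- runif(500, 0, 2704); y <- runif(500, 0, 1520)
  for (nm in names(geo$regions)) {
    p <- geo$regions[[nm]]
    got <- point_in_polygon(x, y, p)
    want <- mgcv::in.out(rbind(p, p[1, ]), cbind(x, y))
    # the oracle's boundary convention may differ; compare interior points
    on_edge <- x %in% p[, 1] | y %in% p[, 2]
    expect_equal(got[!on_edge], want[!on_edge])
  }
})

test_that("generated region dwell is recovered by the occupancy budget", {
  # a chain that rests 30% of the time parks the nose at the sidewall
  stay <- 0.995
  tm <- matrix(c(0.65, 0.30, 0.04, 0.01), 4, 4, byrow = TRUE)
  tm <- tm * (1 - stay) / rowSums(tm * 1) ; diag(tm) <- 0
  tm <- matrix(0, 4, 4)
  # build a chain whose stationary law is (0.55, 0.30, 0.10, 0.05)
  target <- c(0.55, 0.30, 0.10, 0.05)
  for (i in 1:4) for (j in 1:4) if (i != j) tm[i, j] <- (1 - stay) * target[j] / (1 - target[i])
  diag(tm) <- 1 - rowSums(tm)
  bm <- behaviour_model(transition_matrix = tm)
  sc <- build_scenario(behaviour = bm, n_frames = 20000, seed = 74,
                       artifacts = artifact_spec(dropout_rate = 0, jump_rate = 0,
                                                 noise_sigma = 2,
                                                 occluded_class_rate = 0))
  sim <- simulate_tracks(sc)
  rest_share <- mean(sim$labels$behaviour == "rest")
  deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry, seed = 75)
  tb <- time_in_region(deg$tracks$nose, sc$geometry$regions)
  got <- tb$percent[tb$key == "sidewall"] / 100
  # the sidewall is the rest anchor; transit and head sweeps leak a little
  expect_lt(abs(got - rest_share), 0.05)
})

test_that("x/y series joins behave like an inner join", {
  tr <- flat_track(50)
  lab <- data.frame(frame = 26:80, behaviour = "rest")
  joined <- xy_series_with_behaviour(tr, lab)
  expect_equal(joined$frame, 26:50)
  expect_true(all(joined$behaviour == "rest"))

  expect_error(xy_series_with_behaviour(tr, data.frame(frame = 100:120,
                                                       behaviour = "rest")),
               "no frames")
  full <- xy_series_with_behaviour(tr, data.frame(frame = 1:50, behaviour = "rest"))
  expect_equal(nrow(full), 50)
  # the join preserves both inputs on the overlap
  expect_equal(full$x, tr$x)
  expect_equal(full$behaviour, rep("rest", 50))
})

test_that("rolling dispersion is zero for stillness and A^2/2 for a sinusoid", {
  tr <- flat_track(200)
  rv <- rolling_dispersion(tr, "y", 30)
  expect_true(all(rv$variance[!is.na(rv$variance)] < 1e-20))

  a <- 40; period <- 20; n <- 2000
  y <- 700 + a * sin(2 * pi * seq_len(n) / period)
  sine <- marker_track(frame = 1:n, x = rep(500, n), y = y,
                       predicted = rep(TRUE, n))
  rvs <- rolling_dispersion(sine, "y", 400)  # window >> period
  mid <- rvs$variance[800:1200]
  expect_equal(mean(mid), a^2 / 2, tolerance = 0.02)

  expect_error(rolling_dispersion(tr, "y", 1), ">= 2")
})

test_that("weight-shift flags separate oscillating from quiet rest", {
  run_ws <- function(amp, seed, threshold = 3) {
    bm <- behaviour_model(rest_y_oscillation_amplitude = amp)
    sc <- build_scenario(behaviour = bm, n_frames = 6000, seed = seed)
    sim <- simulate_tracks(sc)
    deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry,
                                  seed = seed + 1)
    nose <- remove_flagged_jumps(deg$tracks$nose)
    suppressMessages(detect_weight_shifting(nose, sim$labels,
                                            variance_ratio_threshold = threshold))
  }
  osc <- run_ws(25, 81)
  quiet <- run_ws(0, 81)
  expect_gt(sum(osc$flagged), 0)
  expect_equal(sum(quiet$flagged), 0)

  # monotone in the threshold: an infinite threshold flags nothing
  inf <- run_ws(25, 81, threshold = Inf)
  expect_equal(sum(inf$flagged), 0)

  # no rest frames: empty result with a notice
  lab <- data.frame(frame = 1:100, behaviour = "feeding")
  expect_message(res <- detect_weight_shifting(flat_track(100), lab), "no rest")
  expect_equal(nrow(res), 0)
})

test_that("behaviour classification respects its rule cascade", {
  # a scanning head high in the image over a still body: standing
  # observation throughout (a perfectly still head would be rest)
  n <- 400
  set.seed(82)
  mk <- function(x, y) marker_track(frame = 1:n, x = x + rnorm(n, 0, 6),
                                    y = y + rnorm(n, 0, 6), predicted = rep(TRUE, n))
  scan_nose <- marker_track(frame = 1:n,
                            x = 600 + 150 * sin(2 * pi * (1:n) / 100) + rnorm(n, 0, 3),
                            y = 400 + rnorm(n, 0, 3), predicted = rep(TRUE, n))
  tracks <- list(nose = scan_nose, withers = mk(900, 450))
  out <- classify_behaviour(tracks)
  expect_true(all(out$behaviour == "standing_observation"))

  # the same body with a still head sustained for the whole video: rest
  still <- list(nose = mk(600, 400), withers = mk(900, 450))
  out_still <- classify_behaviour(still, smooth_window = 9)
  expect_gt(mean(out_still$behaviour == "rest"), 0.8)

  # move_threshold 0: every frame classified moving
  out0 <- classify_behaviour(tracks, move_threshold = 0)
  expect_true(all(out0$behaviour == "moving"))

  # a nose below the feeding line with a quiet withers is feeding
  feed <- list(nose = mk(1400, 1300), withers = mk(1300, 900))
  outf <- classify_behaviour(feed)
  expect_true(all(outf$behaviour == "feeding"))

  # insufficient nose coverage errors
  sparse <- marker_track(frame = 1:n, x = c(rep(500, 100), rep(NA, 300)),
                         y = c(rep(500, 100), rep(NA, 300)),
                         predicted = c(rep(TRUE, 100), rep(FALSE, 300)))
  expect_error(classify_behaviour(list(nose = sparse, withers = mk(900, 450))),
               "50%")
})

test_that("classification recovers generator labels on a seeded scenario", {
  sc <- build_scenario(n_frames = 8000, seed = 83)
  sim <- simulate_tracks(sc)
  deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry, seed = 84)
  pred <- classify_behaviour(deg$tracks)
  agreement <- mean(pred$behaviour == sim$labels$behaviour)
  expect_gt(agreement, 0.9)
})

test_that("behaviour time budgets convert frames to minutes and conserve percent", {
  lab <- data.frame(frame = 1:480, behaviour = "feeding")
  tb <- behaviour_time_budget(lab, fps_tlv = 2)
  expect_equal(tb$minutes[tb$key == "feeding"], 4)
  expect_equal(tb$percent[tb$key == "feeding"], 100)
  # absent classes are present with zero
  expect_equal(tb$frames[tb$key == "moving"], 0)
  expect_equal(nrow(tb), 4)
  expect_equal(sum(tb$percent), 100, tolerance = 1e-9)

  sc <- small_scenario(seed = 85)
  sim <- simulate_tracks(sc)
  tb2 <- behaviour_time_budget(sim$labels, sc$fps_tlv)
  expect_equal(sum(tb2$percent), 100, tolerance = 1e-9)
  expect_equal(sum(tb2$frames), nrow(sim$labels))

  expect_error(behaviour_time_budget(data.frame(frame = integer(),
                                                behaviour = character())),
               "empty")
  expect_error(behaviour_time_budget(data.frame(frame = 1, behaviour = "grazing")),
               "unknown")
})
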