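test_that("prediction rates divide predicted images by total images", {
  pred <- c(rep(TRUE, 700), rep(FALSE, 300))
  tr <- marker_track(frame = 1:1000, x = ifelse(pred, 500, NA),
                     y = ifelse(pred, 500, NA), predicted = pred)
  meta <- video_meta("v", 1000)
  pr <- prediction_rates(tr, meta)
  expect_equal(pr$PM, 700)
  expect_equal(pr$pm_ti, 0.7)

  none <- marker_track(frame = 1:10, x = rep(NA_real_, 10), y = rep(NA_real_, 10),
                       predicted = rep(FALSE, 10))
  expect_equal(prediction_rates(none, video_meta("v", 10))$pm_ti, 0)
  all_tr <- flat_track(10)
  expect_equal(prediction_rates(all_tr, video_meta("v", 10))$pm_ti, 1)
  expect_error(prediction_rates(all_tr, list(n_frames = 0)), "positive")
})

test_that("confusion classification handles the canonical frame cases", {
  truth <- data.frame(frame = 1:4, marker = "nose",
                      x = c(100, 100, NA, 100), y = c(100, 100, NA, 100),
                      visibility = c("visible", "visible", "not_visible",
                                     "occluded50"))
  # frame 1: exact hit; frame 2: 101 px off -> FP; frame 3: hidden,
  # unpredicted -> TN; frame 4: occluded with position, unpredicted -> FN
  pred <- marker_track(frame = 1:4, x = c(100, 201, NA, NA),
                       y = c(100, 100, NA, NA),
                       predicted = c(TRUE, TRUE, FALSE, FALSE), marker = "nose")
  cc <- classify_confusion(pred, truth, match_radius_px = 100, window = 1:4)
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(1, 1, 1, 1))

  # a prediction on a hidden frame is a false positive
  pred2 <- marker_track(frame = 3, x = 50, y = 50, predicted = TRUE,
                        marker = "nose")
  cc2 <- classify_confusion(pred2, truth, 100, window = 3)
  expect_equal(cc2$FP, 1)

  expect_error(classify_confusion(pred, truth, 100, window = 1:9),
               "neither table")
})

test_that("confusion classification equals the brute-force per-frame oracle", {
  for (s in 1:60) {
    pair <- random_eval_pair(n = 120, seed = s)
    win <- sort(sample(pair$truth$frame, 80))
    got <- classify_confusion(pair$pred, pair$truth, 100, win)
    want <- oracle_confusion(pair$pred, pair$truth, 100, win)
    expect_equal(got[c("TP", "TN", "FP", "FN")], want)
    expect_equal(got$TP + got$TN + got$FP + got$FN, length(win))
  }
})

test_that("performance formulas and their ranges are exact", {
  expect_equal(performance_metrics(list(TP = 88, TN = 0, FP = 0, FN = 12))$sensitivity,
               0.88, tolerance = 1e-12)
  expect_equal(performance_metrics(list(TP = 94, TN = 0, FP = 6, FN = 0))$error_rate,
               0.06, tolerance = 1e-12)
  expect_equal(performance_metrics(list(TP = 50, TN = 30, FP = 10, FN = 10))$accuracy,
               0.80, tolerance = 1e-12)

  # zero denominators are undefined values, not errors
  und <- performance_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(und$sensitivity))
  expect_true(is.na(und$error_rate))
  expect_equal(und$accuracy, 1)

  # accuracy is 1 iff there are no wrong frames
  set.seed(4)
  for (i in 1:50) {
    cts <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                            c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cts)) == 0) next
    pm <- performance_metrics(cts)
    for (v in pm) if (!is.na(v)) expect_true(v >= 0 && v <= 1)
    expect_equal(isTRUE(all.equal(pm$accuracy, 1)),
                 cts$FP == 0 && cts$FN == 0)
  }
})

test_that("mean/SD aggregation excludes undefined values and is permutation-invariant", {
  agg <- aggregate_mean_sd(c(0.7, 0.9))
  expect_equal(agg$mean, 0.8)
  expect_equal(agg$sd, sqrt(((0.7 - 0.8)^2 + (0.9 - 0.8)^2) / 1))
  expect_equal(agg$sd, 0.1414, tolerance = 1e-3)

  one <- aggregate_mean_sd(0.5)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1)

  mixed <- aggregate_mean_sd(c(0.5, NA, 0.7))
  expect_equal(mixed$mean, 0.6)
  expect_equal(mixed$n, 2)
  expect_equal(mixed$n_undefined, 1)
  expect_error(aggregate_mean_sd(c(NA_real_, NA_real_)), "undefined")

  set.seed(8)
  v <- runif(12)
  p <- sample(v)
  expect_equal(aggregate_mean_sd(v)[c("mean", "sd")],
               aggregate_mean_sd(p)[c("mean", "sd")])
})

test_that("paired version comparison matches the textbook t formula", {
  mk <- function(vals, version) {
    data.frame(video_id = sprintf("v%02d", seq_along(vals)), marker = "nose",
               PM = vals, TI = 1000, pm_ti = vals / 1000, WP = 0, pct_wp = 0)
  }
  a_vals <- c(712, 640, 801, 553, 699, 745, 688, 630)
  b_vals <- c(694, 651, 770, 561, 661, 700, 691, 601)
  res <- compare_versions(mk(a_vals), mk(b_vals), quantities = "PM")

  # oracle: hand-computed paired t and p via the t distribution
  d <- a_vals - b_vals
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-6)
  expect_equal(res$p_value, p_hand, tolerance = 1e-6)
  expect_equal(res$df, 7)

  # identical versions: t = 0, p = 1
  same <- compare_versions(mk(a_vals), mk(a_vals), quantities = "PM")
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  # constant nonzero shift: degenerate, reported as such
  shift <- compare_versions(mk(a_vals), mk(a_vals + 10), quantities = "PM")
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p_value))

  expect_error(compare_versions(mk(a_vals)[1:3, ], mk(b_vals)),
               "unmatched videos")
})

test_that("one-way ANOVA across markers matches hand-computed sums of squares", {
  vals <- c(0.91, 0.88, 0.93, 0.85, 0.78, 0.74, 0.81, 0.70, 0.95, 0.96, 0.93, 0.92)
  grp <- rep(c("withers", "tail", "nose"), each = 4)
  res <- compare_markers_anova(vals, grp)

  # oracle: explicit between/within sums of squares
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$F, f_hand, tolerance = 1e-9)
  expect_equal(c(res$df_between, res$df_within), c(2, 9))
  expect_equal(res$p_value, pf(f_hand, 2, 9, lower.tail = FALSE), tolerance = 1e-9)

  # two groups: F equals the square of the pooled t statistic
  v2 <- vals[1:8]; g2 <- grp[1:8]
  res2 <- compare_markers_anova(v2, g2)
  tt <- t.test(v2[g2 == "withers"], v2[g2 == "tail"], var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-9)

  # identical groups: F = 0, p = 1
  resid <- compare_markers_anova(rep(c(0.5, 0.6), 6), rep(c("a", "b", "c"), each = 4))
  expect_equal(resid$F, 0)
  expect_equal(resid$p_value, 1)

  expect_error(compare_markers_anova(c(1, 2), c("a", "b")), ">= 2 groups")
})

test_that("sensitivity falls with dropout and error rate rises with jumps", {
  measure <- function(dropout, jumps, seed) {
    art <- artifact_spec(dropout_rate = dropout, jump_count = jumps,
                         noise_sigma = 2, occluded_class_rate = 0)
    sc <- build_scenario(artifacts = art, n_frames = 2000, seed = seed)
    sim <- simulate_tracks(sc)
    deg <- degrade_to_predictions(sim$ground_truth, sc$artifacts, sc$geometry,
                                  seed = seed + 1)
    cc <- classify_confusion(deg$tracks$nose, sim$ground_truth, 100, 1:2000)
    performance_metrics(cc)
  }
  sens <- sapply(c(0, 0.1, 0.3, 0.6), function(d) measure(d, 0, 61)$sensitivity)
  expect_true(all(diff(sens) < 0))
  errs <- sapply(c(0, 10, 40), function(j) measure(0, j, 62)$error_rate)
  expect_true(all(diff(errs) > 0))
})
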