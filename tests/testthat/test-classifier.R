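test_that("first-round segmentation returns a contiguous partition", {
  s <- simulate_gaze(fig4_scenario(), seed = 1)
  for (k in c(1, 3)) {
    segs <- first_round_segment(s, k, seed = 1)
    expect_equal(segs$start[1], 1)
    expect_equal(segs$end[nrow(segs)], nrow(s))
    if (nrow(segs) > 1)
      expect_equal(segs$start[-1], segs$end[-nrow(segs)] + 1)
    expect_true(all(segs$end >= segs$start))
  }
  expect_equal(nrow(first_round_segment(s, 1, seed = 1)), 1)
})

test_that("two fixations split by a saccade are segmented near the truth", {
  spec <- scenario_spec(list(list(behavior = "fixation", duration = 1),
                             list(behavior = "saccade", duration = 0.044),
                             list(behavior = "fixation", duration = 1)),
                        start = c(600, 540))
  s <- simulate_gaze(spec, seed = 7)
  segs <- first_round_segment(s, 2, seed = 1)
  expect_equal(nrow(segs), 2)
  # true boundary: the saccade sits at samples 91-94
  expect_lt(abs(segs$end[1] - 92), 3 + 2)
})

test_that("short first-round runs are merged into longer neighbours", {
  runs <- gazehmm:::label_runs(c(1, 1, 1, 1, 2, 1, 1, 1, 1, 1))
  merged <- gazehmm:::merge_short_runs(runs, 3)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$value, 1)
  runs2 <- gazehmm:::label_runs(c(1, 1, 1, 2, 2, 3, 3, 3, 3))
  merged2 <- gazehmm:::merge_short_runs(runs2, 3)
  expect_equal(merged2$value, c(1, 3))
  expect_equal(merged2$end - merged2$start + 1, c(3, 6))
})

test_that("degenerate low-spread segments take the fallback label", {
  spec <- scenario_spec(list(list(behavior = "fixation", duration = 2)),
                        start = c(960, 540))
  s <- simulate_gaze(spec, seed = 3)
  lab <- second_round_classify(s, c(1, nrow(s)), seed = 1)
  expect_true(all(lab == "fixation"))
})

test_that("second round confines saccade labels to the high-velocity burst", {
  spec <- scenario_spec(list(list(behavior = "fixation", duration = 1),
                             list(behavior = "saccade", duration = 0.044),
                             list(behavior = "fixation", duration = 1)),
                        start = c(600, 540))
  for (seed in c(1, 5, 9)) {
    s <- simulate_gaze(spec, seed = seed)
    lab <- second_round_classify(s, c(1, nrow(s)), seed = seed)
    sac_pred <- which(lab == "saccade")
    sac_true <- which(s$label == "saccade")
    expect_gt(length(sac_pred), 0)
    expect_true(all(sac_pred >= min(sac_true) - 2 &
                    sac_pred <= max(sac_true) + 2))
  }
})

test_that("the full pipeline classifies the worked example correctly", {
  s <- simulate_gaze(fig4_scenario(), seed = 0)
  pred <- classify_gaze(s, seed = 0)
  expect_equal(length(pred$label), nrow(s))
  runs <- rle(as.character(pred$label))
  expect_equal(sum(runs$values == "saccade"), 2)
  in_pursuit <- s$t >= 0.5 & s$t < 1.5
  expect_gt(mean(pred$label[in_pursuit] == "pursuit"), 0.5)
  r <- report(confusion(s, pred))
  expect_gt(r$accuracy, 0.9)
})

test_that("a stationary fixation-only recording is labelled all fixation", {
  spec <- scenario_spec(list(list(behavior = "fixation", duration = 3)),
                        start = c(960, 540))
  s <- simulate_gaze(spec, seed = 2)
  pred <- classify_gaze(s, seed = 0)
  expect_true(all(pred$label == "fixation"))
})

test_that("classification is deterministic and shift-invariant", {
  s <- simulate_gaze(fig4_scenario(), seed = 4)
  p1 <- classify_gaze(s, seed = 3)
  p2 <- classify_gaze(s, seed = 3)
  expect_identical(as.character(p1$label), as.character(p2$label))
  # translate space and shift time: labels unchanged
  s2 <- gaze_sequence(s$t + 100, s$x + 57.5, s$y - 21)
  p3 <- classify_gaze(s2, seed = 3)
  expect_identical(as.character(p3$label), as.character(p1$label))
})

test_that("every sample receives exactly one label in temporal order", {
  for (seed in 0:2) {
    s <- simulate_gaze(fig4_scenario(), seed = seed)
    pred <- classify_gaze(s, seed = seed)
    expect_equal(nrow(pred), nrow(s))
    expect_equal(pred$t, s$t)
    expect_false(any(is.na(pred$label)))
  }
})

test_that("the hierarchical classifier beats I-VT on most benchmark seeds", {
  seqs <- standard_benchmark(8, seed = 0)
  wins <- 0
  for (i in seq_along(seqs)) {
    truth <- seqs[[i]]
    f1_g <- report(confusion(truth, classify_gaze(truth,
                                                  seed = i - 1)))$macro_f1
    f1_v <- report(confusion(truth, classify_ivt(truth)))$macro_f1
    wins <- wins + (f1_g > f1_v)
  }
  expect_gte(wins / length(seqs), 0.8)
})

test_that("configuration validation and YAML loading work", {
  expect_error(classifier_config(K_m = 0), ">= 1")
  expect_error(classifier_config(gmm_k_round2 = 6), "between 1 and 5")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("K_m: 6", "min_run_length: 5", "log_velocity: false"), f)
  cfg <- read_classifier_config(f)
  expect_equal(cfg$K_m, 6)
  expect_equal(cfg$min_run_length, 5)
  expect_false(cfg$log_velocity)
  expect_equal(cfg$n_restarts, 10)  # untouched default
  writeLines("bogus_key: 1", f)
  expect_error(read_classifier_config(f), "unknown config key")
})
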