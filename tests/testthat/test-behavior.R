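# Activity, freezing, fear-conditioning summaries, open-field metrics.

test_that("activity is the fraction of changed pixels", {
  f1 <- matrix(0, 8, 8)
  f2 <- f1; f2[1:4, ] <- 1       # half the pixels change
  f3 <- f2 + 1                   # every pixel changes
  act <- compute_activity(array(c(f1, f1, f2, f3), dim = c(8, 8, 4)))
  expect_equal(act$activity, c(0, 0, 0.5, 1))
  expect_error(compute_activity(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "same shape")
})

test_that("freezing bouts are maximal sub-threshold runs above min duration", {
  t <- seq(0, 20, by = 0.1)
  act <- rep(0.2, length(t))
  act[t >= 5 & t < 8] <- 0       # 3 s still
  trace <- tibble::tibble(time_s = t, activity = act)
  bouts <- detect_freezing(trace, theta = 0.05, min_duration = 1)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$start_s, 5)
  expect_equal(bouts$duration_s, 3, tolerance = 0.11)

  act2 <- rep(0.2, length(t))
  act2[t >= 5 & t < 5.5] <- 0    # 0.5 s: below min duration
  bouts2 <- detect_freezing(tibble::tibble(time_s = t, activity = act2),
                            theta = 0.05, min_duration = 1)
  expect_equal(nrow(bouts2), 0)
  expect_error(detect_freezing(trace[0, ]), "empty")
})

test_that("raising theta never removes covered freezing time", {
  set.seed(31)
  t <- seq(0, 60, by = 0.1)
  trace <- tibble::tibble(time_s = t,
                          activity = abs(stats::rnorm(length(t), 0.05, 0.05)))
  thetas <- c(0.02, 0.05, 0.1, 0.2)
  covers <- lapply(thetas, function(th) {
    b <- detect_freezing(trace, theta = th, min_duration = 0.3)
    covered <- rep(FALSE, length(t))
    for (i in seq_len(nrow(b))) {
      covered <- covered | (t >= b$start_s[i] & t < b$end_s[i])
    }
    covered
  })
  for (i in seq_len(length(thetas) - 1)) {
    expect_true(all(covers[[i + 1]][covers[[i]]]))
  }
})

test_that("detected bouts overlap generator truth with high IoU", {
  ious <- vapply(1:10, function(s) {
    bt <- sim_behavior_trace(phenotype = "hearing", freeze_fraction = 0.8,
                             seed = s)
    det <- detect_freezing(bt$trace, theta = 0.01, min_duration = 1)
    bout_iou(det, bt$truth_bouts, t_max = 300)
  }, numeric(1))
  expect_true(all(ious >= 0.9))
})

test_that("fear-conditioning summary uses the pre/post tone bins", {
  bt <- sim_behavior_trace(phenotype = "hearing", freeze_latency = 0,
                           freeze_fraction = 1, seed = 4)
  fc <- fc_summary(bt$trace)
  expect_equal(fc$bin, c("pre", "post"))
  expect_equal(fc$start_s, c(90, 150))
  expect_equal(fc$freezing_s, c(0, 60))
  expect_equal(fc$mean_activity[2], 0)
  expect_gt(fc$mean_activity[1], 0.1)

  # constant supra-threshold activity: mean a in both bins, no freezing
  t <- seq(0, 299.9, by = 0.1)
  const <- tibble::tibble(time_s = t, activity = 0.3)
  fc2 <- fc_summary(const, tone_onset_s = 150)
  expect_equal(fc2$mean_activity, c(0.3, 0.3))
  expect_equal(fc2$freezing_s, c(0, 0))

  # missing protocol annotation is rejected
  expect_error(fc_summary(const), "tone onset")
  expect_error(fc_summary(tibble::tibble(time_s = 1:10, activity = 0.1),
                          tone_onset_s = 150), "does not cover")
})

test_that("bouts crossing a bin boundary contribute their overlap to each bin", {
  bouts <- tibble::tibble(start_s = c(140, 200), end_s = c(160, 205))
  bins <- tibble::tibble(start_s = c(90, 150), end_s = c(150, 210))
  out <- freezing_by_bin(bouts, bins)
  expect_equal(out$freezing_s, c(10, 15))
})

test_that("deaf-phenotype pre/post freezing difference is not significant", {
  prepost <- purrr::map_dfr(1:50, function(s) {
    bt <- sim_behavior_trace(phenotype = "deaf", freeze_fraction = 0.5,
                             seed = 400 + s)
    fc <- fc_summary(bt$trace)
    tibble::tibble(pre = fc$freezing_s[1], post = fc$freezing_s[2])
  })
  res <- paired_contrast(prepost, pre, post)
  expect_gt(res$p.value, 0.01)
})

test_that("open-field metrics: rotations, distance, center time", {
  arena <- sqrt(2.5)
  n <- 6001
  t <- seq(300, 900, length.out = n)

  # uniform 720 degree clockwise nose sweep around a stationary center
  th <- seq(0, -4 * pi, length.out = n)
  tr <- tibble::tibble(time_s = t, cx = arena / 2, cy = arena / 2,
                       nx = arena / 2 + 0.03 * cos(th),
                       ny = arena / 2 + 0.03 * sin(th))
  of <- open_field(tr, arena_side_m = arena)
  expect_equal(of$rotations_cw, 2)
  expect_equal(of$rotations_ccw, 0)
  expect_equal(of$distance_cm, 0)
  expect_equal(of$center_s, 600, tolerance = 0.2)

  # rotation counting is invariant to 2x temporal upsampling
  t2 <- seq(300, 900, length.out = 2 * n - 1)
  th2 <- seq(0, -4 * pi, length.out = 2 * n - 1)
  tr2 <- tibble::tibble(time_s = t2, cx = arena / 2, cy = arena / 2,
                        nx = arena / 2 + 0.03 * cos(th2),
                        ny = arena / 2 + 0.03 * sin(th2))
  of2 <- open_field(tr2, arena_side_m = arena)
  expect_equal(of2$rotations_cw, of$rotations_cw)
  expect_equal(of2$rotations_ccw, of$rotations_ccw)

  # straight path at 5 cm/s for 600 s: 3000 cm, outside the center zone
  tr3 <- tibble::tibble(time_s = seq(300, 900, by = 0.1),
                        cx = 0.05 + 0.05 * (seq(300, 900, by = 0.1) - 300),
                        cy = 0.1)
  of3 <- open_field(tr3, arena_side_m = arena)
  expect_equal(of3$distance_cm, 3000, tolerance = 1e-6)
  expect_true(is.na(of3$rotations_cw))
  expect_equal(of3$center_s, 0)
})
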