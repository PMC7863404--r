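# Synthetic-data generators: determinism, programmed effects, truth
# consistency.

test_that("generators are deterministic given seed and parameters", {
  p <- cochlea_sim_params(n_cells_per_row = 4, seed = 8)
  a <- sim_cochlea_stack(p)
  b <- sim_cochlea_stack(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stack$channels, b$stack$channels)

  d1 <- sim_dpoae_levels(seed = 4)
  d2 <- sim_dpoae_levels(seed = 4)
  expect_identical(d1$amplitude_db, d2$amplitude_db)

  s1 <- sim_abr_series(abr_sim_params(frequencies = "6", seed = 4))
  s2 <- sim_abr_series(abr_sim_params(frequencies = "6", seed = 4))
  expect_identical(s1$series$voltage_uv, s2$series$voltage_uv)

  bt1 <- sim_behavior_trace(seed = 4)
  bt2 <- sim_behavior_trace(seed = 4)
  expect_identical(bt1$trace, bt2$trace)

  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(sim_dpoae_levels(seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("wild-type truth distances equal the programmed values without jitter", {
  sim <- sim_cochlea_stack(
    cochlea_sim_params(n_cells_per_row = 20, noise_sd = 0,
                       nucleus_jitter_sd = 0, seed = 1),
    render = FALSE)
  expect_equal(sim$truth$arc_distance_um[sim$truth$type == "OHC"],
               rep(10, 60))
  expect_equal(sim$truth$arc_distance_um[sim$truth$type == "IHC"],
               rep(9, 20))
})

test_that("knockout shifts OHC nuclei apically by the programmed effect", {
  mean_ohc <- function(genotype, seed) {
    sim <- sim_cochlea_stack(
      cochlea_sim_params(n_cells_per_row = 20, genotype = genotype,
                         nucleus_offset_effect = 3, survival_base = 1,
                         survival_slope = 0, seed = seed),
      render = FALSE)
    mean(sim$truth$arc_distance_um[sim$truth$type == "OHC"])
  }
  wt <- vapply(1:10, function(s) mean_ohc("WT", s), numeric(1))
  ko <- vapply(1:10, function(s) mean_ohc("KO", 100 + s), numeric(1))
  # jitter SE of the difference of means: sd 0.4, n 60 per specimen
  se <- 0.4 * sqrt(2 / (60 * 10))
  expect_lt(abs((mean(wt) - mean(ko)) - 3), 4 * se)
})

test_that("rendered truth is internally consistent: landmarks lie on the cell arc", {
  sim <- sim_cochlea_stack(cochlea_sim_params(n_cells_per_row = 5, seed = 6),
                           render = FALSE)
  mm <- measure_nuclei(sim$truth)
  expect_equal(mm$distance_um, sim$truth$arc_distance_um, tolerance = 1e-6)
})

test_that("re-measuring a rendered noiseless stack recovers truth distances", {
  sim <- fix_clean_sim()
  det <- fix_clean_detections()
  m <- match_truth(det, sim$truth)
  truth_alive <- sim$truth[sim$truth$alive, ]
  mm <- measure_nuclei(det)
  err <- abs(mm$distance_um - truth_alive$arc_distance_um[m])
  expect_lt(max(err), sqrt(sum(sim$stack$voxel_size^2)))  # < 1 voxel diagonal
})

test_that("ABR averaging reduces noise like one over sqrt(n_sweeps)", {
  baseline_sd <- function(n_sweeps, seed) {
    sim <- sim_abr_series(abr_sim_params(
      true_threshold = 95, frequencies = "6", intensities = c(10, 15),
      n_sweeps = n_sweeps, seed = seed))
    suppressWarnings(sd(sim$series$voltage_uv[sim$series$time_ms < 1]))
  }
  sds_512 <- vapply(1:100, function(s) {
    suppressWarnings(baseline_sd(512, s))
  }, numeric(1))
  sds_1 <- vapply(1:100, function(s) {
    suppressWarnings(baseline_sd(1, 200 + s))
  }, numeric(1))
  ratio <- mean(sds_512) / mean(sds_1)
  expect_lt(abs(ratio - 1 / sqrt(512)) / (1 / sqrt(512)), 0.2)
})

test_that("ABR truth is censored when the threshold exceeds the grid", {
  expect_warning(
    sim <- sim_abr_series(abr_sim_params(true_threshold = 95,
                                         frequencies = "30")),
    "censored")
  expect_true(sim$truth$censored)
  # noiseless: first nonzero averaged trace appears at the true threshold
  clean <- sim_abr_series(abr_sim_params(true_threshold = 35,
                                         frequencies = "12", noise_sd = 0))
  nonzero <- clean$series |>
    dplyr::group_by(intensity_db) |>
    dplyr::summarise(any = any(voltage_uv != 0))
  expect_equal(nonzero$any, nonzero$intensity_db >= 35)
})

test_that("sub-threshold DPOAE spectra keep the DP bin inside the noise", {
  zs <- vapply(1:100, function(s) {
    d <- sim_dpoae_levels(levels = 20, true_threshold = 60, seed = s)
    res <- dp_extract(d)
    (res$dp_db - (-15)) / 2    # (dp - noise_floor) / noise sd
  }, numeric(1))
  # pooled z of the mean DP-bin deviation
  expect_lt(abs(mean(zs)) / (1 / sqrt(100)), 3)
  expect_true(all(abs(zs) < 4))
})

test_that("behavior generator renders truth bouts exactly into the activity channel", {
  bt <- sim_behavior_trace(phenotype = "hearing", freeze_latency = 0,
                           freeze_fraction = 1, seed = 2)
  expect_equal(nrow(bt$truth_bouts), 1)
  expect_equal(bt$truth_bouts$start_s, 150)
  expect_equal(bt$truth_bouts$end_s, 300)
  frozen <- bt$trace$activity == 0
  expect_true(all(frozen == (bt$trace$time_s >= 150)))

  none <- sim_behavior_trace(freeze_fraction = 0, seed = 2)
  expect_equal(nrow(none$truth_bouts), 0)
  expect_true(all(none$trace$activity > 0))
})

test_that("deaf-phenotype freezing is independent of the tone period", {
  share_in_tone <- vapply(1:50, function(s) {
    bt <- sim_behavior_trace(phenotype = "deaf", freeze_fraction = 0.5,
                             seed = s)
    b <- bt$truth_bouts
    tot <- sum(b$end_s - b$start_s)
    if (tot == 0) return(NA_real_)
    in_tone <- sum(pmax(0, pmin(b$end_s, 300) - pmax(b$start_s, 150)))
    in_tone / tot
  }, numeric(1))
  # tone occupies half the session: expected share 0.5; one-sided test for
  # an excess should not be significant
  tt <- stats::t.test(share_in_tone, mu = 0.5, alternative = "greater")
  expect_gt(tt$p.value, 0.01)
})
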