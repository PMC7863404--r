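# ABR threshold/feature extraction and DPOAE distortion-product analysis.

make_trace <- function(v, dt = 0.1) {
  tibble::tibble(time_ms = seq_along(v) * dt - dt, voltage_uv = v)
}

test_that("response detection applies the amplitude-over-noise rule", {
  # flat zero trace is never a response
  expect_false(detect_response(make_trace(rep(0, 100)),
                               baseline_window = c(0, 2),
                               response_window = c(2, 6)))

  # baseline SD 0.1 uV, response peak-to-peak 1.0 uV, k = 4 -> detected
  v <- c(rep(c(-0.1, 0.1), 10), rep(0, 80))
  v[40] <- 0.6; v[50] <- -0.4
  tr <- make_trace(v)
  expect_true(detect_response(tr, baseline_window = c(0, 2),
                              response_window = c(2, 6), k = 4))
  # same trace fails a stricter criterion
  expect_false(detect_response(tr, baseline_window = c(0, 2),
                               response_window = c(2, 6), k = 15))

  expect_error(detect_response(tr, baseline_window = c(0, 3),
                               response_window = c(2, 6)), "disjoint")
  expect_error(detect_response(tr, baseline_window = c(2, 2),
                               response_window = c(2, 6)), "positive length")
})

test_that("noiseless series detect exactly at and above the true threshold", {
  sim <- sim_abr_series(abr_sim_params(true_threshold = 35,
                                       frequencies = "12", noise_sd = 0))
  per_int <- vapply(seq(10, 90, 5), function(i) {
    detect_response(dplyr::filter(sim$series, intensity_db == i))
  }, logical(1))
  expect_equal(per_int, seq(10, 90, 5) >= 35)
  thr <- abr_threshold(sim$series)
  expect_equal(thr$threshold_db, 35)
  expect_false(thr$censored)
})

test_that("threshold applies the monotone rule and censoring convention", {
  # hand-built series: response at 40, gap at 45, responses from 50 up
  grid <- seq(10, 90, 5)
  resp <- function(on) {
    v <- rep(0, 90)
    if (on) { v[30] <- 1; v[40] <- -1 }
    v
  }
  series <- purrr::map_dfr(grid, function(i) {
    on <- (i == 40) | (i >= 50)
    dplyr::mutate(make_trace(resp(on)), frequency = "click",
                  intensity_db = i)
  })
  thr <- abr_threshold(series, baseline_window = c(0, 1),
                       response_window = c(1, 6))
  expect_equal(thr$threshold_db, 50)
  expect_false(thr$censored)

  # never detected: censored as grid max + step, flagged
  series0 <- purrr::map_dfr(grid, function(i) {
    dplyr::mutate(make_trace(resp(FALSE)), frequency = "click",
                  intensity_db = i)
  })
  thr0 <- abr_threshold(series0, baseline_window = c(0, 1),
                        response_window = c(1, 6))
  expect_equal(thr0$threshold_db, 95)
  expect_true(thr0$censored)
})

test_that("P1/N1 features are read exactly off a clean constructed wave", {
  t <- seq(0, 8, by = 0.1)
  v <- 1.2 * exp(-((t - 1.5)^2) / (2 * 0.2^2)) -
    0.8 * exp(-((t - 2.3)^2) / (2 * 0.25^2))
  ft <- abr_features(tibble::tibble(time_ms = t, voltage_uv = v),
                     search_window = c(0.5, 4), onset_ms = 0)
  expect_true(ft$detected)
  expect_equal(ft$p1_latency_ms, 1.5, tolerance = 1e-9)
  expect_equal(ft$p1_uv, max(v), tolerance = 1e-9)
  expect_equal(ft$p1n1_uv, max(v) - min(v), tolerance = 1e-9)
  expect_equal(ft$p1n1_uv, 2.0, tolerance = 0.02)

  flat <- abr_features(make_trace(rep(0, 50)))
  expect_false(flat$detected)
  expect_true(is.na(flat$p1_latency_ms))
})

test_that("feature trends recover the generator's programmed slopes", {
  p <- abr_sim_params(true_threshold = 40, frequencies = "12",
                      intensities = seq(40, 90, 5), noise_sd = 0,
                      sampling_rate = 64)
  sim <- sim_abr_series(p)
  ft <- abr_feature_table(sim$series, search_window = c(1, 4), onset_ms = 1)
  expect_true(all(ft$detected))
  expect_true(all(diff(ft$p1_latency_ms) < 0))
  expect_true(all(diff(ft$p1n1_uv) > 0))
  lat_slope <- stats::coef(stats::lm(p1_latency_ms ~ intensity_db, ft))[2]
  amp_slope <- stats::coef(stats::lm(p1n1_uv ~ intensity_db, ft))[2]
  expect_equal(unname(lat_slope), -p$latency_shift_per_db, tolerance = 0.05)
  expect_equal(unname(amp_slope), 1.8 * p$amplitude_growth, tolerance = 0.05)
})

test_that("distortion product is read at 2f1-f2 with a local noise floor", {
  freqs <- seq(6000, 14000, by = 100)
  base <- tibble::tibble(frequency_hz = freqs,
                         amplitude_db = rep(-10, length(freqs)),
                         f1_hz = 10000, f2_hz = 12000)
  sp <- base
  sp$amplitude_db[sp$frequency_hz == 8000] <- 20
  res <- dp_extract(sp)
  expect_equal(res$dp_hz, 8000)
  expect_equal(res$dp_db, 20)
  expect_equal(res$noise_db, -10)
  expect_true(res$detected)

  # generator places the DP at 2*(12/1.2)-12 = 8 kHz
  d <- sim_dpoae_levels(f2_khz = 12, ratio = 1.2, levels = 60, seed = 1)
  res2 <- dp_extract(dplyr::filter(d, level_db == 60))
  expect_equal(res2$dp_hz, 8000, tolerance = 50)

  # DP bin colliding with a primary is a stimulus-design error
  bad <- base
  attr(bad, "f1_hz") <- NULL
  bad$f1_hz <- 12000; bad$f2_hz <- 12000
  expect_error(dp_extract(bad), "f1 must be below f2")
  col <- base; col$f1_hz <- 8000; col$f2_hz <- 8010
  expect_error(dp_extract(col), "collides|outside")
})

test_that("DPOAE threshold follows the level series with censoring", {
  d <- sim_dpoae_levels(true_threshold = 40, seed = 3)
  res <- d |>
    dplyr::group_by(level_db) |>
    dplyr::group_modify(~ dp_extract(.x)) |>
    dplyr::ungroup()
  thr <- dpoae_threshold(res)
  expect_equal(thr$threshold_db, 40)
  expect_false(thr$censored)

  never <- tibble::tibble(level_db = seq(10, 80, 5), detected = FALSE)
  thr0 <- dpoae_threshold(never)
  expect_equal(thr0$threshold_db, 85)
  expect_true(thr0$censored)
  expect_error(dpoae_threshold(never[0, ]), "no levels")
})

test_that("DPOAE detection recovers the true threshold within one step", {
  hits <- vapply(1:50, function(s) {
    d <- sim_dpoae_levels(true_threshold = 40, seed = s)
    res <- d |>
      dplyr::group_by(level_db) |>
      dplyr::group_modify(~ dp_extract(.x)) |>
      dplyr::ungroup()
    dpoae_threshold(res)$threshold_db
  }, numeric(1))
  expect_gte(mean(abs(hits - 40) <= 5), 0.95)
})
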