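#' Detect a stimulus-evoked response in an averaged ABR trace
#'
#' The study defines the ABR threshold as the lowest intensity with a
#' reproducible waveform; that judgement is operationalised here as an
#' amplitude-over-noise criterion: a trace counts as a response when the
#' peak-to-peak amplitude in the response window exceeds `k` times the
#' residual noise SD. The noise SD is estimated from the difference of
#' the two interleaved half averages (`voltage_a`/`voltage_b`) when the
#' trace carries them — the difference cancels any stimulus-locked signal
#' over the whole record, the standard "plus-minus" noise estimate for
#' evoked potentials — and otherwise from the pre-stimulus baseline
#' window. `k` defaults to 6: the expected peak-to-peak of pure noise
#' across an ~80-sample response window is already about 5 SD, so a
#' smaller multiple fires on noise alone regardless of recording quality.
#' A split-half cross-correlation criterion is available as an
#' alternative (`method = "xcorr"`).
#'
#' @param trace A tibble with columns `time_ms` and `voltage_uv`
#'   (uniformly sampled), optionally `voltage_a`/`voltage_b`.
#' @param baseline_window,response_window Length-2 numeric `c(from, to)`
#'   in ms; must be disjoint and inside the record.
#' @param k Noise-SD multiple for the amplitude criterion (default 6).
#' @param method `"amplitude"` (default) or `"xcorr"`.
#' @param min_r Split-half correlation required when `method = "xcorr"`.
#' @param noise_from `"auto"` (split-half difference when available),
#'   `"split_half"`, or `"baseline"`.
#' @return Logical scalar.
#' @export
detect_response <- function(trace, baseline_window = c(0, 1),
                            response_window = c(1, 6), k = 6,
                            method = c("amplitude", "xcorr"), min_r = 0.5,
                            noise_from = c("auto", "split_half", "baseline")) {
  method <- match.arg(method)
  noise_from <- match.arg(noise_from)
  t <- trace$time_ms
  if (diff(baseline_window) <= 0 || diff(response_window) <= 0) {
    abort("windows must have positive length")
  }
  if (baseline_window[2] > response_window[1] &&
      response_window[2] > baseline_window[1]) {
    abort("baseline and response windows must be disjoint")
  }
  bl <- t >= baseline_window[1] & t < baseline_window[2]
  rw <- t >= response_window[1] & t < response_window[2]
  if (!any(bl) || !any(rw)) abort("windows fall outside the record")

  has_halves <- all(c("voltage_a", "voltage_b") %in% names(trace))
  if (method == "xcorr") {
    if (!has_halves) {
      abort("xcorr criterion needs split-half columns voltage_a/voltage_b")
    }
    va <- trace$voltage_a[rw]; vb <- trace$voltage_b[rw]
    if (sd(va) == 0 || sd(vb) == 0) return(FALSE)
    return(stats::cor(va, vb) >= min_r)
  }

  v <- trace$voltage_uv
  use_halves <- switch(noise_from,
                       auto = has_halves,
                       split_half = {
                         if (!has_halves) abort("no split-half columns")
                         TRUE
                       },
                       baseline = FALSE)
  noise <- if (use_halves) {
    sd((trace$voltage_a - trace$voltage_b) / 2)
  } else {
    sd(v[bl])
  }
  p2p <- max(v[rw]) - min(v[rw])
  if (noise == 0) return(p2p > 0)
  p2p > k * noise
}

#' ABR threshold over an intensity series
#'
#' The threshold is the lowest intensity at which a response is detected
#' at that intensity and at every higher intensity (monotone enforcement:
#' isolated detections below a gap are ignored, so a single false positive
#' cannot lower the threshold). When no intensity qualifies the threshold
#' is censored and encoded as `max(grid) + step` with `censored = TRUE`,
#' so group summaries remain computable.
#'
#' @param series A long tibble with columns `frequency` (kHz, or "click"),
#'   `intensity_db`, `time_ms`, `voltage_uv` — one trace per
#'   frequency-intensity pair on a complete, uniformly stepped grid.
#' @param frequency Optional subset of frequencies; default: all present.
#' @param ... Passed to [detect_response()].
#' @return A tibble with one row per frequency: `frequency`,
#'   `threshold_db`, `censored`.
#' @export
abr_threshold <- function(series, frequency = NULL, ...) {
  series <- as_tibble(series)
  freqs <- unique(series$frequency)
  if (!is.null(frequency)) freqs <- intersect(freqs, frequency)
  purrr::map_dfr(freqs, function(fq) {
    sub <- dplyr::filter(series, .data$frequency == fq)
    grid <- sort(unique(sub$intensity_db))
    steps <- diff(grid)
    if (length(grid) < 2L || length(unique(steps)) != 1L) {
      abort("intensity grid must be complete with a uniform step")
    }
    detected <- vapply(grid, function(i) {
      detect_response(dplyr::filter(sub, .data$intensity_db == i), ...)
    }, logical(1))
    # lowest intensity detected at itself and everything above it
    all_above <- rev(cumprod(rev(detected))) > 0
    if (any(all_above)) {
      tibble(frequency = fq, threshold_db = grid[which(all_above)[1]],
             censored = FALSE)
    } else {
      tibble(frequency = fq, threshold_db = max(grid) + steps[1],
             censored = TRUE)
    }
  })
}

#' P1/N1 features of an averaged ABR trace
#'
#' P1 is the first local maximum after stimulus onset within the search
#' window; N1 is the first local minimum after P1. To keep "first local
#' maximum" meaningful on noisy averages, candidate peaks are located on
#' a lightly Gaussian-smoothed copy of the trace (only maxima reaching
#' `min_height_frac` of the window's smoothed maximum count), and the
#' reported latency and amplitudes are then read from the raw trace at
#' the local extremum nearest each candidate — so clean traces are
#' measured exactly. P1 latency is measured from onset; the P1-N1
#' amplitude is `V(P1) - V(N1)`.
#'
#' @param trace A tibble with `time_ms`, `voltage_uv`.
#' @param search_window Length-2 `c(from, to)` ms (relative to the record)
#'   in which P1 is sought.
#' @param onset_ms Stimulus onset (ms).
#' @param smooth_ms SD of the Gaussian smoothing used for peak location
#'   (ms); 0 disables smoothing.
#' @param min_height_frac Fraction of the smoothed window maximum a local
#'   maximum must reach to be a P1 candidate.
#' @return One-row tibble: `detected`, `p1_latency_ms`, `p1_uv`, `n1_uv`,
#'   `p1n1_uv`. When no qualifying local maximum exists in the window,
#'   `detected` is `FALSE` and the features are `NA`.
#' @export
abr_features <- function(trace, search_window = c(0.5, 4), onset_ms = 0,
                         smooth_ms = 0.25, min_height_frac = 0.4) {
  t <- trace$time_ms
  v <- trace$voltage_uv
  n <- length(v)
  none <- tibble(detected = FALSE, p1_latency_ms = NA_real_, p1_uv = NA_real_,
                 n1_uv = NA_real_, p1n1_uv = NA_real_)
  if (n < 3L) return(none)
  dt <- t[2] - t[1]
  vs <- if (smooth_ms > 0) gaussian_smooth(v, smooth_ms / dt) else v

  interior <- 2:(n - 1)
  is_max <- vs[interior] > vs[interior - 1] & vs[interior] >= vs[interior + 1]
  is_min <- vs[interior] < vs[interior - 1] & vs[interior] <= vs[interior + 1]
  in_win <- t[interior] > onset_ms & t[interior] >= search_window[1] &
    t[interior] <= search_window[2]
  if (!any(in_win)) return(none)
  height_floor <- min_height_frac * max(vs[interior][in_win])
  cand_p1 <- interior[is_max & in_win & vs[interior] >= height_floor]
  if (length(cand_p1) == 0L) return(none)
  ip1 <- refine_extremum(v, cand_p1[1], ceiling(smooth_ms / dt) + 1, max)
  cand_n1 <- interior[is_min & interior > ip1]
  if (length(cand_n1) == 0L) return(none)
  in1 <- refine_extremum(v, cand_n1[1], ceiling(smooth_ms / dt) + 1, min)
  if (in1 <= ip1) return(none)
  tibble(
    detected = TRUE,
    p1_latency_ms = t[ip1] - onset_ms,
    p1_uv = v[ip1],
    n1_uv = v[in1],
    p1n1_uv = v[ip1] - v[in1]
  )
}

# Gaussian smoothing with reflected edges; sd in samples.
gaussian_smooth <- function(v, sd_samples) {
  half <- max(1L, ceiling(3 * sd_samples))
  w <- stats::dnorm(seq(-half, half), 0, sd_samples)
  w <- w / sum(w)
  padded <- c(rev(v[seq_len(half)]), v, rev(v[(length(v) - half + 1):length(v)]))
  sm <- stats::filter(padded, w, sides = 2)
  as.numeric(sm[(half + 1):(half + length(v))])
}

# Index of the raw-trace extremum nearest a smoothed candidate index.
refine_extremum <- function(v, i, halfwidth, which_fun) {
  lo <- max(1L, i - halfwidth)
  hi <- min(length(v), i + halfwidth)
  win <- v[lo:hi]
  lo + which(win == which_fun(win))[1] - 1L
}

#' P1/N1 feature table for a whole ABR series
#'
#' Applies [abr_features()] to every frequency-intensity trace of a series.
#'
#' @inheritParams abr_threshold
#' @inheritParams abr_features
#' @return A tibble with one row per (frequency, intensity).
#' @export
abr_feature_table <- function(series, search_window = c(0.5, 4), onset_ms = 0) {
  series |>
    dplyr::group_by(.data$frequency, .data$intensity_db) |>
    dplyr::group_modify(function(tr, key) {
      abr_features(tr, search_window = search_window, onset_ms = onset_ms)
    }) |>
    dplyr::ungroup()
}

#' Extract the 2f1-f2 distortion product from a DPOAE spectrum
#'
#' Reads the amplitude at the spectral bin nearest `2*f1 - f2` and
#' estimates the surrounding noise floor as the mean amplitude of
#' `noise_bins` bins on each side of the DP bin, skipping `guard_bins`
#' immediately adjacent to it and skipping bins at the primaries. The DP
#' is called detected when its amplitude exceeds the noise floor by at
#' least `criterion` dB.
#'
#' @param spectrum A tibble with columns `frequency_hz`, `amplitude_db`
#'   and attributes (or columns) `f1_hz`, `f2_hz`.
#' @param noise_bins Bins averaged on each side (default 5).
#' @param guard_bins Bins skipped next to the DP bin (default 2).
#' @param criterion Detection criterion in dB above the noise floor
#'   (default 6).
#' @return One-row tibble: `dp_hz`, `dp_db`, `noise_db`, `detected`.
#' @export
dp_extract <- function(spectrum, noise_bins = 5, guard_bins = 2,
                       criterion = 6) {
  f <- spectrum$frequency_hz
  a <- spectrum$amplitude_db
  f1 <- attr(spectrum, "f1_hz") %||% spectrum$f1_hz[1]
  f2 <- attr(spectrum, "f2_hz") %||% spectrum$f2_hz[1]
  if (is.null(f1) || is.null(f2)) abort("spectrum must carry f1_hz and f2_hz")
  if (f1 >= f2) abort("f1 must be below f2")
  dp_freq <- 2 * f1 - f2
  if (dp_freq < min(f) || dp_freq > max(f)) {
    abort("2f1-f2 falls outside the spectrum range")
  }
  idp <- which.min(abs(f - dp_freq))
  i1 <- which.min(abs(f - f1))
  i2 <- which.min(abs(f - f2))
  if (idp == i1 || idp == i2) {
    abort("the DP bin collides with a primary-tone bin")
  }
  take <- function(side) {
    step <- if (side == "lo") -1L else 1L
    out <- integer(0)
    i <- idp + step * guard_bins
    while (length(out) < noise_bins) {
      i <- i + step
      if (i < 1L || i > length(f)) break
      if (i == i1 || i == i2) next
      out <- c(out, i)
    }
    out
  }
  nb <- c(take("lo"), take("hi"))
  if (length(nb) == 0L) abort("no noise bins available around the DP bin")
  noise <- mean(a[nb])
  tibble(
    dp_hz = f[idp],
    dp_db = a[idp],
    noise_db = noise,
    detected = a[idp] >= noise + criterion
  )
}

#' DPOAE threshold over ascending stimulus levels
#'
#' Lowest stimulus level at which the distortion product is detected at
#' that level and every higher level (same monotone rule and censoring
#' convention as [abr_threshold()]).
#'
#' @param results A tibble with columns `level_db` (ascending grid) and
#'   `detected` (from [dp_extract()] per level).
#' @return One-row tibble: `threshold_db`, `censored`.
#' @export
dpoae_threshold <- function(results) {
  if (nrow(results) == 0L) abort("no levels supplied")
  results <- dplyr::arrange(as_tibble(results), .data$level_db)
  levels <- results$level_db
  step <- if (length(levels) > 1) diff(levels)[1] else 5
  all_above <- rev(cumprod(rev(results$detected))) > 0
  if (any(all_above)) {
    tibble(threshold_db = levels[which(all_above)[1]], censored = FALSE)
  } else {
    tibble(threshold_db = max(levels) + step, censored = TRUE)
  }
}
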