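#' Frame-to-frame activity from an image sequence
#'
#' Activity at frame `t` is the fraction of pixels whose absolute
#' intensity change from frame `t - 1` exceeds `pixel_delta_threshold`;
#' the first frame's activity is 0 by convention. This mirrors automated
#' video-tracking activity measures (frame-to-frame pixel change).
#'
#' @param frames A 3D array `(height, width, n_frames)` or a list of
#'   equally sized matrices.
#' @param pixel_delta_threshold Minimum absolute intensity change for a
#'   pixel to count as changed.
#' @return A tibble with `frame` and `activity` (fraction in `[0, 1]`).
#' @export
compute_activity <- function(frames, pixel_delta_threshold = 0) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) abort("all frames must share the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) abort("`frames` must be (h, w, n)")
  n <- dim(frames)[3]
  if (n < 2L) abort("need at least 2 frames")
  npix <- prod(dim(frames)[1:2])
  act <- c(0, vapply(2:n, function(i) {
    sum(abs(frames[, , i] - frames[, , i - 1]) > pixel_delta_threshold) / npix
  }, numeric(1)))
  tibble(frame = seq_len(n), activity = act)
}

#' Detect freezing bouts in an activity series
#'
#' Freezing is the absence of all movement; it is scored as a maximal run
#' of frames with activity strictly below `theta` lasting at least
#' `min_duration` seconds. Bout boundaries are frame times; a frame's
#' activity covers the interval up to the next frame.
#'
#' @param trace A tibble with columns `time_s` (strictly increasing) and
#'   `activity`.
#' @param theta Activity threshold (fraction of changed pixels). The study
#'   set its threshold by manual video inspection and does not publish the
#'   value; the default 0.01 is a package choice and should be calibrated
#'   per rig.
#' @param min_duration Minimum bout duration in seconds (default 1).
#' @return A tibble of bouts with `start_s`, `end_s`, `duration_s`,
#'   sorted and disjoint (possibly 0 rows).
#' @export
detect_freezing <- function(trace, theta = 0.01, min_duration = 1) {
  if (nrow(trace) == 0L) abort("empty activity series")
  check_number(theta, "theta", lower = .Machine$double.xmin)
  check_number(min_duration, "min_duration", lower = .Machine$double.xmin)
  t <- trace$time_s
  if (any(diff(t) <= 0)) abort("time must be strictly increasing")
  frozen <- trace$activity < theta
  r <- rle(frozen)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  dt <- median(diff(t))
  keep <- which(r$values)
  if (length(keep) == 0L) {
    return(tibble(start_s = numeric(0), end_s = numeric(0),
                  duration_s = numeric(0)))
  }
  start_s <- t[starts_idx[keep]]
  # a frame's activity state extends to the next frame time
  end_s <- ifelse(ends_idx[keep] < length(t), t[ends_idx[keep] + 1L],
                  t[length(t)] + dt)
  bouts <- tibble(start_s = start_s, end_s = end_s,
                  duration_s = end_s - start_s)
  dplyr::filter(bouts, .data$duration_s >= min_duration)
}

#' Cumulative freezing per time bin
#'
#' @param bouts A [detect_freezing()] result.
#' @param bins A two-column data frame (`start_s`, `end_s`) of analysis
#'   bins; bouts crossing a boundary contribute their overlap to each bin.
#' @return `bins` with a `freezing_s` column appended.
#' @export
freezing_by_bin <- function(bouts, bins) {
  bins <- as_tibble(bins)
  bins$freezing_s <- vapply(seq_len(nrow(bins)), function(i) {
    if (nrow(bouts) == 0L) return(0)
    sum(pmax(0, pmin(bouts$end_s, bins$end_s[i]) -
                pmax(bouts$start_s, bins$start_s[i])))
  }, numeric(1))
  bins
}

#' Cued fear conditioning summary (day 2)
#'
#' Mean activity and cumulative freezing in the two day-2 analysis bins:
#' pre-tone (90-150 s) and post-tone (150-210 s), the bin edge being the
#' day-2 tone onset.
#'
#' @param trace A behavior tibble with `time_s` and `activity` covering at
#'   least 90-210 s; its `tone_onset_s` attribute (or the `tone_onset_s`
#'   argument) sets the bin edge.
#' @param theta,min_duration Passed to [detect_freezing()].
#' @param tone_onset_s Day-2 tone onset in seconds (default from the trace
#'   attribute, else 150).
#' @return A two-row tibble: `bin` ("pre"/"post"), `start_s`, `end_s`,
#'   `mean_activity`, `freezing_s`.
#' @export
fc_summary <- function(trace, theta = 0.01, min_duration = 1,
                       tone_onset_s = NULL) {
  tone_onset_s <- tone_onset_s %||% attr(trace, "tone_onset_s")
  if (is.null(tone_onset_s)) {
    abort("no tone onset annotation: supply `tone_onset_s`")
  }
  bins <- tibble(bin = c("pre", "post"),
                 start_s = c(tone_onset_s - 60, tone_onset_s),
                 end_s = c(tone_onset_s, tone_onset_s + 60))
  if (min(trace$time_s) > bins$start_s[1] + 1e-9 ||
      max(trace$time_s) < bins$end_s[2] - median(diff(trace$time_s)) - 1e-9) {
    abort("trace does not cover the 90-210 s analysis window")
  }
  bouts <- detect_freezing(trace, theta = theta, min_duration = min_duration)
  out <- freezing_by_bin(bouts, bins)
  out$mean_activity <- vapply(seq_len(nrow(bins)), function(i) {
    inb <- trace$time_s >= bins$start_s[i] & trace$time_s < bins$end_s[i]
    mean(trace$activity[inb])
  }, numeric(1))
  out[, c("bin", "start_s", "end_s", "mean_activity", "freezing_s")]
}

#' Open-field metrics: rotations, distance, center time
#'
#' Within the analysis window (default 300-900 s, allowing the animal to
#' adapt first), computes: clockwise and counterclockwise rotations from
#' the accumulated signed angle of the center-to-nose vector (one rotation
#' per full +/-360 degrees; the accumulator resets after each counted
#' rotation and on direction reversal); distance travelled as the summed
#' center-point displacement in cm; and cumulative time spent inside the
#' central square of area `center_area_m2`.
#'
#' @param trace A tibble with `time_s`, center-point columns `cx`, `cy`
#'   and (for rotations) nose columns `nx`, `ny`, all in metres, origin at
#'   the arena corner.
#' @param arena_side_m Arena side length in metres (2.5 m^2 arena:
#'   ~1.581 m).
#' @param center_area_m2 Area of the central zone in m^2 (default 0.4).
#' @param window Analysis window `c(from, to)` in seconds.
#' @return One-row tibble: `rotations_cw`, `rotations_ccw`, `distance_cm`,
#'   `center_s`. Rotations are `NA` when nose tracking is absent.
#' @export
open_field <- function(trace, arena_side_m = sqrt(2.5),
                       center_area_m2 = 0.4, window = c(300, 900)) {
  tr <- dplyr::filter(as_tibble(trace),
                      .data$time_s >= window[1], .data$time_s <= window[2])
  if (nrow(tr) < 2L) abort("trace does not cover the analysis window")

  dist_cm <- sum(sqrt(diff(tr$cx)^2 + diff(tr$cy)^2)) * 100

  half_zone <- sqrt(center_area_m2) / 2
  cx0 <- arena_side_m / 2
  in_center <- abs(tr$cx - cx0) <= half_zone & abs(tr$cy - cx0) <= half_zone
  dt <- diff(tr$time_s)
  center_s <- sum(dt[in_center[-length(in_center)]])

  if (!all(c("nx", "ny") %in% names(tr)) || anyNA(tr$nx) || anyNA(tr$ny)) {
    rot <- c(NA_real_, NA_real_)
  } else {
    heading <- atan2(tr$ny - tr$cy, tr$nx - tr$cx)
    dth <- diff(heading)
    dth <- (dth + pi) %% (2 * pi) - pi  # unwrap to (-pi, pi]
    cw <- 0L; ccw <- 0L; acc <- 0
    for (d in dth) {
      if (sign(d) != 0 && sign(acc) != 0 && sign(d) != sign(acc)) acc <- 0
      acc <- acc + d
      if (acc >= 2 * pi - 1e-9) { ccw <- ccw + 1L; acc <- 0 }
      if (acc <= -(2 * pi - 1e-9)) { cw <- cw + 1L; acc <- 0 }
    }
    rot <- c(cw, ccw)
  }
  tibble(rotations_cw = rot[1], rotations_ccw = rot[2],
         distance_cm = dist_cm, center_s = center_s)
}
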