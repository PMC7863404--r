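#' Cochlear axis polyline
#'
#' The cochlear axis is digitised as an ordered polyline drawn along the
#' pillar-cell region, starting at the apex. Axial positions of cells are
#' arc lengths along this polyline.
#'
#' @param points A data frame (or matrix) of ordered vertex coordinates in
#'   micrometres, columns `x` and `y` (a `z` column is allowed and used if
#'   present). The first vertex is the apex by convention.
#' @return An object of class `oto_polyline`: tibble of vertices with a
#'   `cum_um` cumulative arc-length column; total length in
#'   `attr(, "length_um")`.
#' @export
cochlea_polyline <- function(points) {
  pts <- as_tibble(as.data.frame(points))
  if (!all(c("x", "y") %in% names(pts))) abort("`points` needs x and y columns")
  if (nrow(pts) < 2L) abort("a polyline needs at least 2 points")
  if (!"z" %in% names(pts)) pts$z <- 0
  seg <- sqrt(diff(pts$x)^2 + diff(pts$y)^2 + diff(pts$z)^2)
  if (any(seg <= 0)) abort("consecutive polyline points must be distinct")
  pts$cum_um <- c(0, cumsum(seg))
  structure(pts, length_um = sum(seg), class = c("oto_polyline", class(pts)))
}

# Project points onto the polyline: nearest point on any segment
# (perpendicular foot or vertex); ties broken toward the smaller arc length.
# Returns arc-length positions (um from apex), an out-of-range flag for
# points whose nearest polyline point is a terminal vertex, and the signed
# lateral offset from the polyline (positive on the left of the direction
# of travel, i.e. toward (-ty, tx)).
project_to_polyline <- function(x, y, z = 0, polyline) {
  stopifnot(inherits(polyline, "oto_polyline"))
  px <- polyline$x; py <- polyline$y; pz <- polyline$z
  cum <- polyline$cum_um
  nseg <- length(px) - 1L
  n <- length(x)
  if (length(z) == 1L) z <- rep(z, n)
  pos <- numeric(n)
  beyond <- logical(n)
  lateral <- numeric(n)
  for (i in seq_len(n)) {
    best_d2 <- Inf; best_s <- 0; best_end <- FALSE; best_lat <- 0
    for (k in seq_len(nseg)) {
      vx <- px[k + 1] - px[k]; vy <- py[k + 1] - py[k]; vz <- pz[k + 1] - pz[k]
      len2 <- vx^2 + vy^2 + vz^2
      t <- ((x[i] - px[k]) * vx + (y[i] - py[k]) * vy + (z[i] - pz[k]) * vz) / len2
      tc <- min(max(t, 0), 1)
      dx <- x[i] - (px[k] + tc * vx)
      dy <- y[i] - (py[k] + tc * vy)
      dz <- z[i] - (pz[k] + tc * vz)
      d2 <- dx^2 + dy^2 + dz^2
      s <- cum[k] + tc * sqrt(len2)
      at_end <- (k == 1L && t < 0) || (k == nseg && t > 1)
      if (d2 < best_d2 - 1e-12 || (abs(d2 - best_d2) <= 1e-12 && s < best_s)) {
        best_d2 <- d2; best_s <- s; best_end <- at_end
        lxy <- sqrt(vx^2 + vy^2)
        best_lat <- if (lxy > 0) (-vy * dx + vx * dy) / lxy else 0
      }
    }
    pos[i] <- best_s
    beyond[i] <- best_end
    lateral[i] <- best_lat
  }
  list(position_um = pos, beyond_ends = beyond, lateral_um = lateral)
}

#' Cochleogram: hair-cell counts in bins along the cochlear axis
#'
#' Projects each detection to its nearest point on the axis polyline and
#' counts inner and outer hair cells in contiguous `bin_width` micrometre
#' bins from the apex. The final partial bin is kept; its density is scaled
#' by `bin_width / actual width` so apical/basal extremes are not lost.
#' Detections projecting beyond either polyline end are assigned to the
#' terminal bin and flagged in the `n_flagged` column.
#'
#' @param detections A detection tibble with columns `type` ("IHC"/"OHC")
#'   and either `position_um` (precomputed arc-length position) or
#'   `nucleus_x`/`nucleus_y` (and optionally `nucleus_z`) coordinates to
#'   project.
#' @param polyline A [cochlea_polyline()].
#' @param bin_width Bin width in micrometres (field convention: 100).
#' @return A tibble of class `oto_cochleogram`: `start_um`, `end_um`,
#'   `ihc`, `ohc`, `ihc_per_100um`, `ohc_per_100um`, `n_flagged`.
#' @export
bin_cochleogram <- function(detections, polyline, bin_width = 100) {
  stopifnot(inherits(polyline, "oto_polyline"))
  check_number(bin_width, "bin_width", lower = 1e-9)
  total <- attr(polyline, "length_um")
  if (total < bin_width) abort("polyline shorter than one bin")

  nb <- max(1L, ceiling(total / bin_width - 1e-9))
  starts <- (seq_len(nb) - 1) * bin_width
  ends <- pmin(starts + bin_width, total)

  det <- as_tibble(detections)
  if (nrow(det) == 0) {
    pos <- numeric(0); beyond <- logical(0); type <- character(0)
  } else {
    if (!"type" %in% names(det)) abort("detections need a `type` column")
    if ("position_um" %in% names(det) && !anyNA(det$position_um)) {
      pos <- det$position_um
      beyond <- pos < 0 | pos > total
      pos <- pmin(pmax(pos, 0), total)
    } else {
      zc <- if ("nucleus_z" %in% names(det)) det$nucleus_z else 0
      pr <- project_to_polyline(det$nucleus_x, det$nucleus_y, zc, polyline)
      pos <- pr$position_um
      beyond <- pr$beyond_ends
    }
    type <- toupper(det$type)
  }

  bin_of <- pmin(pmax(findInterval(pos, starts), 1L), nb)
  ihc <- tabulate(bin_of[type == "IHC"], nbins = nb)
  ohc <- tabulate(bin_of[type == "OHC"], nbins = nb)
  flagged <- tabulate(bin_of[beyond], nbins = nb)

  width <- ends - starts
  out <- tibble(
    start_um = starts, end_um = ends,
    ihc = ihc, ohc = ohc,
    ihc_per_100um = ihc * 100 / width,
    ohc_per_100um = ohc * 100 / width,
    n_flagged = flagged
  )
  structure(out, bin_width = bin_width, length_um = total,
            class = c("oto_cochleogram", class(out)))
}

#' Mouse place-frequency map
#'
#' Tonotopic transform between stimulus frequency and cochlear place,
#' `percent from base = a - b * log10(f / kHz)`, with the percentage
#' converted to millimetres from the apex via the organ-of-Corti length
#' `L`: `d_apex = (1 - percent/100) * L`.
#'
#' @param intercept Map intercept `a` in percent distance from the base
#'   (default 156.5, the published mouse map).
#' @param slope Map slope `b` in percent per decade of frequency
#'   (default 82.5).
#' @param length_mm Organ of Corti length `L` in mm (default 5.13).
#' @return An object of class `oto_pfmap`.
#' @export
place_frequency_map <- function(intercept = 156.5, slope = 82.5,
                                length_mm = 5.13) {
  check_number(intercept, "intercept")
  check_number(slope, "slope", lower = 1e-9)
  check_number(length_mm, "length_mm", lower = 1e-9)
  structure(list(intercept = intercept, slope = slope, length_mm = length_mm),
            class = "oto_pfmap")
}

#' Convert between frequency and cochlear place
#'
#' `frequency_to_place()` maps stimulus frequency (kHz) to distance from
#' the apex (mm); `place_to_frequency()` is the exact algebraic inverse.
#' Frequencies whose mapped percent-from-base falls outside `[0, 100]` are
#' rejected with the admissible frequency range.
#'
#' @param f_khz Frequency in kHz.
#' @param d_mm Distance from the apex in mm.
#' @param map A [place_frequency_map()].
#' @return Numeric vector (mm from apex, or kHz).
#' @examples
#' frequency_to_place(12)   # inside the 1.63-1.69 mm window at 12 kHz
#' @export
frequency_to_place <- function(f_khz, map = place_frequency_map()) {
  stopifnot(inherits(map, "oto_pfmap"))
  if (any(f_khz <= 0)) abort("frequency must be positive")
  pct_from_base <- map$intercept - map$slope * log10(f_khz)
  if (any(pct_from_base < 0 | pct_from_base > 100)) {
    fmin <- 10^((map$intercept - 100) / map$slope)
    fmax <- 10^(map$intercept / map$slope)
    abort(sprintf(
      "frequency outside map domain; admissible range is %.3f-%.3f kHz",
      fmin, fmax))
  }
  (1 - pct_from_base / 100) * map$length_mm
}

#' @rdname frequency_to_place
#' @export
place_to_frequency <- function(d_mm, map = place_frequency_map()) {
  stopifnot(inherits(map, "oto_pfmap"))
  if (any(d_mm < 0 | d_mm > map$length_mm)) {
    abort(sprintf("place must lie in [0, %.3f] mm", map$length_mm))
  }
  pct_from_base <- (1 - d_mm / map$length_mm) * 100
  10^((map$intercept - pct_from_base) / map$slope)
}

#' Hair-cell density at a frequency region
#'
#' Mean cell density (per 100 um) of the cochleogram bins overlapping the
#' window centred on the cochlear place of frequency `f_khz`, weighted by
#' each bin's overlap with the window.
#'
#' @param bins A [bin_cochleogram()] result.
#' @param f_khz Stimulus frequency in kHz.
#' @param map A [place_frequency_map()].
#' @param window_mm Window width in mm centred on the place (study
#'   convention for the 12 kHz region: 0.06 mm, i.e. 1.63-1.69 mm).
#' @param type `"OHC"` or `"IHC"`.
#' @return A one-row tibble: `f_khz`, `place_mm`, `window_lo_mm`,
#'   `window_hi_mm`, `density_per_100um`.
#' @export
region_density <- function(bins, f_khz, map = place_frequency_map(),
                           window_mm = 0.06, type = c("OHC", "IHC")) {
  stopifnot(inherits(bins, "oto_cochleogram"))
  type <- match.arg(type)
  check_number(window_mm, "window_mm", lower = 1e-12)
  place_um <- frequency_to_place(f_khz, map) * 1000
  lo <- place_um - window_mm * 1000 / 2
  hi <- place_um + window_mm * 1000 / 2
  total <- attr(bins, "length_um")
  if (lo < 0 || hi > total) abort("window lies outside the cochlea extent")

  dens_col <- if (type == "OHC") bins$ohc_per_100um else bins$ihc_per_100um
  overlap <- pmax(0, pmin(bins$end_um, hi) - pmax(bins$start_um, lo))
  if (sum(overlap) == 0) abort("window overlaps no cochleogram bin")
  tibble(
    f_khz = f_khz,
    place_mm = place_um / 1000,
    window_lo_mm = lo / 1000,
    window_hi_mm = hi / 1000,
    density_per_100um = sum(dens_col * overlap) / sum(overlap)
  )
}
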