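#' Otsu threshold of an intensity array
#'
#' Histogram-based automatic threshold maximizing the between-class
#' variance, computed on 256 equal-width bins between the array minimum
#' and maximum.
#'
#' @param x Numeric array or vector of intensities.
#' @param n_bins Histogram bins (default 256).
#' @return The threshold intensity; `NA` for a constant input.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w <- cumsum(as.numeric(h))
  m <- cumsum(as.numeric(h) * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  w0 <- w[-n_bins]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (total_m - m[-n_bins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  breaks[which.max(between) + 1]
}

#' Segment nuclei in a stack channel
#'
#' Automatic thresholding (Otsu) followed by a 3D watershed: the binary
#' foreground is split at ridges of its Euclidean distance transform,
#' with regional maxima of the distance transform as markers, so touching
#' nuclei separate. Regions smaller than `min_volume` are discarded.
#' Labels are renumbered in raster-scan order of each region's first
#' voxel, so labelling is deterministic given the input.
#'
#' @param stack An [oto_stack()].
#' @param channel Channel to segment (default `"DAPI"`).
#' @param min_volume Minimum region volume in um^3.
#' @param min_seed_radius Minimum distance-transform value (um) for a
#'   regional maximum to seed a region; suppresses noise spurs.
#' @return A tibble of class `oto_segments`, one row per nucleus:
#'   `label`, centroid `x`, `y`, `z` (um, voxel centres at 0-based index
#'   times voxel size), `volume_um3`, `n_voxels`. The dense label array
#'   and voxel size ride along as attributes `labels` and `voxel_size`.
#' @export
segment_nuclei <- function(stack, channel = "DAPI", min_volume = 20,
                           min_seed_radius = 1) {
  stopifnot(inherits(stack, "oto_stack"))
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("channel '%s' not in stack", channel))
  }
  check_number(min_volume, "min_volume", lower = 0)
  img <- stack$channels[[channel]]
  vx <- stack$voxel_size
  empty <- tibble(label = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), volume_um3 = numeric(0),
                  n_voxels = integer(0))

  thr <- otsu_threshold(img)
  if (is.na(thr)) {
    labels <- array(0L, dim = dim(img))
    return(structure(empty, labels = labels, voxel_size = vx,
                     class = c("oto_segments", class(empty))))
  }
  mask <- img > thr
  dim(mask) <- dim(img)
  edt <- cpp_edt(mask, vx)
  markers <- cpp_regional_maxima(edt, mask, min_seed_radius)
  labels <- cpp_watershed(edt, markers, mask)

  voxel_vol <- prod(vx)
  counts <- tabulate(labels[labels > 0])
  keep <- which(counts * voxel_vol >= min_volume)
  if (length(keep) == 0L) {
    labels[] <- 0L
    return(structure(empty, labels = labels, voxel_size = vx,
                     class = c("oto_segments", class(empty))))
  }
  # drop small regions and renumber in raster order of first occurrence
  relab <- integer(length(counts))
  first_idx <- match(keep, labels)
  ord <- keep[order(first_idx)]
  relab[ord] <- seq_along(ord)
  nz <- labels > 0
  labels[nz] <- relab[labels[nz]]

  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  cen <- rowsum((idx - 1) %*% diag(vx), lab) / as.vector(table(lab))
  nvox <- as.integer(table(lab))
  seg <- tibble(
    label = sort(unique(lab)),
    x = cen[, 1], y = cen[, 2], z = cen[, 3],
    volume_um3 = nvox * voxel_vol,
    n_voxels = nvox
  )
  structure(seg, labels = labels, voxel_size = vx,
            class = c("oto_segments", class(seg)))
}

# 1D clustering of lateral offsets into rows: sort, split at gaps wider
# than min_gap. Deterministic; handles 1 to 4 rows.
cluster_rows <- function(offsets, min_gap) {
  ord <- order(offsets)
  so <- offsets[ord]
  breaks <- which(diff(so) > min_gap)
  grp_sorted <- cumsum(c(1L, seq_along(so)[-1] %in% (breaks + 1L)))
  grp <- integer(length(offsets))
  grp[ord] <- grp_sorted
  grp
}

# Assign each offset to the nearest row centre; exact ties go to the
# lower row index and are flagged ambiguous.
assign_to_rows <- function(offs, centers, row_ids, tol = 1e-9) {
  d <- abs(outer(offs, centers, `-`))
  res <- apply(d, 1, function(r) {
    o <- order(r)
    amb <- length(r) > 1 && abs(r[o[1]] - r[o[2]]) < tol
    best <- if (amb) {
      cand <- o[abs(r[o] - r[o[1]]) < tol]
      cand[which.min(row_ids[cand])]
    } else o[1]
    c(best, amb)
  })
  list(row = row_ids[res[1, ]], ambiguous = as.logical(res[2, ]))
}

#' Classify segmented nuclei into IHC and OHC rows
#'
#' Fits a smooth mid-curve through the nucleus centroids (principal-axis
#' rotation followed by a smoothing spline), clusters the signed lateral
#' offsets from that curve into up to four row groups (split at gaps wider
#' than `min_gap`), and assigns each segment to the nearest row. The IHC
#' row is the extreme row whose nuclei are largest (IHC somata and nuclei
#' exceed OHC ones); with a single row everything is typed IHC. OHC rows
#' are numbered 1-3 by increasing distance from the IHC row. Segments
#' equidistant from two rows are assigned to the lower row index and
#' flagged `ambiguous`; no segment is silently dropped. Apical and basal
#' landmarks are read from the myosin-VIIa channel: the z extent of the
#' above-half-max myosin signal in a cylinder around each nucleus, with
#' the landmark xy at the myosin intensity centroid of the top/bottom
#' slab.
#'
#' @param segments An [segment_nuclei()] result (non-empty).
#' @param stack The [oto_stack()] the segments came from.
#' @param geometry Optional row model override: a list with `row_of` (a
#'   function mapping lateral offsets to row indices 0-3). Default NULL:
#'   estimated from the data as described.
#' @param axis Optional [cochlea_polyline()] along the pillar-cell
#'   region. When supplied, lateral offsets are measured from this
#'   polyline instead of a self-estimated mid-curve — far more robust on
#'   specimens with heavy, spatially graded cell loss, where the
#'   self-estimated curve drifts with row occupancy. Axial positions
#'   (`position_um`) are filled in from the projection as well.
#' @param myo_channel Myosin channel name (default `"MYO7A"`).
#' @param min_gap Minimum lateral gap (um) separating row clusters.
#' @param landmark_radius_um Cylinder radius for landmark extraction.
#' @return A tibble of class `oto_detections`, one row per segment:
#'   `cell_id`, `label`, `type`, `row`, `ambiguous`, nucleus centroid
#'   (`nucleus_x/y/z`), `volume_um3`, landmarks (`apical_x/y/z`,
#'   `basal_x/y/z`). Attributes `labels` and `voxel_size` are carried
#'   through for intensity measurements.
#' @export
classify_cells <- function(segments, stack, geometry = NULL, axis = NULL,
                           myo_channel = "MYO7A", min_gap = 4,
                           landmark_radius_um = 4.5) {
  stopifnot(inherits(segments, "oto_segments"))
  if (nrow(segments) == 0L) abort("no segments to classify")
  if (nrow(segments) < 4L && is.null(geometry) && is.null(axis)) {
    abort("too few segments to fit row curves; supply `geometry` or `axis`")
  }

  position_um <- rep(NA_real_, nrow(segments))
  if (!is.null(axis)) {
    pr <- project_to_polyline(segments$x, segments$y, 0, axis)
    offs <- pr$lateral_um
    position_um <- pr$position_um
  } else {
    xy <- cbind(segments$x, segments$y)
    ctr <- colMeans(xy)
    pc <- eigen(stats::cov(xy))$vectors
    e1 <- pc[, 1]
    e2 <- c(-e1[2], e1[1])
    u <- as.vector((xy[, 1] - ctr[1]) * e1[1] + (xy[, 2] - ctr[2]) * e1[2])
    v <- as.vector((xy[, 1] - ctr[1]) * e2[1] + (xy[, 2] - ctr[2]) * e2[2])
    # mid-curve of the cell band; residual offsets separate the rows
    fitted_v <- if (length(unique(u)) > 4) {
      stats::fitted(stats::smooth.spline(u, v, df = min(4, length(u) - 1)))
    } else rep(mean(v), length(v))
    offs <- v - fitted_v
  }

  if (is.null(geometry)) {
    grp <- cluster_rows(offs, min_gap)
    n_rows <- max(grp)
    if (n_rows > 4L) {
      abort(sprintf("found %d candidate rows (expected at most 4); raise `min_gap`",
                    n_rows))
    }
    centers <- vapply(seq_len(n_rows), function(g) mean(offs[grp == g]),
                      numeric(1))
    ord <- order(centers)
    centers <- centers[ord]
    mean_vol <- vapply(ord, function(g) mean(segments$volume_um3[grp == g]),
                       numeric(1))
    if (n_rows == 1L) {
      row_ids <- 0L   # a lone row is the IHC row
    } else {
      ihc_at_low <- mean_vol[1] >= mean_vol[n_rows]
      row_ids <- if (ihc_at_low) seq_len(n_rows) - 1L else rev(seq_len(n_rows) - 1L)
    }
    asg <- assign_to_rows(offs, centers, row_ids)
    row <- asg$row
    ambiguous <- asg$ambiguous
  } else {
    row <- geometry$row_of(offs)
    ambiguous <- rep(FALSE, length(offs))
  }
  type <- ifelse(row == 0L, "IHC", "OHC")

  # landmarks from the myosin channel
  has_myo <- myo_channel %in% names(stack$channels)
  if (!has_myo) {
    warn(sprintf("channel '%s' absent: landmarks set to NA", myo_channel))
  }
  vx <- stack$voxel_size
  lm <- matrix(NA_real_, nrow(segments), 6)
  if (has_myo) {
    myo <- stack$channels[[myo_channel]]
    d3 <- dim(myo)
    xs <- (seq_len(d3[1]) - 1) * vx[1]
    ys <- (seq_len(d3[2]) - 1) * vx[2]
    zs <- (seq_len(d3[3]) - 1) * vx[3]
    for (i in seq_len(nrow(segments))) {
      inx <- which(abs(xs - segments$x[i]) <= landmark_radius_um)
      iny <- which(abs(ys - segments$y[i]) <= landmark_radius_um)
      sub <- myo[inx, iny, , drop = FALSE]
      prof <- apply(sub, 3, max)
      above <- which(prof >= 0.5 * max(prof))
      iz_top <- max(above)
      iz_bot <- min(above)
      slab_xy <- function(iz) {
        sl <- sub[, , iz]
        w <- sum(sl)
        if (w == 0) return(c(segments$x[i], segments$y[i]))
        c(sum(sl * xs[inx]) / w, sum(t(sl) * ys[iny]) / w)
      }
      top <- slab_xy(iz_top)
      bot <- slab_xy(iz_bot)
      lm[i, ] <- c(top, zs[iz_top], bot, zs[iz_bot])
    }
  }

  out <- tibble(
    cell_id = seq_len(nrow(segments)),
    label = segments$label,
    type = type, row = as.integer(row), ambiguous = ambiguous,
    nucleus_x = segments$x, nucleus_y = segments$y, nucleus_z = segments$z,
    position_um = position_um,
    volume_um3 = segments$volume_um3,
    apical_x = lm[, 1], apical_y = lm[, 2], apical_z = lm[, 3],
    basal_x = lm[, 4], basal_y = lm[, 5], basal_z = lm[, 6]
  )
  structure(out, labels = attr(segments, "labels"), voxel_size = vx,
            class = c("oto_detections", class(out)))
}

# Mean channel intensity over each detection's nucleus mask.
cell_channel_intensity <- function(detections, stack, channel) {
  labels <- attr(detections, "labels")
  if (is.null(labels)) abort("detections carry no label array")
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("channel '%s' not in stack", channel))
  }
  img <- stack$channels[[channel]]
  nz <- labels > 0
  sums <- rowsum(img[nz], labels[nz])
  ns <- rowsum(rep(1, sum(nz)), labels[nz])
  means <- setNames(as.vector(sums / ns), rownames(sums))
  unname(means[as.character(detections$label)])
}

#' Control-animal intensity statistics
#'
#' Per-cell-type mean and SD of nuclear channel intensity in an
#' un-injected control specimen, acquired with the same settings. The
#' mean is the background `mu_c` subtracted during normalization; the
#' positivity cutoff is `mu_c + 2 sd_c`.
#'
#' @param detections Control-specimen detections ([classify_cells()]).
#' @param stack The control [oto_stack()].
#' @param channel Intensity channel (default `"GFP"`).
#' @param pooled Pool IHC and OHC into one cutoff (default FALSE:
#'   computed per cell type).
#' @return A tibble of class `oto_control_stats`: `type`, `mu`, `sigma`,
#'   `n`.
#' @export
control_stats <- function(detections, stack, channel = "GFP",
                          pooled = FALSE) {
  I <- cell_channel_intensity(detections, stack, channel)
  d <- tibble(type = if (pooled) "pooled" else detections$type, I = I)
  out <- d |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(mu = mean(.data$I), sigma = sd(.data$I),
                     n = dplyr::n(), .groups = "drop")
  out$sigma[is.na(out$sigma)] <- 0
  structure(out, pooled = pooled, channel = channel,
            class = c("oto_control_stats", class(out)))
}

#' Quantify per-cell transduction against a control
#'
#' For each detected cell, the raw intensity `I` is the mean of the
#' channel over the nucleus mask; the normalized intensity is
#' `(I - mu_c) / mu_c` (background-subtracted, in units of the control
#' mean); and the cell is positive when `I > mu_c + 2 sd_c`, with the
#' control statistics matched by cell type (or pooled, if the control was
#' pooled).
#'
#' @param detections A [classify_cells()] result.
#' @param stack The matching [oto_stack()].
#' @param control A [control_stats()] result.
#' @param channel Intensity channel (default the control's channel).
#' @return The detections tibble with `intensity`, `normalized`, and
#'   `positive` columns appended; per-type transduction rates are
#'   available via [transduction_rate()].
#' @export
gfp_quantify <- function(detections, stack, control, channel = NULL) {
  stopifnot(inherits(control, "oto_control_stats"))
  channel <- channel %||% attr(control, "channel")
  if (any(control$mu == 0)) {
    abort("control mean intensity is zero: normalization undefined")
  }
  I <- cell_channel_intensity(detections, stack, channel)
  key <- if (attr(control, "pooled")) rep("pooled", nrow(detections)) else
    detections$type
  m <- match(key, control$type)
  if (anyNA(m)) abort("control stats missing for some cell type")
  mu <- control$mu[m]
  sg <- control$sigma[m]
  out <- as_tibble(detections)
  out$intensity <- I
  out$normalized <- (I - mu) / mu
  out$positive <- I > mu + 2 * sg
  structure(out, labels = attr(detections, "labels"),
            voxel_size = attr(detections, "voxel_size"),
            class = c("oto_detections", class(out)))
}

#' Transduction rate per cell type
#'
#' @param quantified A [gfp_quantify()] result.
#' @return A tibble: `type`, `n`, `n_positive`, `rate`.
#' @export
transduction_rate <- function(quantified) {
  quantified |>
    as_tibble() |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(n = dplyr::n(), n_positive = sum(.data$positive),
                     rate = mean(.data$positive), .groups = "drop")
}

# Trilinear interpolation of a 3D array at physical positions (um).
interp3 <- function(img, voxel_size, pts) {
  d <- dim(img)
  g <- sweep(pts, 2, voxel_size, `/`)   # 0-based voxel coordinates
  g0 <- floor(g)
  fr <- g - g0
  val <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    i0 <- pmin(pmax(g0[i, ] + 1, 1), d)       # 1-based corners, clamped
    i1 <- pmin(i0 + 1, d)
    f <- fr[i, ]
    c00 <- img[i0[1], i0[2], i0[3]] * (1 - f[1]) + img[i1[1], i0[2], i0[3]] * f[1]
    c10 <- img[i0[1], i1[2], i0[3]] * (1 - f[1]) + img[i1[1], i1[2], i0[3]] * f[1]
    c01 <- img[i0[1], i0[2], i1[3]] * (1 - f[1]) + img[i1[1], i0[2], i1[3]] * f[1]
    c11 <- img[i0[1], i1[2], i1[3]] * (1 - f[1]) + img[i1[1], i1[2], i1[3]] * f[1]
    c0 <- c00 * (1 - f[2]) + c10 * f[2]
    c1 <- c01 * (1 - f[2]) + c11 * f[2]
    val[i] <- c0 * (1 - f[3]) + c1 * f[3]
  }
  val
}

#' FLAG/DAPI line profile across the nuclear envelope
#'
#' Casts a radial line from the nucleus centroid outward, centres it at
#' the nuclear periphery — the position of maximal DAPI along the line —
#' and samples both channels on `[-half_width, +half_width]` around that
#' centre. Each channel is normalized by its own maximum on the line, so
#' profiles are comparable across cells and channels.
#'
#' @param detection A one-row detection (from [classify_cells()]).
#' @param stack The matching [oto_stack()].
#' @param channels Length-2 channel names, `c(signal, reference)`;
#'   default `c("FLAG", "DAPI")` (the reference defines the centre).
#' @param half_width Half-width of the profile (um).
#' @param direction Length-3 direction of the radial line (um space);
#'   default lateral `+y`.
#' @param step Sample spacing (um); default half the smallest voxel side.
#' @return A tibble: `position_um` (0 at the periphery), one normalized
#'   column per channel.
#' @export
envelope_profile <- function(detection, stack, channels = c("FLAG", "DAPI"),
                             half_width = 2, direction = c(0, 1, 0),
                             step = NULL) {
  if (nrow(detection) != 1L) abort("pass exactly one detection row")
  check_number(half_width, "half_width", lower = .Machine$double.xmin)
  missing_ch <- setdiff(channels, names(stack$channels))
  if (length(missing_ch)) {
    abort(paste0("channels absent from stack: ",
                 paste(missing_ch, collapse = ", ")))
  }
  vx <- stack$voxel_size
  step <- step %||% (min(vx) / 2)
  dirn <- direction / sqrt(sum(direction^2))
  c0 <- c(detection$nucleus_x, detection$nucleus_y, detection$nucleus_z)

  ref <- channels[length(channels)]
  reach <- half_width + 8
  t_out <- seq(0, reach, by = step)
  pts_out <- t(vapply(t_out, function(s) c0 + s * dirn, numeric(3)))
  ref_out <- interp3(stack$channels[[ref]], vx, pts_out)
  if (all(ref_out == 0)) abort("reference channel is zero along the line")
  t_center <- t_out[which.max(ref_out)]

  pos <- seq(-half_width, half_width, by = step)
  pts <- t(vapply(pos, function(s) c0 + (t_center + s) * dirn, numeric(3)))
  out <- tibble(position_um = pos)
  for (chn in channels) {
    v <- interp3(stack$channels[[chn]], vx, pts)
    mx <- max(v)
    if (mx == 0) abort(sprintf("channel '%s' is zero along the line", chn))
    out[[tolower(chn)]] <- v / mx
  }
  out
}
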