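# Synthetic raw-data generators with known ground truth.
# Every generator draws from one seeded RNG per call and restores the
# caller's RNG state on exit, so calls are deterministic and side-effect
# free.

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulation parameters for a synthetic organ-of-Corti stack
#'
#' Defines a whole-mount specimen: one inner hair-cell (IHC) row and three
#' outer hair-cell (OHC) rows of soft-edged ellipsoidal nuclei along a
#' gently curved planar cochlear axis, imaged in four channels (DAPI,
#' MYO7A, GFP, FLAG). Each cell body follows a circular arc of radius
#' `cell_arc_radius` from its cuticular plate (apical landmark) down to
#' its basal end, and the nucleus centre sits a programmed arc distance
#' from the apical landmark — so ground-truth arc distances are known by
#' construction, independently of any fitting code. Knockout (`KO`)
#' specimens shift OHC nuclei apically by `nucleus_offset_effect`
#' micrometres and lose OHCs along a survival gradient; `KO_treated`
#' specimens recover a `treated_rescue` fraction of both effects.
#'
#' @param n_cells_per_row Cells in each of the four rows.
#' @param row_spacing Lateral spacing between OHC rows (um).
#' @param cell_spacing Longitudinal cell pitch along the axis (um).
#' @param genotype `"WT"`, `"KO"`, or `"KO_treated"`.
#' @param nucleus_offset_effect Mean apical shift of OHC nuclei under KO
#'   (um). No published effect size in micrometres exists; 3 um is a package default of
#'   the order of one nuclear radius.
#' @param nucleus_jitter_sd SD of per-cell jitter on the programmed
#'   nuclear arc distance (um).
#' @param survival_base,survival_slope OHC survival probability under KO:
#'   `clamp(survival_base + survival_slope * (position/L - 0.5))`. The
#'   default negative slope makes loss stronger toward the base
#'   (high-frequency end); pass a positive slope to reverse the gradient.
#' @param treated_rescue Fraction of the KO nuclear shift and survival
#'   loss reversed in `KO_treated` specimens.
#' @param transduced_fraction Fraction of cells expressing the transgene
#'   (GFP/FLAG positive).
#' @param gfp_mu_on,gfp_sigma_on,gfp_mu_off,gfp_sigma_off Per-cell GFP
#'   intensity distributions (arbitrary units) for transduced and
#'   untransduced cells; `gfp_mu_on` must exceed `gfp_mu_off`.
#' @param noise_sd Additive Gaussian intensity noise (a.u.); the nuclear
#'   DAPI amplitude is 100 a.u., so the default 5 gives SNR 20.
#' @param voxel_size Voxel spacing `(dx, dy, dz)` in um.
#' @param cell_arc_radius Radius of the cell-body arc (um).
#' @param cell_arc_length Apical-to-basal arc length of a cell (um).
#' @param wt_ohc_distance,wt_ihc_distance Programmed wild-type nuclear arc
#'   distances from the cuticular plate (um).
#' @param axis_bow Amplitude of the planar bow of the cochlear axis (um).
#' @param seed Integer seed; same seed and parameters give byte-identical
#'   output.
#' @return A validated parameter list of class `cochlea_sim_params`.
#' @export
cochlea_sim_params <- function(n_cells_per_row = 20,
                               row_spacing = 8,
                               cell_spacing = 10,
                               genotype = c("WT", "KO", "KO_treated"),
                               nucleus_offset_effect = 3,
                               nucleus_jitter_sd = 0.4,
                               survival_base = 0.55,
                               survival_slope = -0.5,
                               treated_rescue = 0.9,
                               transduced_fraction = 0,
                               gfp_mu_on = 150, gfp_sigma_on = 20,
                               gfp_mu_off = 30, gfp_sigma_off = 8,
                               noise_sd = 5,
                               voxel_size = c(0.5, 0.5, 1),
                               cell_arc_radius = 40,
                               cell_arc_length = 15,
                               wt_ohc_distance = 10,
                               wt_ihc_distance = 9,
                               axis_bow = 5,
                               seed = 1) {
  genotype <- match.arg(genotype)
  check_number(n_cells_per_row, "n_cells_per_row", lower = 1)
  check_number(transduced_fraction, "transduced_fraction", 0, 1)
  check_number(treated_rescue, "treated_rescue", 0, 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (any(voxel_size <= 0)) abort("voxel_size must be strictly positive")
  if (gfp_mu_on <= gfp_mu_off) {
    abort("gfp_mu_on must exceed gfp_mu_off for a detectable effect")
  }
  if (nucleus_offset_effect >= cell_arc_length) {
    abort("nuclear shift exceeds the cell arc length")
  }
  if (wt_ohc_distance - nucleus_offset_effect <= 0) {
    abort("KO nuclear distance would be non-positive")
  }
  params <- as.list(environment())
  params$axis_length <- n_cells_per_row * cell_spacing
  class(params) <- "cochlea_sim_params"
  params
}

# Soft-edged ellipsoid intensity: ~amp inside, sigmoidal falloff at the
# boundary (edge width `soft` in normalized radius units).
render_blob <- function(img, center_um, radii_um, amp, voxel_size,
                        soft = 0.15, rim_gain = 0) {
  dims <- dim(img)
  lo <- pmax(1, floor((center_um - 1.6 * radii_um) / voxel_size) + 1)
  hi <- pmin(dims, ceiling((center_um + 1.6 * radii_um) / voxel_size) + 1)
  if (any(lo > hi)) return(img)
  xs <- (lo[1]:hi[1] - 1) * voxel_size[1]
  ys <- (lo[2]:hi[2] - 1) * voxel_size[2]
  zs <- (lo[3]:hi[3] - 1) * voxel_size[3]
  qx <- (xs - center_um[1]) / radii_um[1]
  qy <- (ys - center_um[2]) / radii_um[2]
  qz <- (zs - center_um[3]) / radii_um[3]
  q <- sqrt(outer(outer(qx^2, qy^2, `+`), qz^2, `+`))
  val <- amp / (1 + exp((q - 1) / soft))
  if (rim_gain > 0) {
    # perinuclear rim (heterochromatin-like): brightest at the boundary
    val <- val + amp * rim_gain * exp(-((q - 1)^2) / (2 * soft^2))
  }
  blk <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(blk, val)
  img
}

# Gaussian shell at the ellipsoid boundary (FLAG at the nuclear envelope).
render_shell <- function(img, center_um, radii_um, amp, voxel_size,
                         shell_sigma = 0.4) {
  dims <- dim(img)
  pad <- 3 * shell_sigma
  lo <- pmax(1, floor((center_um - radii_um - pad) / voxel_size) + 1)
  hi <- pmin(dims, ceiling((center_um + radii_um + pad) / voxel_size) + 1)
  if (any(lo > hi)) return(img)
  xs <- (lo[1]:hi[1] - 1) * voxel_size[1]
  ys <- (lo[2]:hi[2] - 1) * voxel_size[2]
  zs <- (lo[3]:hi[3] - 1) * voxel_size[3]
  qx <- (xs - center_um[1]) / radii_um[1]
  qy <- (ys - center_um[2]) / radii_um[2]
  qz <- (zs - center_um[3]) / radii_um[3]
  q <- sqrt(outer(outer(qx^2, qy^2, `+`), qz^2, `+`))
  r_eff <- mean(radii_um)
  val <- amp * exp(-((q - 1) * r_eff)^2 / (2 * shell_sigma^2))
  blk <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(blk, val)
  img
}

#' Generate a synthetic organ-of-Corti image stack with ground truth
#'
#' @param params A [cochlea_sim_params()] object.
#' @param render Render the voxel channels (default TRUE). With
#'   `render = FALSE` only the ground-truth table and polyline are
#'   returned (`stack` is NULL); the truth is identical either way for a
#'   given seed, which makes truth-level checks cheap.
#' @return A list with:
#'   * `stack` — an [oto_stack()] with channels DAPI, MYO7A, GFP, FLAG;
#'   * `truth` — per-cell tibble: `cell_id`, `type`, `row`, `alive`,
#'     `transduced`, `arc_distance_um` (programmed nucleus-to-cuticular
#'     plate arc distance), landmark coordinates (`apical_*`, `nucleus_*`,
#'     `basal_*`, um), `position_um` (arc length from the apex along the
#'     axis), `gfp_intensity`;
#'   * `polyline` — the axis polyline (a [cochlea_polyline()]) along the
#'     pillar-cell region, starting at the apex.
#' @export
sim_cochlea_stack <- function(params = cochlea_sim_params(), render = TRUE) {
  stopifnot(inherits(params, "cochlea_sim_params"))
  p <- params
  with_local_seed(p$seed, {
    L <- p$axis_length
    # planar axis parameterized by arc length via dense sampling
    xs_dense <- seq(0, L * 1.02, length.out = 2000)
    y_of <- function(x) p$axis_bow * sin(pi * x / L)
    ys_dense <- y_of(xs_dense)
    cum <- c(0, cumsum(sqrt(diff(xs_dense)^2 + diff(ys_dense)^2)))
    x_at_s <- function(s) approx(cum, xs_dense, xout = s, rule = 2)$y

    margin_x <- 10
    # lateral frame: IHC on the negative side of the pillar polyline
    offsets <- c(-p$row_spacing, p$row_spacing * c(0.5, 1.5, 2.5))
    margin_y <- p$row_spacing + 8
    z_top <- 4 + p$cell_arc_length + 4   # cuticular plate depth in the stack

    rows <- tibble(
      row = rep(0:3, each = p$n_cells_per_row),
      type = rep(c("IHC", "OHC", "OHC", "OHC"), each = p$n_cells_per_row),
      k = rep(seq_len(p$n_cells_per_row), times = 4)
    )
    n_cells <- nrow(rows)
    s_pos <- (rows$k - 0.5) * p$cell_spacing

    # programmed nuclear arc distance
    base_dist <- ifelse(rows$type == "IHC", p$wt_ihc_distance,
                        p$wt_ohc_distance)
    shift <- switch(p$genotype,
      WT = 0,
      KO = p$nucleus_offset_effect,
      KO_treated = p$nucleus_offset_effect * (1 - p$treated_rescue))
    dist_n <- base_dist - ifelse(rows$type == "OHC", shift, 0) +
      stats::rnorm(n_cells, 0, p$nucleus_jitter_sd)
    dist_n <- pmin(pmax(dist_n, 1), p$cell_arc_length - 1)

    # survival (OHC only; IHCs survive in this disease model)
    if (p$genotype == "WT") {
      p_alive <- rep(1, n_cells)
    } else {
      ps <- pmin(pmax(p$survival_base +
                        p$survival_slope * (s_pos / L - 0.5), 0), 1)
      if (p$genotype == "KO_treated") ps <- ps + p$treated_rescue * (1 - ps)
      p_alive <- ifelse(rows$type == "IHC", 1, ps)
    }
    alive <- stats::runif(n_cells) < p_alive
    transduced <- stats::runif(n_cells) < p$transduced_fraction
    gfp_int <- ifelse(transduced,
                      stats::rnorm(n_cells, p$gfp_mu_on, p$gfp_sigma_on),
                      stats::rnorm(n_cells, p$gfp_mu_off, p$gfp_sigma_off))
    gfp_int <- pmax(gfp_int, 0)

    # geometry per cell: foot on the axis, arc in the (lateral, -z) plane
    xa <- x_at_s(s_pos)
    ya <- y_of(xa)
    # unit tangent / normal of the axis at each foot
    eps <- 1e-3
    tx <- 1; ty_ <- (y_of(xa + eps) - y_of(xa - eps)) / (2 * eps)
    tn <- sqrt(tx^2 + ty_^2)
    nxv <- -ty_ / tn; nyv <- tx / tn     # lateral unit normal (+ = OHC side)
    foot_x <- xa + offsets[rows$row + 1] * nxv + margin_x
    foot_y <- ya + offsets[rows$row + 1] * nyv + margin_y

    R <- p$cell_arc_radius
    arc_pt <- function(u, i) {
      # arc from the apical point, initial tangent straight down (-z),
      # bending toward the lateral normal
      lat <- R * (1 - cos(u / R))
      c(foot_x[i] + lat * nxv[i], foot_y[i] + lat * nyv[i],
        z_top - R * sin(u / R))
    }
    apical <- t(vapply(seq_len(n_cells), function(i) arc_pt(0, i),
                       numeric(3)))
    nucleus <- t(vapply(seq_len(n_cells), function(i) arc_pt(dist_n[i], i),
                        numeric(3)))
    basal <- t(vapply(seq_len(n_cells),
                      function(i) arc_pt(p$cell_arc_length, i), numeric(3)))

    truth <- tibble(
      cell_id = seq_len(n_cells),
      type = rows$type, row = rows$row,
      alive = alive, transduced = transduced,
      arc_distance_um = dist_n,
      apical_x = apical[, 1], apical_y = apical[, 2], apical_z = apical[, 3],
      nucleus_x = nucleus[, 1], nucleus_y = nucleus[, 2],
      nucleus_z = nucleus[, 3],
      basal_x = basal[, 1], basal_y = basal[, 2], basal_z = basal[, 3],
      position_um = s_pos,
      gfp_intensity = gfp_int
    )
    # axis polyline (pillar region), starting at the apex, in stack coords
    s_poly <- seq(0, L, length.out = 101)
    xp <- x_at_s(s_poly)
    polyline <- cochlea_polyline(tibble(x = xp + margin_x,
                                        y = y_of(xp) + margin_y))
    if (!render) {
      return(list(stack = NULL, truth = truth, polyline = polyline))
    }

    # stack extent
    dims_um <- c(L + 2 * margin_x,
                 max(offsets) - min(offsets) + 2 * margin_y + p$axis_bow,
                 z_top + 6)
    dims <- ceiling(dims_um / p$voxel_size)
    blank <- array(0, dim = dims)
    ch <- list(DAPI = blank, MYO7A = blank, GFP = blank, FLAG = blank)

    nuc_r <- function(type) if (type == "IHC") rep(2.6, 3) else rep(2.2, 3)
    body_r <- function(type) if (type == "IHC") 4 else 3.4

    for (i in seq_len(n_cells)) {
      if (!alive[i]) next
      rr <- nuc_r(rows$type[i])
      ch$DAPI <- render_blob(ch$DAPI, nucleus[i, ], rr, 100, p$voxel_size,
                             rim_gain = 0.8)
      ch$GFP <- render_blob(ch$GFP, nucleus[i, ], rr, gfp_int[i],
                            p$voxel_size)
      if (transduced[i]) {
        ch$FLAG <- render_shell(ch$FLAG, nucleus[i, ], rr, 80, p$voxel_size)
      }
      # myosin-VIIa cell body: soft spheres stamped along the cell arc,
      # centres inset by one body radius so the half-max intensity edge
      # falls exactly at the apical and basal landmarks
      br <- body_r(rows$type[i])
      us <- seq(br, p$cell_arc_length - br, length.out = 9)
      for (u in us) {
        ch$MYO7A <- render_blob(ch$MYO7A, arc_pt(u, i), rep(br, 3), 60,
                                p$voxel_size, soft = 0.2)
      }
    }
    if (p$noise_sd > 0) {
      for (nm in names(ch)) {
        ch[[nm]] <- pmax(ch[[nm]] +
                           array(stats::rnorm(length(ch[[nm]]), 0, p$noise_sd),
                                 dim = dims), 0)
      }
    }

    list(stack = oto_stack(ch, p$voxel_size), truth = truth,
         polyline = polyline)
  })
}

#' Simulation parameters for ABR recordings
#'
#' @param true_threshold True threshold in dB SPL (scalar, recycled over
#'   frequencies, or a named vector). A threshold above the grid is
#'   allowed: the truth table flags it censored (with a warning).
#' @param frequencies Stimulus set; the standard protocol is click plus 6, 12,
#'   18, 24, 30, 35 kHz.
#' @param intensities Intensity grid in dB SPL (standard grid: 10-90 step 5).
#' @param n_sweeps Sweeps averaged per trace (conventionally 512); averaging
#'   divides the single-sweep noise SD by `sqrt(n_sweeps)`.
#' @param p1_latency P1 latency at threshold (ms after onset).
#' @param latency_shift_per_db Latency decrease per dB above threshold
#'   (ms/dB).
#' @param amplitude_growth P1 amplitude growth per dB above threshold
#'   (uV/dB).
#' @param base_p1_amp P1 amplitude at threshold (uV).
#' @param noise_sd Single-sweep noise SD (uV).
#' @param sampling_rate Sampling rate in kHz (>= 8 for ms-scale peaks).
#' @param duration_ms Record length (ms); stimulus onset at `onset_ms`.
#' @param onset_ms Stimulus onset within the record (ms).
#' @param seed Integer seed.
#' @export
abr_sim_params <- function(true_threshold = 35,
                           frequencies = c("click", "6", "12", "18", "24",
                                           "30", "35"),
                           intensities = seq(10, 90, by = 5),
                           n_sweeps = 512,
                           p1_latency = 1.6,
                           latency_shift_per_db = 0.008,
                           amplitude_growth = 0.04,
                           base_p1_amp = 0.5,
                           noise_sd = 2,
                           sampling_rate = 16,
                           duration_ms = 10,
                           onset_ms = 1,
                           seed = 1) {
  if (length(intensities) > 1L &&
      (any(diff(intensities) <= 0) ||
         length(unique(diff(intensities))) != 1L)) {
    abort("intensity grid must be ascending with a uniform step")
  }
  check_number(n_sweeps, "n_sweeps", lower = 1)
  check_number(sampling_rate, "sampling_rate", lower = 8)
  params <- as.list(environment())
  if (is.null(names(params$true_threshold))) {
    params$true_threshold <- setNames(
      rep_len(params$true_threshold, length(frequencies)), frequencies)
  }
  class(params) <- "abr_sim_params"
  params
}

#' Generate an averaged ABR intensity series
#'
#' Below the true threshold the averaged trace is noise only; at and above
#' it a stimulus-locked P1/N1 complex appears whose P1-N1 amplitude grows
#' and whose P1 latency shrinks with intensity. Two independent half
#' averages (`voltage_a`, `voltage_b`) are included so the split-half
#' reproducibility criterion can be exercised; `voltage_uv` is their mean.
#'
#' @param params An [abr_sim_params()] object.
#' @return A list with `series` (long tibble: `frequency`, `intensity_db`,
#'   `time_ms`, `voltage_uv`, `voltage_a`, `voltage_b`) and `truth`
#'   (tibble: `frequency`, `threshold_db`, `censored`).
#' @export
sim_abr_series <- function(params = abr_sim_params()) {
  stopifnot(inherits(params, "abr_sim_params"))
  p <- params
  with_local_seed(p$seed, {
    t_ms <- seq(0, p$duration_ms, by = 1 / p$sampling_rate)
    nt <- length(t_ms)
    half_sd <- p$noise_sd / sqrt(p$n_sweeps / 2)

    truth <- tibble(frequency = p$frequencies,
                    threshold_db = unname(p$true_threshold[p$frequencies]),
                    censored = unname(p$true_threshold[p$frequencies]) >
                      max(p$intensities))
    if (any(truth$censored)) {
      warn("true threshold above the intensity grid: truth marked censored")
    }

    series <- purrr::map_dfr(p$frequencies, function(fq) {
      thr <- p$true_threshold[[fq]]
      purrr::map_dfr(p$intensities, function(I) {
        sig <- numeric(nt)
        if (I >= thr) {
          above <- I - thr
          amp <- p$base_p1_amp + p$amplitude_growth * above
          lat <- max(p$p1_latency - p$latency_shift_per_db * above, 0.3)
          tp1 <- p$onset_ms + lat
          tn1 <- tp1 + 0.7
          sig <- amp * exp(-((t_ms - tp1)^2) / (2 * 0.22^2)) -
            0.8 * amp * exp(-((t_ms - tn1)^2) / (2 * 0.3^2))
        }
        va <- sig + stats::rnorm(nt, 0, half_sd)
        vb <- sig + stats::rnorm(nt, 0, half_sd)
        tibble(frequency = fq, intensity_db = I, time_ms = t_ms,
               voltage_uv = (va + vb) / 2, voltage_a = va, voltage_b = vb)
      })
    })
    list(series = series, truth = truth)
  })
}

#' Generate DPOAE spectra over a stimulus-level series
#'
#' Each spectrum carries the two primaries at `f1 = f2/ratio` and `f2`, a
#' noise floor with dB-scale jitter, and a 2f1-f2 distortion product whose
#' amplitude rises above the noise floor only for stimulus levels at or
#' above the true threshold.
#'
#' @param f2_khz f2 primary frequency (kHz).
#' @param ratio f2/f1 ratio (conventionally 1.2; must exceed 1).
#' @param levels Ascending stimulus levels (dB SPL).
#' @param dp_gain DP growth above threshold (dB per dB of stimulus level).
#' @param dp_onset DP amplitude above the noise floor at threshold (dB).
#' @param true_threshold True DPOAE threshold (dB SPL).
#' @param noise_floor Mean noise-floor amplitude (dB SPL).
#' @param noise_sd_db SD of the per-bin noise amplitude (dB).
#' @param bin_hz Spectral bin spacing (Hz).
#' @param seed Integer seed.
#' @return A tibble of class `oto_dpoae`: `level_db`, `frequency_hz`,
#'   `amplitude_db`, `f1_hz`, `f2_hz`, with the truth threshold in
#'   `attr(, "true_threshold")`.
#' @export
sim_dpoae_levels <- function(f2_khz = 12, ratio = 1.2,
                             levels = seq(10, 80, by = 5),
                             dp_gain = 1, dp_onset = 10,
                             true_threshold = 40,
                             noise_floor = -15, noise_sd_db = 2,
                             bin_hz = 50, seed = 1) {
  if (ratio <= 1) abort("ratio must exceed 1 (f1 must be below f2)")
  if (any(diff(levels) <= 0)) abort("levels must be ascending")
  f2 <- f2_khz * 1000
  f1 <- f2 / ratio
  dp <- 2 * f1 - f2
  with_local_seed(seed, {
    freqs <- seq(floor(0.7 * dp), ceiling(1.15 * f2), by = bin_hz)
    i_dp <- which.min(abs(freqs - dp))
    i_f1 <- which.min(abs(freqs - f1))
    i_f2 <- which.min(abs(freqs - f2))
    out <- purrr::map_dfr(levels, function(lv) {
      amp <- noise_floor + stats::rnorm(length(freqs), 0, noise_sd_db)
      amp[i_f1] <- lv
      amp[i_f2] <- lv
      if (lv >= true_threshold) {
        amp[i_dp] <- noise_floor + dp_onset + dp_gain * (lv - true_threshold)
      }
      tibble(level_db = lv, frequency_hz = freqs, amplitude_db = amp,
             f1_hz = f1, f2_hz = f2)
    })
    structure(out, true_threshold = true_threshold,
              class = c("oto_dpoae", class(out)))
  })
}

#' Cued fear-conditioning protocol
#'
#' Day 1: 90 s baseline, then a 20 s tone pip at 6 kHz followed by a 2 s
#' 0.7 mA shock, a 60 s inter-trial interval, and a second tone + shock.
#' Day 2: 150 s baseline, then the same tone for 150 s with no shock.
#'
#' @param day1_baseline_s,tone_s,tone_khz,shock_s,shock_ma,intertrial_s
#'   Day-1 protocol fields (seconds / kHz / mA).
#' @param day2_baseline_s,day2_tone_s Day-2 fields (seconds).
#' @param frame_rate Video frame rate (Hz).
#' @return A validated list of class `fc_protocol`.
#' @export
fc_protocol <- function(day1_baseline_s = 90, tone_s = 20, tone_khz = 6,
                        shock_s = 2, shock_ma = 0.7, intertrial_s = 60,
                        day2_baseline_s = 150, day2_tone_s = 150,
                        frame_rate = 10) {
  check_number(frame_rate, "frame_rate", lower = .Machine$double.xmin)
  for (v in c(day1_baseline_s, tone_s, shock_s, intertrial_s,
              day2_baseline_s, day2_tone_s)) {
    check_number(v, "protocol durations", lower = .Machine$double.xmin)
  }
  structure(as.list(environment()), class = "fc_protocol")
}

#' Generate a day-2 fear-conditioning behavior trace
#'
#' Hearing animals freeze after the day-2 tone onset (with latency
#' `freeze_latency` and a total frozen fraction `freeze_fraction` of the
#' tone period); deaf animals freeze the same total amount but at times
#' drawn uniformly over the whole session, independent of the tone. The
#' activity channel is ~0.2 while moving and exactly 0 inside bouts, and
#' the returned truth bout table matches the activity channel exactly.
#'
#' @param protocol An [fc_protocol()].
#' @param phenotype `"hearing"` or `"deaf"`.
#' @param freeze_latency Latency from tone onset to first bout (s).
#' @param freeze_fraction Fraction of the tone period spent frozen.
#' @param seed Integer seed.
#' @return A list with `trace` (tibble: `frame`, `time_s`, `activity`,
#'   `cx`, `cy`, `nx`, `ny`; attribute `tone_onset_s`) and `truth_bouts`
#'   (tibble `start_s`, `end_s`).
#' @export
sim_behavior_trace <- function(protocol = fc_protocol(),
                               phenotype = c("hearing", "deaf"),
                               freeze_latency = 2,
                               freeze_fraction = 0.8,
                               seed = 1) {
  stopifnot(inherits(protocol, "fc_protocol"))
  phenotype <- match.arg(phenotype)
  check_number(freeze_fraction, "freeze_fraction", 0, 1)
  p <- protocol
  with_local_seed(seed, {
    dur <- p$day2_baseline_s + p$day2_tone_s
    dt <- 1 / p$frame_rate
    time_s <- seq(0, dur - dt, by = dt)
    nf <- length(time_s)
    onset <- p$day2_baseline_s

    total_freeze <- freeze_fraction * p$day2_tone_s
    window <- if (phenotype == "hearing") {
      c(onset + freeze_latency, dur)
    } else c(0, dur)
    total_freeze <- min(total_freeze, diff(window))

    bouts <- tibble(start_s = numeric(0), end_s = numeric(0))
    if (total_freeze > 0) {
      if (total_freeze >= diff(window) - dt / 2) {
        bouts <- tibble(start_s = window[1], end_s = window[2])
      } else {
        # draw bout lengths (2-8 s) until the budget is spent, then place
        # them in order with uniform gaps
        lens <- numeric(0)
        while (sum(lens) < total_freeze) {
          lens <- c(lens, stats::runif(1, 2, 8))
        }
        lens[length(lens)] <- total_freeze - sum(head(lens, -1))
        lens <- lens[lens >= 1]
        slack <- diff(window) - sum(lens)
        gaps <- stats::runif(length(lens) + 1)
        gaps <- gaps / sum(gaps) * slack
        starts <- window[1] + cumsum(gaps[seq_along(lens)]) +
          cumsum(c(0, head(lens, -1)))
        # snap to the frame grid so truth matches the rendered channel
        starts <- round(starts / dt) * dt
        ends <- round((starts + lens) / dt) * dt
        keep <- ends > starts
        bouts <- tibble(start_s = starts[keep], end_s = ends[keep])
      }
    }

    frozen <- rep(FALSE, nf)
    for (i in seq_len(nrow(bouts))) {
      frozen <- frozen | (time_s >= bouts$start_s[i] - dt / 2 &
                            time_s < bouts$end_s[i] - dt / 2)
    }
    activity <- pmax(stats::rnorm(nf, 0.2, 0.04), 0.05)
    activity[frozen] <- 0

    # center-point random walk; stationary while frozen
    step_sd <- 0.01
    dxs <- ifelse(frozen, 0, stats::rnorm(nf, 0, step_sd))
    dys <- ifelse(frozen, 0, stats::rnorm(nf, 0, step_sd))
    cx <- pmin(pmax(0.4 + cumsum(dxs), 0.05), 0.75)
    cy <- pmin(pmax(0.4 + cumsum(dys), 0.05), 0.75)
    heading <- cumsum(ifelse(frozen, 0, stats::rnorm(nf, 0, 0.2)))
    trace <- tibble(frame = seq_len(nf), time_s = time_s,
                    activity = activity, cx = cx, cy = cy,
                    nx = cx + 0.03 * cos(heading),
                    ny = cy + 0.03 * sin(heading))
    attr(trace, "tone_onset_s") <- onset
    attr(trace, "protocol") <- p
    list(trace = trace, truth_bouts = bouts)
  })
}
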