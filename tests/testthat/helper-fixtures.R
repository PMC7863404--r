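# Shared fixtures, built once per session and cached. All synthetic, all
# generated in code.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noiseless 4-row specimen: segmentation/classification ground truth is exact
fix_clean_sim <- function() fixture("clean_sim", function() {
  sim_cochlea_stack(cochlea_sim_params(n_cells_per_row = 12, noise_sd = 0,
                                       seed = 3))
})

# noisy (SNR 20) half-transduced specimen plus an untransduced control
fix_noisy_sim <- function() fixture("noisy_sim", function() {
  sim_cochlea_stack(cochlea_sim_params(n_cells_per_row = 8, noise_sd = 5,
                                       transduced_fraction = 0.5, seed = 11))
})
fix_control_sim <- function() fixture("control_sim", function() {
  sim_cochlea_stack(cochlea_sim_params(n_cells_per_row = 8, noise_sd = 5,
                                       transduced_fraction = 0, seed = 12))
})

fix_clean_detections <- function() fixture("clean_det", function() {
  sim <- fix_clean_sim()
  classify_cells(segment_nuclei(sim$stack), sim$stack)
})

fix_noisy_detections <- function() fixture("noisy_det", function() {
  sim <- fix_noisy_sim()
  classify_cells(segment_nuclei(sim$stack), sim$stack)
})

# index of the nearest truth cell for each detection
match_truth <- function(detections, truth) {
  alive <- truth[truth$alive, ]
  vapply(seq_len(nrow(detections)), function(i) {
    which.min((alive$nucleus_x - detections$nucleus_x[i])^2 +
                (alive$nucleus_y - detections$nucleus_y[i])^2 +
                (alive$nucleus_z - detections$nucleus_z[i])^2)
  }, integer(1))
}

# interval IoU between two bout tables over a common grid
bout_iou <- function(a, b, t_max, dt = 0.05) {
  grid <- seq(0, t_max, by = dt)
  cover <- function(bouts) {
    inb <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(bouts))) {
      inb <- inb | (grid >= bouts$start_s[i] & grid < bouts$end_s[i])
    }
    inb
  }
  ca <- cover(a); cb <- cover(b)
  if (!any(ca | cb)) return(1)
  sum(ca & cb) / sum(ca | cb)
}

# minimal stack/labels pair with nc constant-intensity nuclei, for
# intensity-rule tests
mini_labelled_stack <- function(intensities, voxel = c(1, 1, 1)) {
  nc <- length(intensities)
  dims <- c(4 * nc, 4, 4)
  labels <- array(0L, dim = dims)
  gfp <- array(0, dim = dims)
  for (i in seq_len(nc)) {
    xs <- (4 * (i - 1) + 2):(4 * (i - 1) + 3)
    labels[xs, 2:3, 2:3] <- i
    gfp[xs, 2:3, 2:3] <- intensities[i]
  }
  stack <- oto_stack(list(GFP = gfp), voxel)
  det <- tibble::tibble(cell_id = seq_len(nc), label = seq_len(nc),
                        type = rep("OHC", nc))
  attr(det, "labels") <- labels
  attr(det, "voxel_size") <- voxel
  class(det) <- c("oto_detections", class(det))
  list(stack = stack, detections = det)
}

manual_control <- function(mu, sigma, type = "OHC", pooled = FALSE) {
  out <- tibble::tibble(type = if (pooled) "pooled" else type,
                        mu = mu, sigma = sigma, n = 10L)
  structure(out, pooled = pooled, channel = "GFP",
            class = c("oto_control_stats", class(out)))
}
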