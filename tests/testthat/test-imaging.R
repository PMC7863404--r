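# Nucleus segmentation, row classification, transduction quantification,
# envelope profiles.

test_that("otsu threshold maximizes between-class variance (brute force oracle)", {
  set.seed(9)
  x <- c(stats::rnorm(500, 10, 2), stats::rnorm(200, 60, 5))
  thr <- otsu_threshold(x, n_bins = 64)
  # oracle: evaluate every candidate cut directly
  breaks <- seq(min(x), max(x), length.out = 65)
  bcv <- vapply(breaks[2:64], function(b) {
    lo <- x[x <= b]; hi <- x[x > b]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  best <- breaks[which.max(bcv) + 1]
  expect_lt(abs(thr - best), diff(range(x)) / 32)
  # the threshold separates the two components almost perfectly
  labels <- rep(c(FALSE, TRUE), c(500, 200))
  expect_gte(mean((x > thr) == labels), 0.98)
  expect_true(is.na(otsu_threshold(rep(3, 10))))
})

make_sphere_stack <- function(centers, radius = 3, dims = c(60, 40, 20),
                              voxel = c(1, 1, 1), amp = 100, noise_sd = 0,
                              seed = 1) {
  img <- array(0, dim = dims)
  xs <- (seq_len(dims[1]) - 1) * voxel[1]
  ys <- (seq_len(dims[2]) - 1) * voxel[2]
  zs <- (seq_len(dims[3]) - 1) * voxel[3]
  for (i in seq_len(nrow(centers))) {
    q <- sqrt(outer(outer((xs - centers[i, 1])^2, (ys - centers[i, 2])^2,
                          `+`), (zs - centers[i, 3])^2, `+`)) / radius
    img <- pmax(img, amp / (1 + exp((q - 1) / 0.1)))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- pmax(img + array(stats::rnorm(length(img), 0, noise_sd),
                            dim = dims), 0)
  }
  oto_stack(list(DAPI = img), voxel)
}

test_that("disjoint bright spheres are segmented with sub-voxel centroids", {
  centers <- rbind(c(10, 10, 6), c(25, 10, 12), c(40, 10, 6),
                   c(15, 28, 10), c(45, 28, 14))
  stack <- make_sphere_stack(centers, noise_sd = 5)  # SNR 20
  seg <- segment_nuclei(stack, min_volume = 20)
  expect_equal(nrow(seg), 5)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((seg$x - centers[i, 1])^2 + (seg$y - centers[i, 2])^2 +
                (seg$z - centers[i, 3])^2)
    expect_lt(min(d), 1)   # < 1 voxel
  }
  # labels partition the foreground: volumes are disjoint by construction
  labels <- attr(seg, "labels")
  expect_equal(sum(labels > 0), sum(seg$n_voxels))
})

test_that("degenerate channels yield zero segments, missing channels reject", {
  zero <- oto_stack(list(DAPI = array(0, c(10, 10, 5))), c(1, 1, 1))
  expect_equal(nrow(segment_nuclei(zero)), 0)
  flat <- oto_stack(list(DAPI = array(7, c(10, 10, 5))), c(1, 1, 1))
  expect_equal(nrow(segment_nuclei(flat)), 0)
  expect_error(segment_nuclei(zero, channel = "GFP"), "not in stack")
})

test_that("watershed splits spheres overlapping by 20% of radius", {
  r <- 4
  centers <- rbind(c(15, 10, 10), c(15 + 1.8 * r, 10, 10))
  stack <- make_sphere_stack(centers, radius = r, dims = c(40, 20, 20))
  seg <- segment_nuclei(stack, min_volume = 20)
  expect_equal(nrow(seg), 2)
  expect_lt(abs(seg$x[1] - 15), 1)
  expect_lt(abs(seg$x[2] - (15 + 1.8 * r)), 1)
})

test_that("noiseless stack detections match ground truth exactly", {
  sim <- fix_clean_sim()
  det <- fix_clean_detections()
  truth_alive <- sim$truth[sim$truth$alive, ]
  expect_equal(nrow(det), nrow(truth_alive))
  m <- match_truth(det, sim$truth)
  expect_equal(sort(m), seq_len(nrow(truth_alive)))  # one-to-one
  expect_equal(det$type, truth_alive$type[m])
  expect_equal(det$row, truth_alive$row[m])
  # nuclear centroids within one voxel diagonal
  err <- sqrt((det$nucleus_x - truth_alive$nucleus_x[m])^2 +
                (det$nucleus_y - truth_alive$nucleus_y[m])^2 +
                (det$nucleus_z - truth_alive$nucleus_z[m])^2)
  expect_lt(max(err), sqrt(sum(c(0.5, 0.5, 1)^2)))
})

test_that("a lone row is typed IHC and ties break to the lower row", {
  sim <- fix_clean_sim()
  det <- fix_clean_detections()
  seg <- segment_nuclei(sim$stack)
  ihc_labels <- det$label[det$type == "IHC"]
  sub <- seg[seg$label %in% ihc_labels, ]
  attr(sub, "labels") <- attr(seg, "labels")
  attr(sub, "voxel_size") <- attr(seg, "voxel_size")
  class(sub) <- class(seg)
  det_sub <- classify_cells(sub, sim$stack)
  expect_true(all(det_sub$type == "IHC"))

  asg <- otoquant:::assign_to_rows(c(4, 0.5, 7.9), c(0, 8), c(0L, 1L))
  expect_equal(asg$row, c(0L, 0L, 1L))
  expect_equal(asg$ambiguous, c(TRUE, FALSE, FALSE))
})

test_that("stacks round-trip through multi-page TIFF with sidecar metadata", {
  set.seed(13)
  ch <- list(DAPI = array(stats::runif(6 * 5 * 4, 0, 90), c(6, 5, 4)),
             GFP = array(stats::runif(6 * 5 * 4, 0, 40), c(6, 5, 4)))
  stack <- oto_stack(ch, c(0.5, 0.5, 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(stack, path)
  back <- read_stack_tiff(path)
  expect_equal(names(back$channels), c("DAPI", "GFP"))
  expect_equal(back$voxel_size, c(0.5, 0.5, 1))
  expect_equal(back$channels$DAPI, ch$DAPI, tolerance = 1e-6)
  expect_equal(back$channels$GFP, ch$GFP, tolerance = 1e-6)
})

test_that("too few segments for a row fit are rejected with a diagnostic", {
  sim <- fix_clean_sim()
  seg <- segment_nuclei(sim$stack)
  sub <- seg[1:2, ]
  attr(sub, "labels") <- attr(seg, "labels")
  attr(sub, "voxel_size") <- attr(seg, "voxel_size")
  class(sub) <- class(seg)
  expect_error(classify_cells(sub, sim$stack), "too few segments")
})

test_that("axis-referenced classification survives heavy graded OHC loss", {
  sim <- sim_cochlea_stack(cochlea_sim_params(n_cells_per_row = 12,
                                              genotype = "KO", seed = 42))
  det <- classify_cells(segment_nuclei(sim$stack), sim$stack,
                        axis = sim$polyline)
  truth_alive <- sim$truth[sim$truth$alive, ]
  m <- match_truth(det, sim$truth)
  expect_equal(det$type, truth_alive$type[m])
  expect_equal(det$row, truth_alive$row[m])
  # axial positions from the projection match programmed truth
  expect_lt(max(abs(det$position_um - truth_alive$position_um[m])), 1)
})

test_that("GFP positivity and normalization follow the 2-SD control rule", {
  ms <- mini_labelled_stack(c(15, 13, 20, 10))
  ctl <- manual_control(mu = 10, sigma = 2)
  q <- gfp_quantify(ms$detections, ms$stack, ctl)
  expect_equal(q$intensity, c(15, 13, 20, 10))
  expect_equal(q$normalized, c(0.5, 0.3, 1.0, 0.0))
  # positive iff I > mu + 2 sigma = 14
  expect_equal(q$positive, c(TRUE, FALSE, TRUE, FALSE))
  rate <- transduction_rate(q)
  expect_equal(rate$rate, 0.5)
  expect_equal(rate$n_positive, 2L)

  # I = mu -> normalized 0, negative (already covered by cell 4)
  expect_false(q$positive[4])
  expect_error(gfp_quantify(ms$detections, ms$stack,
                            manual_control(mu = 0, sigma = 1)),
               "normalization undefined")
})

test_that("positivity is invariant under a global intensity gain", {
  ms <- mini_labelled_stack(c(15, 13, 20, 10, 30, 2))
  ctl_cells <- mini_labelled_stack(c(9, 11, 10, 8, 12, 10))
  positives_at_gain <- function(g) {
    scale_stack <- function(s) {
      oto_stack(list(GFP = s$channels$GFP * g), s$voxel_size)
    }
    ctl <- control_stats(ctl_cells$detections, scale_stack(ctl_cells$stack))
    gfp_quantify(ms$detections, scale_stack(ms$stack), ctl)$positive
  }
  base <- positives_at_gain(1)
  expect_equal(positives_at_gain(3.7), base)
  expect_equal(positives_at_gain(0.2), base)
})

test_that("control statistics are computed per cell type", {
  sim <- fix_control_sim()
  det <- classify_cells(segment_nuclei(sim$stack), sim$stack)
  cs <- control_stats(det, sim$stack)
  expect_setequal(cs$type, c("IHC", "OHC"))
  expect_true(all(cs$sigma >= 0))
  # control cells draw from the off distribution (mu 30)
  expect_true(all(abs(cs$mu - 30) < 15))
  pooled <- control_stats(det, sim$stack, pooled = TRUE)
  expect_equal(nrow(pooled), 1)
})

test_that("envelope profile centres on the nuclear periphery", {
  sim <- fix_noisy_sim()
  det <- fix_noisy_detections()
  truth_alive <- sim$truth[sim$truth$alive, ]
  m <- match_truth(det, sim$truth)
  idx <- which(truth_alive$transduced[m])[1]
  prof <- envelope_profile(det[idx, ], sim$stack)
  # FLAG shell was rendered at the nuclear boundary: peak within 1 voxel
  # of the profile centre
  expect_lte(abs(prof$position_um[which.max(prof$flag)]), 1)
  # normalization identity: each channel's max on the line is 1
  expect_equal(max(prof$flag), 1)
  expect_equal(max(prof$dapi), 1)

  # uniform signal channel -> flat normalized profile of 1
  uni <- sim$stack
  uni$channels$FLAG[] <- 5
  prof_u <- envelope_profile(det[idx, ], uni)
  expect_true(all(abs(prof_u$flag - 1) < 1e-12))

  # all-zero channel on the line is rejected
  zero <- sim$stack
  zero$channels$FLAG[] <- 0
  expect_error(envelope_profile(det[idx, ], zero), "zero along the line")
})
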