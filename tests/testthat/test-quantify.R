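make_registered_stack <- function(seed = 21, n = 10, side = 60L, ...) {
  scene <- synthetic_scene(image_size_px = c(side, side), shift_range_px = 0,
                           rot_range_deg = 0, motion_line_prob = 0,
                           seed = seed, ...)
  sim <- simulate_stack(scene, default_scale, n)
  sim$stack$registered <- TRUE
  sim
}

test_that("average_frames is the identity at n=1 and averages exactly", {
  sim <- make_registered_stack(seed = 2, n = 3)
  roi <- full_roi()
  a1 <- average_frames(sim$stack, 1, roi)
  expect_identical(a1$image, sim$stack$frames[[1]])
  same <- frame_stack(rep(sim$stack$frames[1], 10))
  same$registered <- TRUE
  a10 <- average_frames(same, 10, roi)
  expect_equal(a10$image, sim$stack$frames[[1]])
  expect_error(average_frames(sim$stack, 4, roi))
  expect_error(average_frames(sim$stack, 0, roi))
})

test_that("an ROI touching invalid pixels is excluded from averaging", {
  sim <- make_registered_stack(seed = 2, n = 2)
  sim$stack$frames[[2]][5, 5] <- NA
  out <- average_frames(sim$stack, 2, full_roi())
  expect_true(out$excluded)
  expect_match(out$reason, "missing coverage")
})

test_that("averaging reduces pixelwise noise variance ~ 1/n", {
  scene <- quiet_scene(seed = 33, speckle_sigma = 0.3)
  tr <- generate_capillary_map(scene, default_scale)
  frames <- lapply(1:10, function(i) render_frame(tr, scene, i))
  v1 <- mean(vapply(frames, function(f) mean((f - tr$clean_image)^2), numeric(1)))
  avg <- Reduce(`+`, frames) / 10
  v10 <- mean((avg - tr$clean_image)^2)
  expect_equal(v10, v1 / 10, tolerance = 0.2)
})

test_that("binarize_roi produces a 360x360 map and binarizes resolvable stripes to their width", {
  sim <- make_registered_stack(seed = 3, n = 1)
  bin <- binarize_roi(sim$stack$frames[[1]], default_scale)
  expect_identical(dim(bin), c(360L, 360L))

  # resolvable stripes (15 um wide): binarized width within +-2 resized px
  # of the rendered full-width-half-maximum
  scene <- quiet_scene(seed = 14, true_icd_um = 38, true_diameter_um = 15,
                       icd_jitter_frac = 0, tortuosity_amp_um = 0,
                       anastomosis_rate = 0)
  tr <- generate_capillary_map(scene, default_scale)
  bin2 <- binarize_roi(tr$clean_image, default_scale)
  rows <- unique(which(tr$centerline_map, arr.ind = TRUE)[, 1])
  n_stripes <- length(rows)
  width_meas <- mean(colSums(bin2[, 30:330]) / n_stripes)
  width_true_px <- 15 / um_per_px(default_scale, resized = TRUE)
  expect_lt(abs(width_meas - width_true_px), 2)

  expect_warning(b0 <- binarize_roi(matrix(0.4, 60, 60), default_scale),
                 "constant")
  expect_false(any(b0))
})

test_that("dilate_to_mask uses the nearest odd disk and contains its skeleton", {
  sim <- make_registered_stack(seed = 5, n = 1)
  bin <- binarize_roi(sim$stack$frames[[1]], default_scale)
  sk <- skeletonize_roi(bin)
  m <- dilate_to_mask(sk, default_scale, 15)
  expect_equal(m$diameter_px, 9)
  expect_true(all(m$mask[sk$skeleton]))
  # one-resized-pixel diameter leaves the skeleton unchanged
  m1 <- dilate_to_mask(sk, default_scale, um_per_px(default_scale, TRUE))
  expect_identical(m1$mask, sk$skeleton)
  empty <- skeletonize_roi(matrix(FALSE, 30, 30))
  expect_false(any(dilate_to_mask(empty, default_scale)$mask))
})

test_that("compute_snr matches hand arithmetic with population SDs", {
  img <- matrix(0, 2, 2); img[1, 1] <- 1; img[2, 1] <- 3
  img[1, 2] <- 0; img[2, 2] <- 2
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  out <- compute_snr(img, mask)
  expect_equal(out$snr, (2 - 1) / sqrt(1 + 1))   # signal {1,3}, background {0,2}
  expect_equal(out$stats$sigma_signal, 1)

  set.seed(8)
  same <- matrix(stats::rnorm(400), 20)
  m2 <- matrix(rep(c(TRUE, FALSE), 200), 20)
  expect_lt(abs(compute_snr(same, m2)$snr), 0.2)  # same distribution ~ 0
  expect_error(compute_snr(matrix(1, 4, 4), matrix(c(TRUE, FALSE), 4, 4)),
               "degenerate")
})

test_that("SNR scales as sqrt(n) under i.i.d. additive noise with a fixed mask", {
  set.seed(52)
  mask <- matrix(FALSE, 80, 80); mask[, seq(5, 75, by = 10)] <- TRUE
  clean <- ifelse(mask, 0.8, 0.1)
  ratios <- replicate(20, {
    noisy <- function(n) {
      acc <- 0
      for (i in seq_len(n)) acc <- acc + clean + matrix(stats::rnorm(6400, 0, 0.3), 80)
      acc / n
    }
    compute_snr(noisy(10), mask)$snr / compute_snr(noisy(1), mask)$snr
  })
  expect_equal(mean(ratios), sqrt(10), tolerance = 0.15)
})

test_that("adding noise strictly lowers SNR against a fixed mask", {
  scene <- quiet_scene(seed = 44)
  tr <- generate_capillary_map(scene, default_scale)
  up <- resize_bicubic(tr$clean_image, 6)
  mask <- dilate_to_mask(skeletonize_roi(binarize_roi(tr$clean_image, default_scale)),
                         default_scale)
  snr_clean <- compute_snr(up, mask)$snr
  set.seed(101)
  for (i in 1:20) {
    noisy <- up + matrix(stats::rnorm(length(up), 0, 0.1), nrow(up))
    expect_lt(compute_snr(noisy, mask)$snr, snr_clean)
  }
})

test_that("capillary density matches arithmetic and is additive over vessels", {
  roi <- full_roi()
  one <- matrix(FALSE, 360, 360); one[180, ] <- TRUE
  sk1 <- list(skeleton = one, total_length_px_units = 359,
              segments = list(), endpoints = matrix(0, 0, 2))
  class(sk1) <- "skeleton_graph"
  d1 <- capillary_density(sk1, roi, default_scale)
  side_mm <- 60 * um_per_px(default_scale) / 1000
  expect_equal(d1, (359 * um_per_px(default_scale, TRUE) / 1000) / side_mm^2)
  expect_equal(d1, 1.742, tolerance = 0.01)   # ~1/side for a spanning vessel

  fifteen <- matrix(FALSE, 360, 360); fifteen[seq(12, 348, by = 24), ] <- TRUE
  sk15 <- sk1; sk15$skeleton <- fifteen; sk15$total_length_px_units <- 15 * 359
  expect_equal(capillary_density(sk15, roi, default_scale), 15 * d1,
               tolerance = 1e-3)

  empty <- sk1; empty$skeleton[] <- FALSE; empty$total_length_px_units <- 0
  expect_equal(capillary_density(empty, roi, default_scale), 0)
})

test_that("ICD recovers a sinusoidal profile period and flags flat profiles", {
  img <- matrix(rep(0.5 + 0.5 * sin(2 * pi * (1:60) / 4), 60), 60, byrow = FALSE)
  roi <- full_roi(orientation = 0)  # profile along rows
  b <- icd_sampling_box(roi, default_scale)
  b$center_px <- c(30.5, 30.5)
  out <- intercapillary_distance(img, b, default_scale)
  expect_true(out$measurable)
  expect_equal(out$icd_um, 4 * um_per_px(default_scale), tolerance = 1e-6)

  flat <- intercapillary_distance(matrix(0.5, 60, 60), b, default_scale)
  expect_false(flat$measurable)
  expect_true(is.na(flat$icd_um))
})

test_that("ICD recovery is within 10% on jittered parallel capillaries", {
  for (seed in c(5, 6)) {
    scene <- quiet_scene(seed = seed, true_icd_um = 35, icd_jitter_frac = 0.05,
                         tortuosity_amp_um = 2, anastomosis_rate = 0)
    tr <- generate_capillary_map(scene, default_scale)
    b <- icd_sampling_box(full_roi(), default_scale)
    b$center_px <- c(30.5, 30.5)
    out <- intercapillary_distance(tr$clean_image, b, default_scale)
    expect_true(out$measurable)
    expect_lt(abs(out$icd_um - 35) / 35, 0.1)
  }
})

test_that("density recovery is within 10% on noise-free scenes", {
  for (seed in c(5, 15)) {
    scene <- quiet_scene(seed = seed, icd_jitter_frac = 0.05,
                         tortuosity_amp_um = 2)
    tr <- generate_capillary_map(scene, default_scale)
    sk <- skeletonize_roi(binarize_roi(tr$clean_image, default_scale))
    d <- capillary_density(sk, full_roi(), default_scale)
    expect_lt(abs(d - tr$true_density_mm_inv) / tr$true_density_mm_inv, 0.1)
  }
})

test_that("quantify_roi is constant across n on a noise-free stack", {
  sim <- make_registered_stack(seed = 9, n = 4, speckle_sigma = 0,
                               additive_sigma = 0)
  m <- quantify_roi(sim$stack, full_roi(), default_scale, n_values = 1:4)
  expect_equal(nrow(m), 4)
  for (col in c("snr", "n_endpoints", "mean_segment_length_um",
                "density_mm_inv", "icd_um")) {
    expect_equal(length(unique(round(m[[col]], 10))), 1, label = col)
  }
})

test_that("quantify_roi flags excluded ROIs all the way through", {
  sim <- make_registered_stack(seed = 9, n = 3)
  sim$stack$frames[[3]][10, 10] <- NA
  m <- quantify_roi(sim$stack, full_roi(), default_scale, n_values = 1:3)
  expect_true(all(m$excluded))
  expect_true(all(is.na(m$snr)))
})
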