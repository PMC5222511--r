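test_that("rigid transforms compose and invert to identity", {
  t <- rigid_transform(2.3, -1.1, 1.7)
  id <- compose_transforms(t, invert_transform(t))
  expect_lt(abs(id$dx_px), 1e-9)
  expect_lt(abs(id$dy_px), 1e-9)
  expect_lt(abs(id$theta_deg), 1e-12)
})

test_that("apply_transform handles identity, integer shifts and round trips", {
  scene <- quiet_scene(seed = 3, tortuosity_amp_um = 3)
  img <- generate_capillary_map(scene, default_scale)$clean_image
  expect_identical(apply_transform(img, rigid_transform(0, 0, 0)), img)

  delta <- matrix(0, 41, 41); delta[21, 21] <- 1
  moved <- apply_transform(delta, rigid_transform(3, -2, 0))
  expect_equal(which(moved == max(moved, na.rm = TRUE), arr.ind = TRUE)[1, ],
               c(row = 19, col = 24))

  # smooth image: t then inverse(t) returns close to the original
  smooth <- rpcavg:::gaussian_local_mean(img, 12)
  t <- rigid_transform(1.3, -0.7, 0.8)
  back <- apply_transform(apply_transform(smooth, t), invert_transform(t))
  inner <- 15:45
  expect_lt(max(abs(back[inner, inner] - smooth[inner, inner])), 0.02)
})

test_that("apply_transform marks out-of-field pixels invalid and conserves mean", {
  img <- rpcavg:::gaussian_local_mean(matrix(stats::runif(90 * 90), 90), 18)
  sh <- apply_transform(img, rigid_transform(5, 0, 0))
  expect_true(all(is.na(sh[, 1:4])))
  expect_false(anyNA(sh[, 7:90]))
  # fully in-field smooth content: mean conserved within 1%
  t <- rigid_transform(1.2, 0.8, 0.5)
  out <- apply_transform(img, t)
  inner <- 10:81
  expect_equal(mean(out[inner, inner]), mean(img[inner, inner]),
               tolerance = 0.01)
})

test_that("select_reference prefers the artifact-free frame and breaks ties low", {
  scene <- quiet_scene(seed = 12)
  clean <- generate_capillary_map(scene, default_scale)$clean_image
  # motion-artifact lines: rows with signal dropout
  spoiled <- function(img, rows) { img[rows, ] <- img[rows, ] * 0.1; img }
  frames <- list(spoiled(clean, c(10, 30)), spoiled(clean, c(5, 20, 40)),
                 clean, spoiled(clean, 50))
  expect_equal(select_reference(frame_stack(frames)), 3)
  same <- frame_stack(list(clean, clean, clean))
  expect_equal(select_reference(same), 1)
  expect_equal(select_reference(frame_stack(list(clean))), 1)
})

test_that("estimate_rigid recovers exact shifts and flags constant images", {
  scene <- quiet_scene(seed = 3, side = 120L)
  img <- generate_capillary_map(scene, default_scale)$clean_image
  est0 <- estimate_rigid(img, img, rot_range_deg = 0)
  expect_lt(abs(est0$dx_px), 0.1); expect_lt(abs(est0$dy_px), 0.1)

  sh <- apply_transform(img, rigid_transform(3, -2, 0))
  est <- estimate_rigid(sh, img, rot_range_deg = 0)
  expect_lt(abs(est$dx_px - (-3)), 0.1)
  expect_lt(abs(est$dy_px - 2), 0.1)

  expect_error(estimate_rigid(matrix(0.5, nrow(img), ncol(img)), img),
               "unregistrable")
})

test_that("estimate_rigid recovers rotation under speckle", {
  scene <- synthetic_scene(seed = 31, speckle_sigma = 0.2, additive_sigma = 0.03,
                           motion_line_prob = 0, shift_range_px = 0,
                           rot_range_deg = 0)
  tr <- generate_capillary_map(scene, default_scale)
  mov <- apply_transform(tr$clean_image, rigid_transform(0, 0, 1.5))
  set.seed(99)
  mov <- pmax(mov * matrix(stats::rnorm(length(mov), 1, 0.2), nrow(mov)), 0)
  est <- estimate_rigid(mov, tr$clean_image, rot_range_deg = 2.5)
  expect_lt(abs(est$theta_deg - (-1.5)), 0.2)
})

test_that("register_stack meets the residual contract on simulated stacks", {
  scene <- synthetic_scene(seed = 23)  # speckle 0.3, shift +-3 px, rot +-1 deg
  sim <- simulate_stack(scene, default_scale, 5)
  reg <- register_stack(sim$stack, rot_range_deg = 2)
  expect_true(reg$registered)
  expect_identical(reg$frames[[1]], sim$stack$frames[[1]])  # reference untouched
  res_t <- c(); res_r <- c()
  for (i in 2:5) {
    resid <- compose_transforms(sim$truth$true_transforms[[i]],
                                reg$transforms[[i]])
    res_t <- c(res_t, abs(resid$dx_px), abs(resid$dy_px))
    res_r <- c(res_r, abs(resid$theta_deg))
  }
  expect_lte(mean(res_t), 0.5)
  expect_lte(mean(res_r), 0.2)
})

test_that("registering an aligned stack returns near-identity transforms", {
  scene <- quiet_scene(seed = 17, side = 120L, speckle_sigma = 0.15)
  sim <- simulate_stack(scene, default_scale, 3)
  reg <- register_stack(sim$stack, rot_range_deg = 1)
  for (t in reg$transforms) {
    expect_lt(abs(t$dx_px), 0.5); expect_lt(abs(t$dy_px), 0.5)
    expect_lt(abs(t$theta_deg), 0.2)
  }
  one <- register_stack(frame_stack(sim$stack$frames[1]))
  expect_length(one$transforms, 1)
})

test_that("transfer_transforms applies given transforms and validates length", {
  scene <- quiet_scene(seed = 19, side = 120L)
  tr <- generate_capillary_map(scene, default_scale)
  # same geometry at two contrasts: estimate on the bright twin, apply to dim
  bright <- tr$clean_image
  dim_ <- 0.25 * tr$clean_image
  true_t <- rigid_transform(2.2, -1.4, 0)
  stack_dim <- frame_stack(list(bright, apply_transform(dim_, true_t)))
  est <- estimate_rigid(apply_transform(bright, true_t), bright,
                        rot_range_deg = 0)
  # the transform estimated on the bright twin aligns the dim one
  expect_lt(abs(est$dx_px - (-2.2)), 0.2)
  expect_lt(abs(est$dy_px - 1.4), 0.2)
  out <- transfer_transforms(stack_dim, list(rigid_transform(0, 0, 0), est))
  expect_true(out$registered)
  # intensity residual is dominated by double bicubic resampling of the
  # ~1 px vessels; the geometric alignment above is the binding check
  inner <- 20:100
  resid <- out$frames[[2]][inner, inner] - dim_[inner, inner]
  expect_lt(mean(abs(resid), na.rm = TRUE), 0.05)

  ident <- transfer_transforms(stack_dim, list(rigid_transform(0, 0, 0),
                                               rigid_transform(0, 0, 0)))
  expect_identical(ident$frames[[2]], stack_dim$frames[[2]])
  expect_error(transfer_transforms(stack_dim, list(rigid_transform(0, 0, 0))),
               "one transform per frame")
})

test_that("transforms serialize to JSON and back", {
  dir <- withr::local_tempdir()
  stack <- frame_stack(list(matrix(stats::runif(100), 10)))
  stack$registered <- TRUE
  stack$transforms <- list(rigid_transform(1.25, -0.5, 0.75))
  p <- file.path(dir, "t.json")
  write_transforms_json(stack, p)
  back <- read_transforms_json(p)
  expect_equal(back$transforms[[1]]$dx_px, 1.25)
  expect_equal(back$transforms[[1]]$theta_deg, 0.75)
})
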