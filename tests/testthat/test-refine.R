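test_that("repeat remapping yields exactly one box per 8 nm repeat", {
  fx <- fx_phantom()
  mg <- simulate_micrograph(fx$vol, fx$spec, size = c(256, 128),
                            rot = 20, theta = 0, snr = Inf,
                            projector = fx$projector)
  # straight vertical filament: 256 px * 5 A = 1280 A of visible length
  n_pts <- 8
  pts <- cbind(seq(40, 216, length.out = n_pts), rep(64.5, n_pts))
  st <- remap_repeats(mg$image, pts, psis = rep(0, n_pts),
                      shifts = matrix(0, n_pts, 2), repeat_A = 80,
                      pixel_size = 5, box_size = 48)
  ctrs <- st$source_positions
  expect_gt(length(st), 1)
  # unique centers at 80 A spacing along the axis
  expect_true(!anyDuplicated(round(ctrs[, 1], 3)))
  d <- diff(sort(ctrs[, 1])) * 5
  expect_true(all(abs(d - 80) < 1))
})

test_that("remapped repeats follow a curved centerline at 80 A arc spacing", {
  img <- matrix(0, 360, 360)
  t <- seq(0, 1, length.out = 12)
  pts <- cbind(60 + 240 * t, 180 + 40 * sin(pi * t))
  st <- remap_repeats(img, pts, psis = rep(0, 12),
                      shifts = matrix(0, 12, 2), repeat_A = 80,
                      pixel_size = 5, box_size = 32)
  arc <- diff(st$meta$arc_pos_A)
  expect_true(all(abs(arc - 80) < 1))
})

test_that("repeats at the image edge are dropped and counted", {
  img <- matrix(0, 120, 120)
  pts <- cbind(seq(10, 110, length.out = 6), rep(60, 6))
  st <- remap_repeats(img, pts, psis = rep(0, 6),
                      shifts = matrix(0, 6, 2), repeat_A = 80,
                      pixel_size = 5, box_size = 60)
  expect_gt(attr(st, "dropped"), 0)
})

test_that("refinement improves perturbed alignments monotonically", {
  fx <- fx_phantom()
  set.seed(21)
  nfil <- 3; nrep <- 8
  boxes <- list(); meta <- NULL; recs <- NULL
  for (f in 1:nfil) {
    rot_f <- runif(1, 0, 360)
    sim <- simulate_filament_segments(fx$vol, fx$spec, nrep, rot = rot_f,
                                      tilt = 90, psi = 0, polarity = "+",
                                      snr = 1, seed = 30 + f,
                                      projector = fx$projector)
    boxes <- c(boxes, sim$stack$boxes)
    meta <- rbind(meta, data.frame(filament_id = f,
                                   repeat_index = sim$truth$repeat_index))
    r <- sim$truth
    r$rot <- r$rot + runif(nrep, -4, 4)    # perturb the starting angles
    r$psi <- r$psi + runif(nrep, -3, 3)
    r$score <- 0
    recs <- rbind(recs, r)
  }
  stack <- mt_segment_stack(boxes, fx$grid$voxel, meta = meta)
  # constant 20 A ladder keeps round scores directly comparable
  out <- refine(stack, recs, make_reference(fx$vol, 20), 14, fx$step$rise,
                ladder = c(20, 20, 20), angle_steps = c(2, 1, 1))
  expect_true(out$converged)
  # round 1 scores against the clean starting reference; from round 2 on
  # the reference is self-consistently reconstructed and scores must not
  # degrade
  expect_true(all(diff(out$score_history[-1]) > -0.02))
  expect_s3_class(out$fsc, "fsc_curve")
  expect_true(is.finite(out$resolution))
})

test_that("sub-frame refinement splits movies into three groups of five", {
  fx <- fx_phantom()
  proj <- fx$projector(25, 90, 0, "+")
  frames <- rep(list(proj), 15)
  movies <- list(mt_movie(frames, fx$grid$voxel))
  recs <- data.frame(rot = 25, tilt = 90, psi = 0, dr = 0, dc = 0,
                     polarity = "+", repeat_index = 0, score = 1)
  out <- subframe_refine(movies, recs, fx$vol)
  expect_equal(nrow(out), 3)
  expect_equal(out$sub_group, 0:2)
  expect_true(all(!out$fallback))
  # zero drift: sub-average parameters equal the full-average parameters
  expect_true(all(abs(out$dr) < 0.51 + 1e-9))
  expect_true(all(abs(out$dc) < 0.51 + 1e-9))
  expect_true(all(abs(out$psi) <= 0.5))
})

test_that("sub-frame refinement tracks injected linear drift", {
  fx <- fx_phantom()
  proj <- fx$projector(25, 90, 0, "+")
  drift <- seq(0, 2.8, length.out = 15)   # linear drift along rows
  frames <- lapply(drift, function(d) fourier_shift(proj, d, 0))
  movies <- list(mt_movie(frames, fx$grid$voxel))
  recs <- data.frame(rot = 25, tilt = 90, psi = 0, dr = 0, dc = 0,
                     polarity = "+", repeat_index = 0, score = 1)
  out <- subframe_refine(movies, recs, fx$vol)
  expect_true(all(diff(out$dr) > 0))   # monotone with the drift
})

test_that("short movies fall back to the full average", {
  fx <- fx_phantom()
  proj <- fx$projector(25, 90, 0, "+")
  movies <- list(mt_movie(rep(list(proj), 6), fx$grid$voxel))
  recs <- data.frame(rot = 25, tilt = 90, psi = 0, dr = 0.7, dc = -0.2,
                     polarity = "+", repeat_index = 0, score = 1)
  out <- subframe_refine(movies, recs, fx$vol)
  expect_equal(nrow(out), 1)
  expect_true(out$fallback)
  expect_equal(out$dr, 0.7)
})
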