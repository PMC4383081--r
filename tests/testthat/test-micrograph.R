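test_that("frame alignment recovers injected shifts", {
  fx <- fx_phantom()
  dr <- rbind(c(0, 0), c(3, -2), c(1.5, 2.5), c(-2, 1))
  im <- imaging_params(pixel_size = fx$grid$voxel, n_frames = 4,
                       drift_per_frame = dr, noise_sigma = 0, ctf = FALSE)
  sm <- simulate_movie(fx$vol, im, view = c(20, 90, 0))
  al <- align_frames(sm$movie, max_shift = 6)
  expect_lt(max(abs(al$drifts - dr)), 0.05)

  # identical frames: all zero drifts
  mv <- mt_movie(rep(list(sm$movie$frames[[1]]), 3), fx$grid$voxel)
  al0 <- align_frames(mv)
  expect_lt(max(abs(al0$drifts)), 1e-6)
})

test_that("frame alignment at SNR 0.5 recovers shifts within 0.5 px RMS", {
  # larger frames carry enough whole-image signal for subpixel tracking
  fx <- fx_phantom()
  base <- fx$projector(20, 90, 0, "+")
  big <- rbind(cbind(base, base), cbind(base, base))   # 128 x 128
  sg <- stats::sd(big) / sqrt(0.5)
  dr <- rbind(c(0, 0), c(2, -1), c(3.5, 1.5), c(-1, 2), c(1, 1))
  set.seed(8)
  frames <- lapply(seq_len(nrow(dr)), function(i)
    fourier_shift(big, dr[i, 1], dr[i, 2]) +
      matrix(rnorm(length(big), sd = sg), nrow(big)))
  al <- align_frames(mt_movie(frames, fx$grid$voxel), max_shift = 6)
  expect_lt(sqrt(mean((al$drifts - dr)^2)), 0.5)
})

test_that("frame alignment is equivariant to an extra shift of one frame", {
  fx <- fx_phantom()
  base <- fx$projector(20, 90, 0, "+")
  frames <- list(base, fourier_shift(base, 1, -1), fourier_shift(base, 2, 1))
  al1 <- align_frames(mt_movie(frames, fx$grid$voxel), max_shift = 6)
  frames2 <- frames
  frames2[[3]] <- fourier_shift(frames2[[3]], 1.5, 0.5)
  al2 <- align_frames(mt_movie(frames2, fx$grid$voxel), max_shift = 6)
  expect_equal(al2$drifts[3, ] - al1$drifts[3, ], c(1.5, 0.5),
               tolerance = 0.05)
  expect_equal(al2$drifts[2, ], al1$drifts[2, ], tolerance = 0.05)
})

test_that("segment extraction follows the half-open arc-length convention", {
  img <- matrix(0, 300, 120)
  # straight vertical path of 800 A at 5 A/px = 160 px
  path <- rbind(c(60, 60), c(220, 60))
  st <- extract_segments(img, path, box_size = 40, step = 80,
                         pixel_size = 5)
  expect_equal(length(st), 10)
  d <- diff(st$meta$arc_pos_A)
  expect_true(all(abs(d - 80) < 1e-9))

  expect_warning(
    st0 <- extract_segments(img, rbind(c(10, 60), c(20, 60)),
                            box_size = 40, step = 80, pixel_size = 5),
    "shorter")
  expect_equal(length(st0), 0)
})

test_that("segment centers track a curved centerline", {
  img <- matrix(0, 400, 400)
  t <- seq(0, 1, length.out = 50)
  path <- cbind(50 + 300 * t, 200 + 60 * sin(pi * t))
  st <- extract_segments(img, path, box_size = 32, step = 80,
                         pixel_size = 5)
  # every returned center must lie within 1 px of the generating curve
  # (compare against a densified polyline, not just its vertices)
  td <- seq(0, 1, length.out = 4000)
  dense <- cbind(50 + 300 * td, 200 + 60 * sin(pi * td))
  for (i in seq_len(length(st))) {
    dmin <- min(sqrt(rowSums(sweep(dense, 2,
                                   st$source_positions[i, ])^2)))
    expect_lt(dmin, 1)
  }
})

test_that("Radon in-plane angle estimation is accurate and equivariant", {
  proj <- fx_projection()
  a0 <- estimate_inplane_angle(proj, search = 30)
  expect_lt(abs(a0$angle), 0.5)
  expect_true(a0$confident)

  r10 <- rotate_image(proj, 10)
  a10 <- estimate_inplane_angle(r10, search = 30)
  expect_equal(a10$angle, 10, tolerance = 0.5)

  # rotation equivariance (mod 180): rotating by +7 moves the estimate by +7
  r7 <- rotate_image(proj, 7)
  a7 <- estimate_inplane_angle(r7, search = 30)
  expect_equal(a7$angle - a0$angle, 7, tolerance = 0.5)

  # isotropic noise: no dominant direction (a box large enough that the
  # per-angle variance estimates are stable around their common mean)
  set.seed(5)
  noise <- matrix(rnorm(128 * 128), 128, 128)
  an <- estimate_inplane_angle(noise)
  expect_false(an$confident)
})

test_that("CTF phase flipping is an involution that preserves power", {
  proj <- fx_projection()
  im <- imaging_params(pixel_size = fx_phantom()$grid$voxel, defocus = 1.5)
  f1 <- ctf_phase_flip(proj, im)
  f2 <- ctf_phase_flip(f1, im)
  expect_equal(f2, proj, tolerance = 1e-12)
  expect_equal(sum(Mod(fft(f1))^2), sum(Mod(fft(proj))^2),
               tolerance = 1e-10)
})

test_that("phase flipping restores positive correlation with the projection", {
  fx <- fx_phantom()
  proj <- fx$projector(20, 90, 0, "+")
  im <- imaging_params(pixel_size = fx$grid$voxel, defocus = 1.5)
  ctf_img <- mtseam:::apply_ctf(proj, im)
  raw_cor <- cor(as.vector(ctf_img), as.vector(proj))
  flip_cor <- cor(as.vector(ctf_phase_flip(ctf_img, im)), as.vector(proj))
  expect_gt(flip_cor, raw_cor)
  expect_gt(flip_cor, 0.5)
})

test_that("compressing a filament shortens it by the group factor", {
  set.seed(3)
  boxes <- lapply(1:64, function(i) matrix(rnorm(16 * 16), 16, 16))
  st <- mt_segment_stack(boxes, 5)
  cp <- compress_filament(st, 8)
  expect_equal(nrow(cp), 8 * 16)       # 64 repeats -> 8 repeats long
  # group = 1 is the identity (plain concatenation)
  expect_equal(compress_filament(st, 1), do.call(rbind, boxes))
  # averaging independent noise cuts the variance ~8-fold
  v_in <- mean(vapply(boxes, var1 <- function(b) stats::var(as.vector(b)),
                      numeric(1)))
  v_out <- stats::var(as.vector(cp))
  expect_equal(v_out / v_in, 1 / 8, tolerance = 0.35)
  expect_error(compress_filament(st, 100), "group")
})

test_that("the 80 A layer line reports decoration", {
  fx <- fx_phantom()
  dec <- fx$projector(37, 90, 0, "+")
  und <- project_volume(fx_phantom_bare(), 37, 90, 0)
  px <- fx$grid$voxel
  expect_gt(layer_line_scan(dec, 80, px)$significance, 3)
  expect_lt(layer_line_scan(und, 80, px)$significance, 1.5)
  # the 40 A (monomer) line is present with or without motors
  expect_gt(layer_line_scan(dec, 40, px)$significance, 3)
  expect_gt(layer_line_scan(und, 40, px)$significance, 3)
  set.seed(1)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(abs(layer_line_scan(noise, 80, px)$significance - 1), 0.5)
  expect_error(layer_line_scan(dec, 2 * px - 1, px), "Nyquist")
})
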