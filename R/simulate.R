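# Synthetic filament data with known ground truth: boxed segment stacks
# and whole micrographs built from the periodic-lattice projector.

#' Simulate a stack of boxed segments of one filament
#'
#' Generates per-repeat boxes of a decorated microtubule at a common
#' filament orientation: each box is the periodic-volume projection at the
#' filament's (rot, tilt), rotated in-plane by `psi`, shifted by the
#' repeat's axial phase plus optional jitter, and corrupted with Gaussian
#' noise at the requested signal-to-noise ratio (variance ratio).
#'
#' @param vol rendered filament volume ([render_density()] with
#'   `periodic_z = TRUE`).
#' @param spec the [lattice_spec()] used to render `vol`.
#' @param n_segments number of boxes (one per 8 nm repeat).
#' @param rot,tilt,psi filament orientation, degrees.
#' @param polarity `"+"` or `"-"`.
#' @param snr signal-to-noise ratio (signal variance / noise variance);
#'   `Inf` for noiseless.
#' @param jitter_px sd of random (row, col) shift jitter per box.
#' @param seed integer seed.
#' @param projector optional prebuilt [make_projector()] closure for `vol`.
#' @return list with `stack` ([mt_segment_stack()]), `truth` (data.frame
#'   of per-box rot, tilt, psi, dr, dc, polarity, repeat_index),
#'   `noise_sigma`.
#' @export
simulate_filament_segments <- function(vol, spec, n_segments, rot = 0,
                                       tilt = 90, psi = 0, polarity = "+",
                                       snr = Inf, jitter_px = 0, seed = 1L,
                                       projector = NULL) {
  if (is.null(projector)) projector <- make_projector(vol)
  base <- projector(rot, tilt, 0, polarity)
  if (abs(psi) > 1e-9) base <- rotate_image(base, psi)
  a <- vol$voxel
  repeat_px <- spec$dimer_repeat / a
  sig <- stats::sd(base)
  noise_sigma <- if (is.finite(snr)) sig / sqrt(snr) else 0
  set.seed(seed)
  # axis direction in the image for in-plane angle psi
  axis_dir <- c(cos(psi * pi / 180), sin(psi * pi / 180)) # (drow, dcol)
  boxes <- vector("list", n_segments)
  truth <- vector("list", n_segments)
  for (k in seq_len(n_segments)) {
    # the projection is exactly repeat-periodic along the axis, so the
    # axial phase lives on [-repeat/2, repeat/2)
    phase <- (k - 1) * repeat_px
    phase <- ((phase + repeat_px / 2) %% repeat_px) - repeat_px / 2
    jit <- if (jitter_px > 0) stats::rnorm(2, sd = jitter_px) else c(0, 0)
    dr <- axis_dir[1] * phase + jit[1]
    dc <- axis_dir[2] * phase + jit[2]
    img <- fourier_shift(base, dr, dc)
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = noise_sigma),
                          nrow(img), ncol(img))
    boxes[[k]] <- img
    truth[[k]] <- data.frame(rot = rot, tilt = tilt, psi = psi,
                             dr = dr, dc = dc, polarity = polarity,
                             repeat_index = k - 1)
  }
  truth <- do.call(rbind, truth)
  stack <- mt_segment_stack(boxes, a, box_step = spec$dimer_repeat,
                            meta = data.frame(filament_id = 1L,
                                              repeat_index = truth$repeat_index))
  list(stack = stack, truth = truth, noise_sigma = noise_sigma)
}

#' Simulate a micrograph containing one straight decorated filament
#'
#' Tiles the periodic-volume projection along the filament axis, rotates
#' it to the requested in-plane angle, embeds it in a larger canvas and
#' adds Gaussian noise. The centerline is returned for ground-truth
#' segment extraction checks.
#'
#' @inheritParams simulate_filament_segments
#' @param size micrograph dimension (rows, cols), pixels.
#' @param theta in-plane filament angle, degrees (0 = vertical).
#' @return list with `image`, `centerline` (two-point polyline, rows/cols),
#'   `noise_sigma`, `truth`.
#' @export
simulate_micrograph <- function(vol, spec, size = c(256, 256), rot = 0,
                                tilt = 90, theta = 0, polarity = "+",
                                snr = Inf, seed = 1L, projector = NULL) {
  if (is.null(projector)) projector <- make_projector(vol)
  base <- projector(rot, tilt, 0, polarity)
  nb <- dim(base)[1]
  ntile <- ceiling(1.6 * max(size) / nb) + 1
  long <- do.call(rbind, rep(list(base), ntile))
  big <- max(dim(long)[1], size[1] * 2, size[2] * 2)
  canvas <- matrix(0, big, dim(long)[2])
  r0 <- floor((big - dim(long)[1]) / 2)
  canvas[r0 + seq_len(dim(long)[1]), ] <- long
  # embed into square canvas centered, then rotate
  sq <- matrix(0, big, big)
  c0 <- floor((big - dim(long)[2]) / 2)
  sq[, c0 + seq_len(dim(long)[2])] <- canvas
  if (abs(theta) > 1e-9) sq <- rotate_image(sq, theta, fill = 0)
  # crop center to requested size
  rr <- floor((big - size[1]) / 2) + seq_len(size[1])
  cc <- floor((big - size[2]) / 2) + seq_len(size[2])
  img <- sq[rr, cc]
  sig <- stats::sd(base)
  noise_sigma <- if (is.finite(snr)) sig / sqrt(snr) else 0
  if (noise_sigma > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sigma),
                        nrow(img), ncol(img))
  }
  ctr <- (size + 1) / 2
  th <- theta * pi / 180
  dirv <- c(cos(th), sin(th))
  half_len <- 0.75 * max(size)
  centerline <- rbind(ctr - half_len * dirv, ctr + half_len * dirv)
  list(image = img, centerline = centerline, noise_sigma = noise_sigma,
       truth = list(rot = rot, tilt = tilt, theta = theta,
                    polarity = polarity))
}
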