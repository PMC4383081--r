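# 2D micrograph-level operations: whole-frame motion correction, boxed
# segment extraction along filament paths, Radon in-plane angle estimation,
# CTF phase flipping, compressed-filament diagnostics and layer-line
# detection in power spectra.

#' Align and average movie frames
#'
#' Iterative whole-frame alignment against the running average (3 passes)
#' with parabolic subpixel peak refinement. Recovered drifts are reported
#' relative to the first frame (the first frame's drift is 0 by
#' convention).
#'
#' @param movie an [mt_movie()].
#' @param max_shift maximum admissible shift in pixels.
#' @param n_iter alignment passes (default 3).
#' @param lowpass resolution (Angstrom) at which frames are band-limited
#'   for shift *estimation* only (the average is formed from the raw
#'   frames); low-dose frames are shot-noise dominated at high frequency
#'   and whole-frame tracking is far more precise on the band-limited
#'   copies. `Inf` disables the filter.
#' @return list with `drifts` (`n_frames` x 2 matrix, rows = (row, col)
#'   drift in px), `average` (shift-corrected mean image), `reliable`
#'   (logical per frame; FALSE when the peak sat at the search boundary).
#' @export
align_frames <- function(movie, max_shift = 8, n_iter = 3,
                         lowpass = 4 * movie$pixel_size) {
  stopifnot(inherits(movie, "mt_movie"))
  n <- length(movie$frames)
  if (n < 2) stop("frame alignment needs at least 2 frames")
  est <- if (is.finite(lowpass))
    lapply(movie$frames, lowpass_field, pixel = movie$pixel_size,
           cutoff = lowpass)
  else movie$frames
  drifts <- matrix(0, n, 2)
  reliable <- rep(TRUE, n)
  ref <- Reduce(`+`, est) / n
  for (it in seq_len(n_iter)) {
    aligned <- vector("list", n)
    for (i in seq_len(n)) {
      pk <- xcorr_peak(ref, est[[i]], max_shift = max_shift)
      # ref ~ frame shifted by pk$shift, so the frame's drift is -shift
      drifts[i, ] <- -pk$shift
      reliable[i] <- !pk$at_boundary
      aligned[[i]] <- fourier_shift(est[[i]],
                                    -drifts[i, 1], -drifts[i, 2])
    }
    ref <- Reduce(`+`, aligned) / n
  }
  ref0 <- drifts[1, ]
  drifts <- sweep(drifts, 2, ref0)
  avg <- Reduce(`+`, lapply(seq_len(n), function(i)
    fourier_shift(movie$frames[[i]], -drifts[i, 1] - ref0[1],
                  -drifts[i, 2] - ref0[2]))) / n
  list(drifts = drifts, average = avg, reliable = reliable)
}

# cumulative arc length of a polyline (rows = points)
polyline_arclen <- function(path) {
  seg <- sqrt(rowSums(diff(path)^2))
  c(0, cumsum(seg))
}

# point at arc length s on a polyline
polyline_point <- function(path, arclen, s) {
  i <- findInterval(s, arclen, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(path) - 1)
  f <- (s - arclen[i]) / pmax(arclen[i + 1] - arclen[i], 1e-12)
  path[i, , drop = FALSE] * (1 - f) + path[i + 1, , drop = FALSE] * f
}

#' Extract overlapping boxed segments along a filament path
#'
#' Box centers are placed at arc-length-uniform midpoints: with path length
#' `L` and step `step`, `floor(L / step)` boxes at arc positions
#' `(k + 0.5) * step` (half-open convention). Boxes are sampled with
#' bilinear interpolation; boxes extending beyond the image are dropped
#' with a warning.
#'
#' @param image micrograph matrix.
#' @param path polyline, matrix of (row, col) pixel coordinates.
#' @param box_size box edge in pixels.
#' @param step center spacing in Angstrom.
#' @param pixel_size Angstrom per pixel.
#' @return an [mt_segment_stack()]; empty (with a warning) when the path is
#'   shorter than one box.
#' @export
extract_segments <- function(image, path, box_size, step, pixel_size) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, step > 0, box_size >= 2)
  arclen <- polyline_arclen(path) * pixel_size   # Angstrom
  L <- arclen[length(arclen)]
  if (L < box_size * pixel_size) {
    warning("path shorter than one box; returning empty stack")
    return(mt_segment_stack(list(), pixel_size, box_step = step))
  }
  n <- floor(L / step)
  centers_s <- (seq_len(n) - 0.5) * step
  ctr <- polyline_point(path, arclen / pixel_size, centers_s / pixel_size)
  half <- (box_size - 1) / 2
  off <- seq_len(box_size) - (box_size + 1) / 2
  boxes <- list(); keep <- logical(0); pos <- NULL
  for (i in seq_len(n)) {
    rs <- outer(ctr[i, 1] + off, rep(1, box_size))
    cs <- outer(rep(1, box_size), ctr[i, 2] + off)
    inside <- ctr[i, 1] - half >= 1 && ctr[i, 1] + half <= nrow(image) &&
      ctr[i, 2] - half >= 1 && ctr[i, 2] + half <= ncol(image)
    if (!inside) { keep <- c(keep, FALSE); next }
    boxes[[length(boxes) + 1]] <- bilinear_sample(image, rs, cs, mean(image))
    keep <- c(keep, TRUE)
    pos <- rbind(pos, ctr[i, ])
  }
  if (any(!keep)) warning(sum(!keep), " boxes dropped at image edge")
  mt_segment_stack(boxes, pixel_size, source_positions = pos,
                   box_step = step,
                   meta = data.frame(arc_pos_A = centers_s[keep]))
}

#' Estimate the in-plane filament angle of a segment (Radon search)
#'
#' Rotates the segment over a grid of candidate angles and measures the
#' ratio of the transverse profile variance (sum along the putative
#' filament axis) to the axial profile variance; the ratio is maximal
#' when the filament is exactly vertical, and dividing by the axial
#' variance cancels the uniform variance loss of rotation interpolation
#' so that isotropic noise scores flat. The peak is refined to
#' sub-degree precision by a local 1 degree scan and parabolic
#' interpolation. Angles are measured from the image column axis,
#' counter-clockwise positive, in `[-90, 90)`.
#'
#' @param segment image matrix containing an elongated feature.
#' @param coarse_step coarse angular step in degrees.
#' @param search half-range of the search in degrees (default full 180).
#' @param center prior angle around which to search.
#' @param conf_threshold minimum peak-to-median ratio of the
#'   directionality statistic; below it the estimate is flagged
#'   low-confidence. The default 2 sits above the null distribution of
#'   the interpolation-normalized statistic on isotropic noise.
#' @return list with `angle` (degrees), `confident` (logical), `ratio`.
#' @export
estimate_inplane_angle <- function(segment, coarse_step = 3, search = 90,
                                   center = 0, conf_threshold = 2) {
  prof_var <- function(th) {
    r <- rotate_image(segment, -th)
    stats::var(colSums(r)) / max(stats::var(rowSums(r)),
                                 .Machine$double.xmin)
  }
  angles <- seq(center - search, center + search - coarse_step / 2,
                by = coarse_step)
  angles <- ((angles + 90) %% 180) - 90
  angles <- unique(angles)
  v <- vapply(angles, prof_var, numeric(1))
  best <- angles[which.max(v)]
  fine <- seq(best - coarse_step, best + coarse_step, by = 1)
  vf <- vapply(fine, prof_var, numeric(1))
  i <- which.max(vf)
  ang <- fine[i]
  if (i > 1 && i < length(vf)) {
    den <- vf[i - 1] - 2 * vf[i] + vf[i + 1]
    if (den < 0) ang <- ang + 0.5 * (vf[i - 1] - vf[i + 1]) / den
  }
  ratio <- max(v) / stats::median(v)
  list(angle = ((ang + 90) %% 180) - 90,
       confident = ratio >= conf_threshold, ratio = ratio)
}

#' Flip CTF phases of an image
#'
#' Multiplies every Fourier component by the sign of the analytic CTF at
#' its frequency; the zero-frequency term is left untouched. Applying the
#' operation twice restores the original image.
#'
#' @param image image matrix.
#' @param imaging an [imaging_params()] holding the known defocus.
#' @return phase-flipped image.
#' @export
ctf_phase_flip <- function(image, imaging) {
  d <- dim(image)
  s <- freq_grid_2d(d[1], d[2], imaging$pixel_size)$s
  sg <- sign(ctf_eval(s, imaging))
  sg[s == 0] <- 1
  sg[sg == 0] <- 1
  Re(fft(fft(image) * sg, inverse = TRUE)) / length(image)
}

#' Compress a filament by averaging groups of repeats
#'
#' Averages consecutive groups of `group` pre-aligned repeat boxes and
#' concatenates the averages along the filament (row) axis, yielding a
#' `group`-fold shortened image with improved signal-to-noise.
#'
#' @param stack an [mt_segment_stack()] of axially aligned repeat boxes.
#' @param group repeats per average (>= 1).
#' @return image matrix of the concatenated group averages.
#' @export
compress_filament <- function(stack, group) {
  n <- length(stack$boxes)
  if (group > n) stop("group exceeds the number of repeats (", n, ")")
  n_groups <- floor(n / group)
  rows <- lapply(seq_len(n_groups), function(g) {
    idx <- ((g - 1) * group + 1):(g * group)
    Reduce(`+`, stack$boxes[idx]) / group
  })
  do.call(rbind, rows)
}

# per-row layer-line statistic: mean power over a near-meridian column
# window (meridian itself excluded) for every row of a centered spectrum
layer_row_power <- function(P, meridian_exclude = 1, window = 10) {
  d <- dim(P)
  cc <- floor(d[2] / 2) + 1
  cols <- setdiff((cc - window):(cc + window),
                  (cc - meridian_exclude):(cc + meridian_exclude))
  cols <- cols[cols >= 1 & cols <= d[2]]
  rowMeans(P[, cols, drop = FALSE])
}

#' Scan a power spectrum for a layer line at a given axial spacing
#'
#' Computes the centered power spectrum and the mean power in a
#' near-meridian window (meridian excluded) for every row. The layer-line
#' amplitude is the mean of this statistic over the pair of rows at axial
#' frequency `1/spacing` (+/- 1 Fourier pixel); significance is its ratio
#' to the median of the same statistic over background rows offset 3-8
#' Fourier pixels from the line. The background is floored at a small
#' fraction of the spectral maximum so that noise-free synthetic images do
#' not produce spurious detections from numerically-zero backgrounds.
#'
#' @param image filament image, filament axis along rows.
#' @param spacing axial repeat distance to probe, Angstrom.
#' @param pixel_size Angstrom per pixel.
#' @param meridian_exclude half-width of the excluded meridian band, px.
#' @param window half-width of the near-meridian column window, px.
#' @return list with `amplitude`, `significance`, `row_offset` (Fourier
#'   pixels from the equator).
#' @export
layer_line_scan <- function(image, spacing, pixel_size,
                            meridian_exclude = 1, window = 10) {
  d <- dim(image)
  if (spacing < 2 * pixel_size)
    stop("spacing is beyond the Nyquist limit (", 2 * pixel_size, " A)")
  P <- power_spectrum(image)
  rp <- layer_row_power(P, meridian_exclude, window)
  cr <- floor(d[1] / 2) + 1
  k <- d[1] * pixel_size / spacing   # layer-line offset in Fourier pixels
  in_range <- function(r) r[r >= 1 & r <= d[1] & abs(r - cr) > 1]
  line_rows <- in_range(unique(round(c(cr - k + (-1:1), cr + k + (-1:1)))))
  bg_rows <- setdiff(in_range(unique(round(c(cr - k + c(-(3:8), 3:8),
                                             cr + k + c(-(3:8), 3:8))))),
                     line_rows)
  amp <- mean(rp[line_rows])
  bg <- stats::median(rp[bg_rows])
  floor_bg <- 1e-9 * max(P)
  list(amplitude = amp, significance = amp / max(bg, floor_bg),
       row_offset = k)
}

#' Locate the strongest decoration-dependent layer line
#'
#' Compares the power spectra of a decorated and an undecorated image of
#' the same filament and returns the axial spacing (Angstrom, at
#' Fourier-pixel precision) of the off-equatorial layer line with the
#' largest decorated-to-undecorated power ratio.
#'
#' @param decorated,undecorated filament images, filament axis along rows,
#'   identical dimensions.
#' @param pixel_size Angstrom per pixel.
#' @param min_spacing ignore spacings below this (Angstrom); guards the
#'   near-Nyquist region.
#' @return list with `spacing` (Angstrom), `row_offset` (Fourier pixels),
#'   `ratio` (decorated/undecorated row power).
#' @export
strongest_new_layer_line <- function(decorated, undecorated, pixel_size,
                                     min_spacing = 3 * pixel_size) {
  stopifnot(identical(dim(decorated), dim(undecorated)))
  d <- dim(decorated)
  Pd <- power_spectrum(decorated)
  Pu <- power_spectrum(undecorated)
  rpd <- layer_row_power(Pd)
  rpu <- layer_row_power(Pu)
  cr <- floor(d[1] / 2) + 1
  kmax <- floor(d[1] * pixel_size / min_spacing)
  ks <- 2:min(kmax, floor(d[1] / 2) - 1)
  floor_u <- 1e-9 * max(Pu)
  ratio <- vapply(ks, function(k) {
    rows <- c(cr - k, cr + k)
    rows <- rows[rows >= 1 & rows <= d[1]]
    mean(rpd[rows]) / max(mean(rpu[rows]), floor_u)
  }, numeric(1))
  k_best <- ks[which.max(ratio)]
  list(spacing = d[1] * pixel_size / k_best, row_offset = k_best,
       ratio = max(ratio))
}
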