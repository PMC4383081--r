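# The iterative refinement driver (projection matching against a
# resolution ladder of filtered references), 8 nm repeat remapping, and
# movie sub-frame refinement.

#' Map refined alignments back to unique 8 nm repeat boxes
#'
#' Fits a smooth centerline through the estimated per-segment axis points,
#' computes the axial lattice phase from the segments' axial shifts, and
#' extracts exactly one box per dimer repeat along the filament at the
#' repeat spacing. Repeats whose boxes would extend beyond the image are
#' dropped (counted in the result).
#'
#' @param image micrograph matrix.
#' @param points n x 2 matrix of estimated axis points (row, col), px.
#' @param psis per-segment in-plane angles, degrees.
#' @param shifts n x 2 matrix of refined (dr, dc) shifts, px.
#' @param repeat_A repeat spacing, Angstrom (80 for the tubulin dimer).
#' @param pixel_size Angstrom per pixel.
#' @param box_size box edge, px.
#' @return an [mt_segment_stack()] with `meta$repeat_index`; attribute
#'   `dropped` counts repeats off the image.
#' @export
remap_repeats <- function(image, points, psis, shifts, repeat_A,
                          pixel_size, box_size) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2)
  # order along the dominant direction
  pc <- stats::prcomp(points)
  t_raw <- pc$x[, 1]
  o <- order(t_raw)
  pts <- points[o, , drop = FALSE]
  # arc-length parameterization of the fitted centerline
  tt <- polyline_arclen(pts)
  fit_row <- if (n >= 5) stats::smooth.spline(tt, pts[, 1], df = min(n - 1, 4))
             else stats::lm(pts[, 1] ~ tt)
  fit_col <- if (n >= 5) stats::smooth.spline(tt, pts[, 2], df = min(n - 1, 4))
             else stats::lm(pts[, 2] ~ tt)
  eval_at <- function(fit, s) {
    if (inherits(fit, "smooth.spline")) stats::predict(fit, s)$y
    else unname(stats::predict(fit, data.frame(tt = s)))
  }
  # dense resample for true arc length
  s_dense <- seq(min(tt), max(tt), length.out = 40 * n)
  dense <- cbind(eval_at(fit_row, s_dense), eval_at(fit_col, s_dense))
  arc <- polyline_arclen(dense) * pixel_size            # Angstrom
  L <- arc[length(arc)]
  # axial lattice phase from the alignments (circular mean over repeats)
  ax <- cbind(cos(psis[o] * pi / 180), sin(psis[o] * pi / 180))
  s_axial <- rowSums(shifts[o, , drop = FALSE] * ax) * pixel_size
  seg_arc <- (tt - min(tt)) * pixel_size
  ph <- (seg_arc + s_axial) %% repeat_A
  ang <- 2 * pi * ph / repeat_A
  phase <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * repeat_A) %%
    repeat_A
  centers_arc <- seq(phase, L, by = repeat_A)
  # map arc positions back to pixel coordinates
  idx <- vapply(centers_arc, function(s) which.min(abs(arc - s)), integer(1))
  ctr <- dense[idx, , drop = FALSE]
  half <- (box_size - 1) / 2
  off <- seq_len(box_size) - (box_size + 1) / 2
  boxes <- list(); kept <- integer(0); pos <- NULL
  for (i in seq_len(nrow(ctr))) {
    inside <- ctr[i, 1] - half >= 1 && ctr[i, 1] + half <= nrow(image) &&
      ctr[i, 2] - half >= 1 && ctr[i, 2] + half <= ncol(image)
    if (!inside) next
    rs <- outer(ctr[i, 1] + off, rep(1, box_size))
    cs <- outer(rep(1, box_size), ctr[i, 2] + off)
    boxes[[length(boxes) + 1]] <- bilinear_sample(image, rs, cs, mean(image))
    kept <- c(kept, i)
    pos <- rbind(pos, ctr[i, ])
  }
  out <- mt_segment_stack(boxes, pixel_size, source_positions = pos,
                          box_step = repeat_A,
                          meta = data.frame(repeat_index = kept - 1L,
                                            arc_pos_A = centers_arc[kept]))
  attr(out, "dropped") <- nrow(ctr) - length(kept)
  out
}

#' Iterative projection-matching refinement
#'
#' Runs rounds of local orientation/shift refinement against a reference
#' low-pass filtered at successive ladder resolutions (20, 15, 12, 10
#' Angstrom by default), reconstructing, pseudo-helically symmetrizing and
#' tight-masking after every round. Aborts with a report if the mean
#' correlation score drops by more than 5 percent between rounds.
#'
#' @param stack an [mt_segment_stack()] with `meta$filament_id` and
#'   `meta$repeat_index`.
#' @param records per-segment starting alignments (`rot`, `tilt`, `psi`,
#'   `dr`, `dc`, `polarity`, `repeat_index`).
#' @param initial_ref starting reference [mt_volume()].
#' @param n_pf protofilament count; `rise` the helical rise per
#'   protofilament (Angstrom).
#' @param ladder resolution ladder, Angstrom.
#' @param angle_steps per-round local angular step sizes, degrees.
#' @param max_shift admissible shift, px.
#' @param mask_threshold tight-mask threshold (fraction of max).
#' @param score_drop_tol abort when the mean score drops by more than
#'   this fraction between rounds (references change between rounds, so
#'   moderate drops are expected when the starting reference is clean).
#' @return list: `map` (masked symmetrized full map), `half_maps`,
#'   `records`, `fsc` curve, `resolution`, `score_history`, `mask`,
#'   `converged`.
#' @export
refine <- function(stack, records, initial_ref, n_pf, rise,
                   ladder = c(20, 15, 12, 10),
                   angle_steps = c(2, 1, 0.5, 0.25), max_shift = 8,
                   mask_threshold = 0.2, score_drop_tol = 0.15) {
  stopifnot(length(ladder) >= 1)
  angle_steps <- rep(angle_steps, length.out = length(ladder))
  current <- initial_ref
  mask <- NULL
  fil_id <- stack$meta$filament_id
  score_hist <- numeric(0)
  converged <- TRUE
  fsc_curve <- NULL
  for (round in seq_along(ladder)) {
    ref <- make_reference(current, ladder[round])
    if (!is.null(mask))
      ref <- mt_volume(ref$data * mask$data, ref$voxel, ref$origin)
    pj <- make_projector(ref)
    st <- angle_steps[round]
    for (f in unique(fil_id)) {
      idx <- which(fil_id == f)
      rot0 <- stats::median(records$rot[idx])
      tilt0 <- stats::median(records$tilt[idx])
      pol <- records$polarity[idx[1]]
      bank <- projection_bank(ref, rot0 + st * (-1:1), tilt0 + st * (-1:1),
                              pol, projector = pj)
      for (i in idx) {
        psis <- records$psi[i] + st * (-1:1)
        m <- match_segment(stack$boxes[[i]], bank, psis, max_shift)
        records$rot[i] <- m$rot; records$tilt[i] <- m$tilt
        records$psi[i] <- m$psi
        records$dr[i] <- m$dr; records$dc[i] <- m$dc
        records$score[i] <- m$score
      }
    }
    score_hist <- c(score_hist, mean(records$score))
    if (round > 1 &&
        score_hist[round] < score_hist[round - 1] * (1 - score_drop_tol)) {
      warning("mean score diverged in round ", round, "; aborting refinement")
      converged <- FALSE
      break
    }
    halves <- backproject(stack, records)
    symA <- symmetrize_pseudo_helical(halves$A, n_pf, rise)
    symB <- symmetrize_pseudo_helical(halves$B, n_pf, rise)
    full <- mt_volume((symA$data + symB$data) / 2, symA$voxel, symA$origin)
    mask <- make_tight_mask(full, threshold = mask_threshold)
    fsc_curve <- fsc(symA, symB, mask)
    current <- full
    half_maps <- list(A = symA, B = symB)
  }
  map <- mt_volume(current$data * mask$data, current$voxel, current$origin)
  list(map = map, half_maps = half_maps, records = records,
       fsc = fsc_curve, resolution = resolution_at(fsc_curve),
       score_history = score_hist, mask = mask, converged = converged)
}

#' Refine movie sub-frame averages
#'
#' Splits each segment's movie into `n_groups` sub-averages of
#' `group_size` frames, then locally re-refines shifts and in-plane angle
#' of every sub-average starting from the segment's full-average
#' parameters. Segments whose movies have too few frames fall back to the
#' full average (flagged in the output).
#'
#' @param movies list of [mt_movie()]s, one per segment (boxed movies).
#' @param records per-segment alignment records.
#' @param reference reference volume for re-refinement.
#' @param group_size frames per sub-average.
#' @param n_groups number of sub-averages.
#' @param max_shift admissible shift, px.
#' @return data.frame of refined records with `sub_group` (0-based) and
#'   `fallback` columns; fallback rows carry the full-average parameters.
#' @export
subframe_refine <- function(movies, records, reference, group_size = 5,
                            n_groups = 3, max_shift = 4) {
  stopifnot(length(movies) == nrow(records))
  pj <- make_projector(reference)
  out <- list()
  for (i in seq_along(movies)) {
    mv <- movies[[i]]
    r <- records[i, ]
    nf <- length(mv$frames)
    if (nf < group_size * n_groups) {
      rr <- r; rr$sub_group <- NA_integer_; rr$fallback <- TRUE
      out[[length(out) + 1]] <- rr
      next
    }
    ref0 <- pj(r$rot, r$tilt, 0, r$polarity)
    for (g in seq_len(n_groups)) {
      fr <- mv$frames[((g - 1) * group_size + 1):(g * group_size)]
      avg <- Reduce(`+`, fr) / group_size
      best <- NULL
      for (dps in c(-0.5, 0, 0.5)) {
        ref <- if (abs(r$psi + dps) > 1e-9)
          rotate_image(ref0, r$psi + dps) else ref0
        pk <- xcorr_peak(avg, ref, max_shift = max_shift)
        if (is.null(best) || pk$score > best$score)
          best <- list(score = pk$score, shift = pk$shift, psi = r$psi + dps)
      }
      rr <- r
      rr$psi <- best$psi; rr$dr <- best$shift[1]; rr$dc <- best$shift[2]
      rr$score <- best$score
      rr$sub_group <- g - 1L; rr$fallback <- FALSE
      out[[length(out) + 1]] <- rr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
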