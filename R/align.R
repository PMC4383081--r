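# Projection matching: reference banks, semi-exhaustive orientation/shift
# search, protofilament-number classification, and per-filament seam /
# polarity determination.

#' Build a bank of reference projections
#'
#' Projects a reference volume at every (rot, tilt, polarity) combination
#' (in-plane angle handled separately by image rotation of the psi = 0
#' projections during matching).
#'
#' @param vol reference [mt_volume()].
#' @param rots,tilts vectors of angles, degrees.
#' @param polarities character vector from `c("+", "-")`.
#' @param projector optional prebuilt projector closure.
#' @return list with `images` (list of matrices) and `params`
#'   (data.frame: rot, tilt, polarity).
#' @export
projection_bank <- function(vol, rots, tilts = 90, polarities = "+",
                            projector = NULL) {
  if (is.null(projector)) projector <- make_projector(vol)
  params <- expand.grid(rot = rots, tilt = tilts, polarity = polarities,
                        stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(params)), function(i)
    projector(params$rot[i], params$tilt[i], 0, params$polarity[i]))
  list(images = images, params = params)
}

#' Match one segment against a projection bank
#'
#' For every bank image and every candidate in-plane angle, the reference
#' is rotated and cross-correlated with the segment; the best normalized
#' correlation over the admissible shift range wins, with parabolic
#' subpixel shift refinement.
#'
#' @param segment image matrix.
#' @param bank a [projection_bank()].
#' @param psis candidate in-plane angles, degrees.
#' @param max_shift admissible shift, pixels.
#' @return one-row data.frame: `rot`, `tilt`, `psi`, `dr`, `dc`,
#'   `polarity`, `score`, `at_boundary`.
#' @export
match_segment <- function(segment, bank, psis = 0, max_shift = 8) {
  best <- NULL
  for (i in seq_along(bank$images)) {
    for (ps in psis) {
      ref <- bank$images[[i]]
      if (abs(ps) > 1e-9) ref <- rotate_image(ref, ps)
      pk <- xcorr_peak(segment, ref, max_shift = max_shift)
      if (is.null(best) || pk$score > best$score) {
        best <- data.frame(rot = bank$params$rot[i],
                           tilt = bank$params$tilt[i], psi = ps,
                           dr = pk$shift[1], dc = pk$shift[2],
                           polarity = bank$params$polarity[i],
                           score = pk$score, at_boundary = pk$at_boundary,
                           stringsAsFactors = FALSE)
      }
    }
  }
  best
}

#' Semi-exhaustive orientation and shift search for one segment
#'
#' Coarse grid over rot (4 degree steps across one protofilament sector or
#' a caller-supplied range), out-of-plane tilt within +/-15 degrees of
#' edge-on (5 degree steps), and in-plane angle around the Radon estimate,
#' followed by two local refinement stages (1 then 0.25 degree steps) with
#' parabolic subpixel shifts.
#'
#' @param segment image matrix.
#' @param vol reference volume.
#' @param psi_prior in-plane angle prior (Radon estimate), degrees.
#' @param rot_range rot search range `c(lo, hi)`, degrees.
#' @param tilt_range tilt search range (default edge-on +/- 15).
#' @param polarity polarity candidate(s) to search.
#' @param max_shift admissible shift, pixels.
#' @param score_floor matches scoring below this are flagged for
#'   exclusion.
#' @param projector optional prebuilt projector.
#' @return one-row data.frame alignment record with `excluded` flag.
#' @export
global_search <- function(segment, vol, psi_prior = 0,
                          rot_range = c(0, 360), tilt_range = c(75, 105),
                          polarity = c("+", "-"), max_shift = 8,
                          score_floor = 0.1, projector = NULL) {
  if (is.null(projector)) projector <- make_projector(vol)
  rots <- seq(rot_range[1], rot_range[2], by = 4)
  rots <- rots[rots < rot_range[2] | rots == rot_range[1]]
  tilts <- seq(tilt_range[1], tilt_range[2], by = 5)
  bank <- projection_bank(vol, rots, tilts, polarity, projector = projector)
  psis <- psi_prior + seq(-4, 4, by = 2)
  best <- match_segment(segment, bank, psis, max_shift)
  for (step in c(1, 0.25)) {
    rots2 <- best$rot + seq(-2 * step, 2 * step, by = step)
    tilts2 <- best$tilt + seq(-2 * step, 2 * step, by = step)
    tilts2 <- tilts2[tilts2 >= tilt_range[1] & tilts2 <= tilt_range[2]]
    bank2 <- projection_bank(vol, rots2, tilts2, best$polarity,
                             projector = projector)
    psis2 <- best$psi + seq(-2 * step, 2 * step, by = step)
    best <- match_segment(segment, bank2, psis2, max_shift)
  }
  best$excluded <- best$score < score_floor
  best
}

#' Classify the protofilament number of each segment and filament
#'
#' Multi-reference matching against a named list of reference volumes
#' (protofilament counts 12-15): each segment takes the class of the
#' best-scoring reference (ties break toward the lower count); each
#' filament takes the majority vote over its segments (ties again toward
#' the lower count).
#'
#' @param stack an [mt_segment_stack()] whose `meta` has `filament_id`.
#' @param references named list of reference volumes; names are the
#'   protofilament counts (e.g. `"12"`, `"13"`, `"14"`, `"15"`).
#' @param psi_priors per-segment in-plane angle priors (degrees; default
#'   0).
#' @param tilts tilt candidates for the matching bank.
#' @param rot_step rot grid step, degrees.
#' @param max_shift admissible shift, pixels.
#' @return list with `segment_class` (integer per segment),
#'   `filament_class` (named integer per filament), `scores` (matrix
#'   segments x references).
#' @export
classify_pf_number <- function(stack, references, psi_priors = NULL,
                               tilts = 90, rot_step = 4, max_shift = 8) {
  ns <- length(stack$boxes)
  if (is.null(psi_priors)) psi_priors <- rep(0, ns)
  pf_counts <- as.integer(names(references))
  stopifnot(!any(is.na(pf_counts)))
  scores <- matrix(NA_real_, ns, length(references),
                   dimnames = list(NULL, names(references)))
  banks <- lapply(seq_along(references), function(j) {
    n_pf <- pf_counts[j]
    rots <- seq(0, 360 / n_pf, by = rot_step)
    projection_bank(references[[j]], rots, tilts, "+")
  })
  for (i in seq_len(ns)) {
    for (j in seq_along(references)) {
      m <- match_segment(stack$boxes[[i]], banks[[j]],
                         psis = psi_priors[i] + c(-2, 0, 2), max_shift)
      scores[i, j] <- m$score
    }
  }
  seg_class <- pf_counts[apply(scores, 1, function(s)
    which(s == max(s))[1])]   # ties: first index = lower count
  fil_id <- stack$meta$filament_id
  fil_class <- vapply(split(seg_class, fil_id), function(cl) {
    tab <- table(cl)
    winners <- as.integer(names(tab)[tab == max(tab)])
    min(winners)
  }, integer(1))
  list(segment_class = seg_class, filament_class = fil_class,
       scores = scores)
}

#' Determine the seam position and polarity of each filament
#'
#' Runs a semi-exhaustive orientation search of each filament's segment
#' average over the full azimuth circle, the out-of-plane tilt window and
#' both polarities (segments of a straight filament share orientation and
#' repeat phase, so their average carries the decision signal at a
#' root-n signal-to-noise gain), locally refines the winner, and reports
#' the seam register as the winning azimuth expressed in protofilament
#' sectors relative to the records' base azimuth. If the summed score of
#' the winning register does not exceed the runner-up register by the
#' margin fraction, the filament is flagged ambiguous. All segments are
#' then locally re-refined under the fixed seam/polarity.
#'
#' @param stack an [mt_segment_stack()] with `meta$filament_id`.
#' @param vol seam-containing reference volume.
#' @param n_pf protofilament count.
#' @param records per-segment starting records (needs `rot` -- the base
#'   azimuth the seam index is reported against -- plus `tilt` and `psi`;
#'   optionally `rot_minus`, the base azimuth for the flipped polarity);
#'   if NULL, rot0 = 0, tilt = 90, psi = 0.
#' @param margin required relative score margin (default 0.02).
#' @param score_floor filaments whose best score falls below this are
#'   flagged ambiguous regardless of margin (structureless averages
#'   correlate near zero).
#' @param max_shift admissible shift, pixels.
#' @param tilt_scan absolute tilt values searched (default the full
#'   +/-15 degree window in 5 degree steps).
#' @param rot_step coarse azimuth step of the full-circle search,
#'   degrees.
#' @param bank optional prebuilt [projection_bank()] covering the search
#'   grid in both polarities (reused across calls).
#' @param projector optional prebuilt projector for `vol`.
#' @return list with `filaments` (data.frame: filament_id, seam_index,
#'   polarity, rot (refined absolute azimuth), tilt, margin, ambiguous)
#'   and `records` (per-segment refined alignment records).
#' @export
find_seam_polarity <- function(stack, vol, n_pf, records = NULL,
                               margin = 0.02, score_floor = 0.15,
                               max_shift = 8,
                               tilt_scan = seq(75, 105, by = 5),
                               rot_step = 3, bank = NULL,
                               projector = NULL) {
  ns <- length(stack$boxes)
  if (is.null(records))
    records <- data.frame(rot = rep(0, ns), tilt = 90, psi = 0)
  if (is.null(projector)) projector <- make_projector(vol)
  twist <- 360 / n_pf
  fil_id <- if (!is.null(stack$meta$filament_id))
    stack$meta$filament_id else rep(1L, ns)
  if (is.null(bank)) {
    bank <- projection_bank(vol, seq(0, 360 - rot_step, by = rot_step),
                            tilt_scan, c("+", "-"), projector = projector)
  }
  fil_out <- list(); rec_out <- records
  rec_out$seam_index <- NA_integer_; rec_out$polarity <- NA_character_
  rec_out$score <- NA_real_
  rec_out$dr <- NA_real_; rec_out$dc <- NA_real_
  for (f in unique(fil_id)) {
    idx <- which(fil_id == f)
    rot0 <- stats::median(records$rot[idx])
    rot0m <- if (!is.null(records$rot_minus))
      stats::median(records$rot_minus[idx]) else rot0
    psi0 <- stats::median(records$psi[idx])
    avg <- Reduce(`+`, stack$boxes[idx]) / length(idx)
    # matching at zero in-plane angle: rotate the average, not the bank
    avg0 <- if (abs(psi0) > 1e-9) rotate_image(avg, -psi0) else avg
    sc <- vapply(bank$images, function(ref)
      xcorr_peak(avg0, ref, max_shift = max_shift)$score, numeric(1))
    # register label of every bank orientation, relative to the records'
    # base azimuth of the matching polarity
    base <- ifelse(bank$params$polarity == "+", rot0, rot0m)
    reg <- (round((bank$params$rot - base) / twist) %% n_pf)
    key <- paste(bank$params$polarity, reg)
    tot <- tapply(sc, key, max)
    o <- order(tot, decreasing = TRUE)
    marg <- (tot[o[1]] - tot[o[2]]) / abs(tot[o[1]])
    jwin <- which.max(sc)
    # local refinement of the winning orientation on the average
    rot_w <- bank$params$rot[jwin]; tilt_w <- bank$params$tilt[jwin]
    pol_w <- bank$params$polarity[jwin]
    best_s <- sc[jwin]
    for (dr_ in seq(-rot_step, rot_step, by = 0.5)) {
      for (dtl in c(-2.5, -1.25, 0, 1.25, 2.5)) {
        s <- xcorr_peak(avg0, projector(bank$params$rot[jwin] + dr_,
                                        bank$params$tilt[jwin] + dtl, 0,
                                        pol_w),
                        max_shift = max_shift)$score
        if (s > best_s) {
          best_s <- s
          rot_w <- bank$params$rot[jwin] + dr_
          tilt_w <- bank$params$tilt[jwin] + dtl
        }
      }
    }
    base_w <- if (pol_w == "+") rot0 else rot0m
    kbest <- (round((rot_w - base_w) / twist) %% n_pf)
    fil_out[[length(fil_out) + 1]] <- data.frame(
      filament_id = f, seam_index = as.integer(kbest), polarity = pol_w,
      rot = rot_w, tilt = tilt_w, margin = unname(marg),
      ambiguous = unname(marg) < margin || best_s < score_floor)
    # local re-refinement of every segment under the fixed orientation
    refbase <- projector(rot_w, tilt_w, 0, pol_w)
    for (i0 in idx) {
      bestm <- NULL
      for (dps in c(-1, 0, 1)) {
        ref <- if (abs(psi0 + dps) > 1e-9)
          rotate_image(refbase, psi0 + dps) else refbase
        pk <- xcorr_peak(stack$boxes[[i0]], ref, max_shift = max_shift)
        if (is.null(bestm) || pk$score > bestm$score)
          bestm <- list(score = pk$score, shift = pk$shift,
                        psi = psi0 + dps)
      }
      rec_out$rot[i0] <- rot_w
      rec_out$tilt[i0] <- tilt_w
      rec_out$psi[i0] <- bestm$psi
      rec_out$dr[i0] <- bestm$shift[1]
      rec_out$dc[i0] <- bestm$shift[2]
      rec_out$polarity[i0] <- pol_w
      rec_out$seam_index[i0] <- as.integer(kbest)
      rec_out$score[i0] <- bestm$score
    }
  }
  list(filaments = do.call(rbind, fil_out), records = rec_out)
}
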