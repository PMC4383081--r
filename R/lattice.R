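#' Parametric microtubule lattice specification
#'
#' Describes a B-lattice microtubule with a seam, decorated by one kinesin
#' motor per tubulin dimer. A microtubule with `n_pf` protofilaments and
#' helix start number `start_number` (in monomer units, canonically 3)
#' places the dimer on protofilament p at azimuth `p * 360 / n_pf` degrees
#' and axial offset `p * start_number * monomer_rise / n_pf`. Crossing all
#' protofilaments therefore accumulates `start_number * monomer_rise` of
#' axial rise (120 Angstrom for the canonical 3-start, 40 Angstrom monomer
#' rise), which is not a multiple of the 80 Angstrom dimer repeat: the
#' resulting half-repeat register jump is the seam.
#'
#' @param n_pf protofilament count, 12 to 15.
#' @param start_number helix start in monomers (default 3).
#' @param monomer_rise axial rise per tubulin monomer, Angstrom (default 40).
#' @param radius protofilament axis radius, Angstrom (default 110).
#' @param seam_position integer in `[0, n_pf)`: the seam sits at azimuth
#'   `seam_position * 360 / n_pf`.
#' @param supertwist protofilament skew, degrees per dimer repeat (default 0).
#' @param decoration_occupancy fraction of dimers carrying a motor, in
#'   `[0, 1]`.
#' @param polarity `"+"` or `"-"`: plus-end toward increasing z or reversed.
#' @return an object of class `lattice_spec`.
#' @export
lattice_spec <- function(n_pf = 14, start_number = 3, monomer_rise = 40,
                         radius = 110, seam_position = 0, supertwist = 0,
                         decoration_occupancy = 1, polarity = "+") {
  if (n_pf != round(n_pf)) stop("n_pf must be an integer")
  n_pf <- as.integer(n_pf)
  if (n_pf < 12L || n_pf > 15L) stop("n_pf must be in [12, 15]")
  if (decoration_occupancy < 0 || decoration_occupancy > 1)
    stop("decoration_occupancy must be in [0, 1]")
  if (seam_position < 0 || seam_position >= n_pf)
    stop("seam_position must be in [0, n_pf)")
  stopifnot(monomer_rise > 0, radius > 0, polarity %in% c("+", "-"))
  structure(list(n_pf = n_pf, start_number = as.integer(start_number),
                 monomer_rise = monomer_rise,
                 dimer_repeat = 2 * monomer_rise, radius = radius,
                 seam_position = as.integer(seam_position),
                 supertwist = supertwist,
                 decoration_occupancy = decoration_occupancy,
                 polarity = polarity),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "<lattice_spec> %d pf, %d-start, rise %.4g A (repeat %.4g A), radius %.4g A\n",
    x$n_pf, x$start_number, x$monomer_rise, x$dimer_repeat, x$radius))
  cat(sprintf("  seam at pf %d, supertwist %.4g deg/dimer, occupancy %.2f, polarity %s\n",
              x$seam_position, x$supertwist, x$decoration_occupancy, x$polarity))
  invisible(x)
}

#' Helical step between adjacent protofilaments
#'
#' The azimuthal step is `360 / n_pf` degrees; the axial step is
#' `start_number * monomer_rise / n_pf` Angstrom. Summed over all `n_pf`
#' protofilaments these close 360 degrees and `start_number * monomer_rise`
#' of rise exactly.
#' @param spec a [lattice_spec()].
#' @return list with `twist` (degrees) and `rise` (Angstrom).
#' @export
helical_step <- function(spec) {
  list(twist = 360 / spec$n_pf,
       rise = spec$start_number * spec$monomer_rise / spec$n_pf)
}

#' Realize a decorated microtubule lattice
#'
#' Places alpha tubulin, beta tubulin and (by occupancy) kinesin subunits for
#' `n_repeats` dimer repeats on every protofilament. Within a dimer the alpha
#' monomer sits at the dimer z and the beta monomer one monomer rise above;
#' the kinesin head is placed radially outward of the beta monomer at
#' `radius + 45` Angstrom. With occupancy < 1 motors are retained
#' deterministically for occupancy 0 or 1 and by a seeded draw otherwise.
#'
#' @param spec a [lattice_spec()].
#' @param n_repeats number of 8 nm repeats to build (>= 1).
#' @param seed integer seed for fractional-occupancy draws.
#' @return object of class `decorated_lattice`: data.frame `placements` with
#'   columns `species`, `pf`, `repeat_index`, `x`, `y`, `z` (Angstrom) and
#'   `azimuth` (degrees), plus the generating `spec`.
#' @export
build_lattice <- function(spec, n_repeats, seed = 1L) {
  stopifnot(inherits(spec, "lattice_spec"), n_repeats >= 1)
  n_repeats <- as.integer(n_repeats)
  hs <- helical_step(spec)
  pol <- if (spec$polarity == "+") 1 else -1
  rows <- vector("list", spec$n_pf * n_repeats)
  idx <- 0L
  set.seed(seed)
  occ_draw <- matrix(stats::runif(spec$n_pf * n_repeats) <
                       spec$decoration_occupancy, spec$n_pf, n_repeats)
  kin_radius <- spec$radius + 45
  for (p in 0:(spec$n_pf - 1)) {
    for (k in 0:(n_repeats - 1)) {
      idx <- idx + 1L
      az <- (spec$seam_position + p) * hs$twist + k * spec$supertwist
      z0 <- pol * (p * hs$rise + k * spec$dimer_repeat)
      a <- az * pi / 180
      xy <- c(cos(a), sin(a))
      sp <- c("alpha_tubulin", "beta_tubulin")
      zs <- z0 + pol * c(0, spec$monomer_rise)
      rr <- data.frame(
        species = sp, pf = p, repeat_index = k,
        x = spec$radius * xy[1], y = spec$radius * xy[2], z = zs,
        azimuth = az, stringsAsFactors = FALSE)
      if (occ_draw[p + 1, k + 1]) {
        rr <- rbind(rr, data.frame(
          species = "kinesin", pf = p, repeat_index = k,
          x = kin_radius * xy[1], y = kin_radius * xy[2],
          z = z0 + pol * spec$monomer_rise,
          azimuth = az, stringsAsFactors = FALSE))
      }
      rows[[idx]] <- rr
    }
  }
  placements <- do.call(rbind, rows)
  rownames(placements) <- NULL
  # center the filament axially on z = 0
  tub <- placements$species != "kinesin"
  placements$z <- placements$z - (min(placements$z[tub]) + max(placements$z[tub])) / 2
  structure(list(placements = placements, spec = spec,
                 n_repeats = n_repeats),
            class = "decorated_lattice")
}

#' @export
print.decorated_lattice <- function(x, ...) {
  tab <- table(x$placements$species)
  cat(sprintf("<decorated_lattice> %d pf x %d repeats: %s\n",
              x$spec$n_pf, x$n_repeats,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
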