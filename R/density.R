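# Density rendering: subunits become small Gaussian mixtures splatted onto
# the voxel grid, then band-limited to the requested resolution. This keeps
# shape realism (monomer-sized blobs, motor heads radially outward) without
# atomic models.

# per-species blob models: mixture component offsets are expressed in a local
# frame (axial = filament z, radial = outward unit vector); weights sum to the
# species mass relative to a tubulin monomer (~50 kDa; kinesin head ~38 kDa)
blob_model <- function(species) {
  switch(species,
    alpha_tubulin = ,
    beta_tubulin = list(sigma = 10,
                        d_axial = c(-8, 0, 8), d_radial = c(0, 0, 0),
                        w = c(0.3, 0.4, 0.3)),
    # the motor head is tilted toward the filament plus end: an axially
    # asymmetric blob, which is what makes polarity identifiable from
    # decorated images
    kinesin = list(sigma = 11,
                   d_axial = c(-6, 0, 10), d_radial = c(-6, 0, 8),
                   w = 0.76 * c(0.35, 0.4, 0.25)),
    stop("unknown species: ", species)
  )
}

# splat isotropic Gaussians (centers Nx3 Angstrom, per-center weight and
# sigma) onto the array of an mt_volume; returns the updated array.
# periodic_z wraps blob tails around the z faces (filament periodicity).
splat_gaussians <- function(arr, voxel, origin, centers, weights, sigmas,
                            periodic_z = FALSE) {
  d <- dim(arr)
  for (i in seq_len(nrow(centers))) {
    s <- sigmas[i]
    half <- ceiling(3.5 * s / voxel)
    cvox <- (centers[i, ] - origin) / voxel + 1  # fractional voxel index
    if (periodic_z) cvox[3] <- ((cvox[3] - 1) %% d[3]) + 1
    i0 <- pmax(1, floor(cvox[1:2] - half))
    i1 <- pmin(d[1:2], ceiling(cvox[1:2] + half))
    if (any(i0 > i1)) next
    ax <- (i0[1]:i1[1] - cvox[1]) * voxel
    ay <- (i0[2]:i1[2] - cvox[2]) * voxel
    gx <- exp(-ax^2 / (2 * s^2)); gy <- exp(-ay^2 / (2 * s^2))
    if (periodic_z) {
      jz <- floor(cvox[3] - half):ceiling(cvox[3] + half)
      az <- (jz - cvox[3]) * voxel
      kz <- ((jz - 1) %% d[3]) + 1
    } else {
      jz <- max(1, floor(cvox[3] - half)):min(d[3], ceiling(cvox[3] + half))
      az <- (jz - cvox[3]) * voxel
      kz <- jz
    }
    gz <- exp(-az^2 / (2 * s^2))
    blob <- weights[i] * outer(outer(gx, gy), gz) / ((2 * pi)^1.5 * s^3)
    for (j in seq_along(kz)) {
      arr[i0[1]:i1[1], i0[2]:i1[2], kz[j]] <-
        arr[i0[1]:i1[1], i0[2]:i1[2], kz[j]] + blob[, , j]
    }
  }
  arr
}

#' Render a decorated lattice to an EM density volume
#'
#' Each subunit contributes a soft three-Gaussian blob (tubulin monomer
#' about 4 nm, kinesin head about 4.5 nm, weight proportional to mass);
#' the summed map is then band-limited to `resolution` with a soft
#' cosine-edge low-pass. Total integrated density is proportional to the
#' number (and mass) of subunits.
#'
#' @param lattice a [build_lattice()] result, or any data.frame with columns
#'   `species`, `x`, `y`, `z`, `azimuth`.
#' @param grid list with `n` (length-3 voxel counts) and `voxel` (Angstrom);
#'   the grid is centered on the origin.
#' @param resolution target resolution in Angstrom (>= 2 voxels).
#' @param periodic_z logical: treat the grid as periodic along z (the
#'   filament axis). The lattice is z-periodic with period one dimer
#'   repeat, so a grid whose z extent is an integer number of repeats
#'   renders a seamless, effectively infinite filament.
#' @return an [mt_volume()].
#' @export
render_density <- function(lattice, grid, resolution, periodic_z = FALSE) {
  pl <- if (inherits(lattice, "decorated_lattice")) lattice$placements else lattice
  stopifnot(is.list(grid), length(grid$n) == 3, grid$voxel > 0)
  if (resolution < 2 * grid$voxel)
    stop("resolution must be at least twice the voxel size")
  if (periodic_z && inherits(lattice, "decorated_lattice")) {
    zext <- grid$n[3] * grid$voxel
    if (abs(zext / lattice$spec$dimer_repeat -
            round(zext / lattice$spec$dimer_repeat)) > 1e-6)
      warning("z extent is not an integer number of dimer repeats; ",
              "the periodic wrap will introduce a seam artifact at the faces")
  }
  arr <- array(0, dim = grid$n)
  origin <- -(grid$n - 1) / 2 * grid$voxel
  if (!is.null(pl) && nrow(pl) > 0) {
    half_ext <- (grid$n - 1) / 2 * grid$voxel
    if (any(abs(pl$x) > half_ext[1]) || any(abs(pl$y) > half_ext[2]) ||
        (!periodic_z && any(abs(pl$z) > half_ext[3])))
      stop("grid too small to contain the lattice")
    centers <- NULL; weights <- NULL; sigmas <- NULL
    for (sp in unique(pl$species)) {
      bm <- blob_model(sp)
      sub <- pl[pl$species == sp, , drop = FALSE]
      a <- sub$azimuth * pi / 180
      rad_hat <- cbind(cos(a), sin(a), 0)
      for (j in seq_along(bm$w)) {
        ctr <- cbind(sub$x, sub$y, sub$z) +
          bm$d_radial[j] * rad_hat +
          matrix(c(0, 0, bm$d_axial[j]), nrow(sub), 3, byrow = TRUE)
        centers <- rbind(centers, ctr)
        weights <- c(weights, rep(bm$w[j], nrow(sub)))
        sigmas <- c(sigmas, rep(bm$sigma, nrow(sub)))
      }
    }
    arr <- splat_gaussians(arr, grid$voxel, origin, centers, weights, sigmas,
                           periodic_z = periodic_z)
    arr <- lowpass_field(arr, grid$voxel, resolution)
  }
  mt_volume(arr, grid$voxel, origin)
}

#' Render an atomic (or bead) model to a density volume
#'
#' One isotropic Gaussian per atom, used for flexible-fitting targets and
#' phantom construction from coordinate models.
#'
#' @param coords N x 3 matrix of Angstrom coordinates.
#' @param grid list with `n` and `voxel` as in [render_density()].
#' @param sigma Gaussian width per atom, Angstrom.
#' @param weights per-atom weights (default 1).
#' @return an [mt_volume()].
#' @export
render_coords_density <- function(coords, grid, sigma = 3, weights = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  arr <- array(0, dim = grid$n)
  origin <- -(grid$n - 1) / 2 * grid$voxel
  arr <- splat_gaussians(arr, grid$voxel, origin, coords, weights,
                         rep(sigma, nrow(coords)))
  mt_volume(arr, grid$voxel, origin)
}
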