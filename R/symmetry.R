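# Pseudo-helical symmetrization: averaging all protofilaments onto one
# "good" protofilament with the helical operators (twist = 360/n_pf about
# the filament axis, rise = start_number * monomer_rise / n_pf), rebuilding
# the full filament from transformed copies, and recombining them through
# complementary soft wedge masks that sum to one everywhere.

#' Rotate and axially shift a volume (helical operator)
#'
#' Resamples the volume after rotating it by `dphi` degrees about the z
#' axis and translating it by `dz` Angstrom along z, with trilinear
#' interpolation. With `periodic_z` the volume is treated as periodic
#' along the filament axis (shifts wrap); out-of-grid samples are zero
#' otherwise.
#'
#' @param vol an [mt_volume()].
#' @param dphi rotation about z, degrees (counter-clockwise looking down
#'   +z).
#' @param dz translation along z, Angstrom.
#' @param periodic_z wrap interpolation along z.
#' @return transformed [mt_volume()].
#' @export
transform_volume <- function(vol, dphi, dz, periodic_z = TRUE) {
  d <- dim(vol$data)
  a <- vol$voxel
  th <- dphi * pi / 180
  cen <- (d + 1) / 2
  ix <- matrix(seq_len(d[1]), d[1], d[2]) - cen[1]
  iy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cen[2]
  # inverse rotation applied to target coords
  sx <- cos(th) * ix + sin(th) * iy + cen[1]
  sy <- -sin(th) * ix + cos(th) * iy + cen[2]
  out <- array(0, dim = d)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  okxy <- x0 >= 1 & x0 <= d[1] - 1 & y0 >= 1 & y0 <= d[2] - 1
  sz_all <- seq_len(d[3]) - dz / a
  z0 <- floor(sz_all); fz <- sz_all - z0
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy
  for (k in seq_len(d[3])) {
    zz0 <- z0[k]; zz1 <- zz0 + 1
    if (periodic_z) {
      zz0 <- ((zz0 - 1) %% d[3]) + 1
      zz1 <- ((zz1 - 1) %% d[3]) + 1
    } else if (zz0 < 1 || zz1 > d[3]) {
      next
    }
    sl0 <- vol$data[, , zz0]; sl1 <- vol$data[, , zz1]
    interp_xy <- function(sl) {
      v <- matrix(0, d[1], d[2])
      i00 <- cbind(x0[okxy], y0[okxy])
      i10 <- cbind(x0[okxy] + 1, y0[okxy])
      i01 <- cbind(x0[okxy], y0[okxy] + 1)
      i11 <- cbind(x0[okxy] + 1, y0[okxy] + 1)
      v[okxy] <- sl[i00] * w00[okxy] + sl[i10] * w10[okxy] +
        sl[i01] * w01[okxy] + sl[i11] * w11[okxy]
      v
    }
    out[, , k] <- interp_xy(sl0) * (1 - fz[k]) + interp_xy(sl1) * fz[k]
  }
  mt_volume(out, a, vol$origin)
}

#' Soft wedge masks forming a partition of unity
#'
#' One mask per protofilament sector: a raised-cosine tent of full angular
#' width `2 * 360 / n_pf` centered on each sector azimuth, so that the
#' masks sum to exactly 1 at every voxel.
#'
#' @param dims volume dimensions (length 3).
#' @param n_pf number of sectors.
#' @param phi0 azimuth of sector 0, degrees.
#' @return list of `n_pf` arrays in `[0, 1]`.
#' @export
wedge_masks <- function(dims, n_pf, phi0 = 0) {
  cen <- (dims[1:2] + 1) / 2
  ix <- matrix(seq_len(dims[1]), dims[1], dims[2]) - cen[1]
  iy <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - cen[2]
  theta <- atan2(iy, ix) * 180 / pi
  w <- 360 / n_pf
  lapply(0:(n_pf - 1), function(k) {
    delta <- (theta - phi0 - k * w + 180) %% 360 - 180
    m2 <- ifelse(abs(delta) < w, 0.5 * (1 + cos(pi * delta / w)), 0)
    array(rep(m2, dims[3]), dim = dims)
  })
}

#' Apply pseudo-helical symmetry to a reconstruction
#'
#' (i) Transforms the map by the inverse helical operators
#' `(-k * twist, -k * rise)` for `k = 0..n_pf - 1` and averages all
#' protofilaments onto the "good" protofilament; (ii) regenerates every
#' protofilament position with the forward operators; (iii) combines the
#' copies through complementary soft wedge masks that sum to one.
#' The seam's half-repeat register offset is reproduced by the operators
#' themselves, so a map built on a seam-containing lattice is (near) a
#' fixed point of this operation.
#'
#' @param vol an [mt_volume()].
#' @param n_pf protofilament count.
#' @param rise helical rise per protofilament, Angstrom (canonically
#'   `start_number * monomer_rise / n_pf`).
#' @param twist helical twist per protofilament, degrees (must equal
#'   `360 / n_pf` within tolerance).
#' @param phi0 azimuth of the good protofilament sector, degrees.
#' @return symmetrized [mt_volume()].
#' @export
symmetrize_pseudo_helical <- function(vol, n_pf, rise, twist = 360 / n_pf,
                                      phi0 = 0) {
  if (abs(twist - 360 / n_pf) > 1e-6)
    stop("twist must equal 360 / n_pf for a closed pseudo-helical family")
  d <- dim(vol$data)
  zext <- d[3] * vol$voxel
  if (rise > zext / 2) stop("rise inconsistent with the grid z extent")
  acc <- vol$data
  for (k in 1:(n_pf - 1)) {
    acc <- acc + transform_volume(vol, -k * twist, -k * rise)$data
  }
  good <- mt_volume(acc / n_pf, vol$voxel, vol$origin)
  masks <- wedge_masks(d, n_pf, phi0)
  out <- array(0, dim = d)
  for (k in 0:(n_pf - 1)) {
    vk <- if (k == 0) good else transform_volume(good, k * twist, k * rise)
    out <- out + masks[[k + 1]] * vk$data
  }
  mt_volume(out, vol$voxel, vol$origin)
}
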