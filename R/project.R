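# Projection geometry and the Fourier central-slice projector.
#
# Orientation convention (documented for the whole package):
#   rot  -- azimuth of the viewing direction about the filament (z) axis
#   tilt -- out-of-plane angle; 90 degrees is exactly edge-on
#   psi  -- in-plane rotation of the image, counter-clockwise positive
# At (rot, tilt = 90, psi = 0) the filament axis (volume z) runs along the
# image row ("column") axis, i.e. the filament appears vertical. Polarity
# "-" views the filament flipped end-over-end (180 degrees about the image
# x axis).

#' Orthonormal view basis for an orientation
#'
#' @param rot,tilt,psi Euler-style angles in degrees (see package
#'   conventions).
#' @param polarity `"+"` or `"-"`.
#' @return list with unit 3-vectors `ex` (image column direction), `ey`
#'   (image row direction) and `d` (projection direction), in the volume
#'   frame.
#' @export
view_basis <- function(rot, tilt = 90, psi = 0, polarity = "+") {
  r <- rot * pi / 180; th <- tilt * pi / 180; ps <- psi * pi / 180
  d <- c(sin(th) * cos(r), sin(th) * sin(r), cos(th))
  ey0 <- c(-cos(th) * cos(r), -cos(th) * sin(r), sin(th))
  ex0 <- c(ey0[2] * d[3] - ey0[3] * d[2],
           ey0[3] * d[1] - ey0[1] * d[3],
           ey0[1] * d[2] - ey0[2] * d[1])
  ex <- cos(ps) * ex0 + sin(ps) * ey0
  ey <- -sin(ps) * ex0 + cos(ps) * ey0
  if (polarity == "-") { ey <- -ey; d <- -d }
  list(ex = ex, ey = ey, d = d)
}

# periodic trilinear interpolation of a complex 3D array at fractional
# 0-based grid coordinates (u1, u2, u3 vectors of equal length)
trilinear_wrap <- function(arr, u1, u2, u3) {
  d <- dim(arr)
  i1 <- floor(u1); i2 <- floor(u2); i3 <- floor(u3)
  f1 <- u1 - i1; f2 <- u2 - i2; f3 <- u3 - i3
  out <- complex(length(u1))
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    w <- (if (c1 == 1) f1 else 1 - f1) *
      (if (c2 == 1) f2 else 1 - f2) *
      (if (c3 == 1) f3 else 1 - f3)
    j1 <- ((i1 + c1) %% d[1]) + 1
    j2 <- ((i2 + c2) %% d[2]) + 1
    j3 <- ((i3 + c3) %% d[3]) + 1
    out <- out + w * arr[cbind(j1, j2, j3)]
  }
  out
}

#' Build a cached projector for a volume
#'
#' Precomputes the volume FFT once; the returned closure extracts central
#' slices at arbitrary orientations and returns real-space projections of
#' size `box` x `box` at the volume's pixel size.
#'
#' @param vol an [mt_volume()].
#' @param box output image edge in pixels (default: volume x dimension).
#' @param pad per-axis Fourier oversampling factors (zero-padding of the
#'   volume). The default `c(2, 2, 1)` oversamples laterally, which keeps
#'   central-slice interpolation errors negligible for near-edge-on views
#'   while preserving the filament's z periodicity.
#' @return function `(rot, tilt, psi, polarity, dr, dc)` returning a
#'   projection matrix; `dr`, `dc` shift the projection in pixels.
#' @export
make_projector <- function(vol, box = dim(vol$data)[1], pad = c(2, 2, 1)) {
  dv0 <- dim(vol$data)
  a <- vol$voxel
  pad <- rep(pad, length.out = 3)
  if (any(pad > 1)) {
    dv <- dv0 * pad
    arr <- array(0, dim = dv)
    lo <- floor((dv - dv0) / 2)
    arr[lo[1] + seq_len(dv0[1]), lo[2] + seq_len(dv0[2]),
        lo[3] + seq_len(dv0[3])] <- vol$data
    cen3 <- (dv0 - 1) / 2 + lo
  } else {
    dv <- dv0
    arr <- vol$data
    cen3 <- (dv0 - 1) / 2
  }
  Fv <- fft(arr)
  # remove the volume-center phase ramp so the Fourier field is smooth and
  # safe to interpolate (object treated as centered at the DFT origin)
  p1 <- exp(2i * pi * fft_freq(dv[1]) * cen3[1])
  p2 <- exp(2i * pi * fft_freq(dv[2]) * cen3[2])
  p3 <- exp(2i * pi * fft_freq(dv[3]) * cen3[3])
  Fv <- Fv * (p1 %o% p2 %o% p3)
  # frequencies of the output image, cycles/Angstrom
  fr <- fft_freq(box, a)                      # row axis (image y)
  fc <- fft_freq(box, a)                      # col axis (image x)
  FR <- matrix(fr, box, box)                  # varies along rows
  FC <- matrix(fc, box, box, byrow = TRUE)
  cen2 <- (box - 1) / 2
  function(rot, tilt = 90, psi = 0, polarity = "+", dr = 0, dc = 0) {
    vb <- view_basis(rot, tilt, psi, polarity)
    kx <- FC; ky <- FR
    k1 <- kx * vb$ex[1] + ky * vb$ey[1]
    k2 <- kx * vb$ex[2] + ky * vb$ey[2]
    k3 <- kx * vb$ex[3] + ky * vb$ey[3]
    u1 <- k1 * dv[1] * a; u2 <- k2 * dv[2] * a; u3 <- k3 * dv[3] * a
    sl <- trilinear_wrap(Fv, as.vector(u1), as.vector(u2), as.vector(u3))
    # place the (centered) projection at the image center plus shift
    F2 <- matrix(sl, box, box)
    F2 <- F2 * exp(-2i * pi * (FR * a * (cen2 + dr) + FC * a * (cen2 + dc)))
    Re(fft(F2, inverse = TRUE)) / (box * box)
  }
}

#' Project a volume at one orientation
#'
#' Convenience wrapper around [make_projector()].
#' @inheritParams make_projector
#' @param rot,tilt,psi orientation in degrees.
#' @param polarity `"+"` or `"-"`.
#' @param dr,dc image-space shift in pixels (rows, cols).
#' @return numeric matrix `box` x `box`.
#' @export
project_volume <- function(vol, rot, tilt = 90, psi = 0, polarity = "+",
                           box = dim(vol$data)[1], dr = 0, dc = 0) {
  make_projector(vol, box)(rot, tilt, psi, polarity, dr, dc)
}
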