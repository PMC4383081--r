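# Fourier helpers shared by the imaging, micrograph and reconstruction code.
# Internal layout is the standard unshifted FFT order (DC at [1,1,...]);
# fftshift is only used for display-style outputs such as power spectra.

#' DFT sample frequencies
#'
#' Frequencies (cycles per physical unit) for an n-point transform with
#' sample spacing `d`, in standard FFT order.
#' @param n number of samples.
#' @param d sample spacing (e.g. Angstrom per pixel).
#' @return numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

#' Shift DC component to array center (2D/3D)
#' @keywords internal
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[c((floor(n / 2) + 1):n, 1:floor(n / 2))])
  }
  idx <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  do.call(`[`, c(list(x), idx))
}

#' Radial frequency magnitude grid for a 2D image
#' @keywords internal
freq_grid_2d <- function(nr, nc, pixel) {
  fr <- fft_freq(nr, pixel)
  fc <- fft_freq(nc, pixel)
  list(fr = matrix(fr, nr, nc), fc = matrix(fc, nr, nc, byrow = TRUE),
       s = sqrt(outer(fr^2, fc^2, `+`)))
}

#' Soft (cosine-edge) low-pass filter of a 2D image or 3D volume
#'
#' Passband is flat below `1/cutoff` minus the edge half-width; a raised
#' cosine rolls off to zero over `edge_width` (in reciprocal Angstrom,
#' default one Fourier pixel equivalent per the grid).
#' @keywords internal
lowpass_field <- function(x, pixel, cutoff, edge_frac = 0.1) {
  if (!is.finite(cutoff)) return(x)
  d <- dim(x)
  fc <- 1 / cutoff
  if (length(d) == 2) {
    s <- freq_grid_2d(d[1], d[2], pixel)$s
  } else {
    f1 <- fft_freq(d[1], pixel); f2 <- fft_freq(d[2], pixel); f3 <- fft_freq(d[3], pixel)
    s <- sqrt(outer(outer(f1^2, f2^2, `+`), f3^2, `+`))
  }
  w <- fc * edge_frac
  filt <- ifelse(s <= fc - w, 1,
                 ifelse(s >= fc + w, 0,
                        0.5 * (1 + cos(pi * (s - (fc - w)) / (2 * w)))))
  Re(fft(fft(x) * filt, inverse = TRUE)) / length(x)
}

#' Subpixel shift of an image by Fourier phase ramps
#'
#' Positive `dr`/`dc` move content toward larger row/column index.
#' @keywords internal
fourier_shift <- function(img, dr, dc) {
  d <- dim(img)
  fr <- fft_freq(d[1])
  fc <- fft_freq(d[2])
  ph <- exp(-2i * pi * (outer(fr * dr, rep(1, d[2])) +
                        outer(rep(1, d[1]), fc * dc)))
  Re(fft(fft(img) * ph, inverse = TRUE)) / length(img)
}

#' Cross-correlation between two images with subpixel peak location
#'
#' Returns the shift (dr, dc) that maps `b` onto `a` (i.e. `a` is
#' approximately `b` shifted by the returned amount) and the peak
#' normalized correlation. Shifts are restricted to `max_shift` pixels.
#' @keywords internal
xcorr_peak <- function(a, b, max_shift = Inf) {
  d <- dim(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE)) / length(a0)
  denom <- sqrt(sum(a0^2) * sum(b0^2))
  if (denom == 0) denom <- .Machine$double.eps
  cc <- cc / denom
  # admissible (wrapped) shifts
  sr <- fft_freq(d[1]) * d[1]
  sc <- fft_freq(d[2]) * d[2]
  ok <- outer(abs(sr) <= max_shift, abs(sc) <= max_shift)
  ccm <- cc
  ccm[!ok] <- -Inf
  pk <- which(ccm == max(ccm), arr.ind = TRUE)[1, ]
  peak <- cc[pk[1], pk[2]]
  at_edge <- (abs(sr[pk[1]]) >= max_shift - 0.5) || (abs(sc[pk[2]]) >= max_shift - 0.5)
  # parabolic subpixel refinement along each axis (wrapped neighbors)
  sub <- function(im1, i0, ip1) {
    den <- im1 - 2 * i0 + ip1
    if (den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (im1 - ip1) / den))
  }
  rp <- pk[1]; cp <- pk[2]
  rm <- if (rp == 1) d[1] else rp - 1; rq <- if (rp == d[1]) 1 else rp + 1
  cm <- if (cp == 1) d[2] else cp - 1; cq <- if (cp == d[2]) 1 else cp + 1
  ddr <- sub(cc[rm, cp], cc[rp, cp], cc[rq, cp])
  ddc <- sub(cc[rp, cm], cc[rp, cp], cc[rp, cq])
  list(shift = c(sr[pk[1]] + ddr, sc[pk[2]] + ddc),
       score = peak, at_boundary = at_edge)
}

#' Rotate an image about its center (bilinear interpolation)
#'
#' Angle in degrees, counter-clockwise positive when the image is viewed
#' with row index increasing upward along the filament ("column") axis.
#' Out-of-bounds samples take the image mean.
#' @keywords internal
rotate_image <- function(img, angle_deg, fill = mean(img)) {
  d <- dim(img)
  th <- angle_deg * pi / 180
  cr <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  r <- matrix(seq_len(d[1]), d[1], d[2]) - cr
  cl <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cc
  # inverse mapping: output (r, c) samples input at rotation by -angle
  rs <- cos(th) * r - sin(th) * cl + cr
  cs <- sin(th) * r + cos(th) * cl + cc
  bilinear_sample(img, rs, cs, fill)
}

#' Bilinear sampling of a matrix at fractional (row, col) positions
#' @keywords internal
bilinear_sample <- function(img, rs, cs, fill = 0) {
  d <- dim(img)
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  out <- array(fill, dim = dim(rs))
  ok <- r0 >= 1 & r0 <= d[1] - 1 & c0 >= 1 & c0 <= d[2] - 1
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i11] * fr[ok] * fc[ok]
  }
  out
}

#' Centered power spectrum of an image
#'
#' @param img numeric matrix.
#' @return matrix of squared Fourier amplitudes with DC at the center.
#' @export
power_spectrum <- function(img) {
  fftshift(Mod(fft(img - mean(img)))^2)
}
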