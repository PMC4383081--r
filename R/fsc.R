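# Reference filtering, tight masking, and Fourier shell correlation.

#' Low-pass filter a reference map
#'
#' Soft cosine-edge low-pass at `1 / cutoff`, the standard preparation of
#' an alignment reference (e.g. a 20 Angstrom cutoff for the initial
#' model).
#'
#' @param vol an [mt_volume()] (or a `decorated_lattice`, which is first
#'   rendered on a default grid).
#' @param cutoff resolution cutoff in Angstrom; `Inf` returns the input.
#' @return filtered [mt_volume()].
#' @export
make_reference <- function(vol, cutoff) {
  if (inherits(vol, "decorated_lattice"))
    stop("render the lattice with render_density() first")
  stopifnot(inherits(vol, "mt_volume"))
  if (!is.finite(cutoff)) return(vol)
  if (cutoff < 2 * vol$voxel)
    stop("cutoff ", cutoff, " A is below the Nyquist limit (",
         2 * vol$voxel, " A)")
  mt_volume(lowpass_field(vol$data, vol$voxel, cutoff), vol$voxel, vol$origin)
}

#' Generate a soft tight mask around the protein density
#'
#' Binarizes a low-pass-filtered copy of the map at a threshold given as a
#' fraction of the filtered map's maximum, then smooths the binary mask
#' with a soft Gaussian of the stated half-width (half-width at half
#' maximum; ~10 Angstrom by default). Output values lie in `[0, 1]`.
#'
#' @param vol an [mt_volume()].
#' @param threshold fraction of the low-passed map maximum in `[0, 1)`.
#' @param smooth Gaussian half-width (HWHM), Angstrom; must exceed the
#'   voxel size.
#' @param lowpass resolution of the thresholded low-pass copy, Angstrom.
#' @return mask as an [mt_volume()] with values in `[0, 1]`.
#' @export
make_tight_mask <- function(vol, threshold = 0.2, smooth = 10, lowpass = 30) {
  stopifnot(inherits(vol, "mt_volume"))
  if (smooth <= vol$voxel) stop("smooth must exceed the voxel size")
  lp <- if (lowpass >= 2 * vol$voxel)
    lowpass_field(vol$data, vol$voxel, lowpass) else vol$data
  if (threshold <= 0) {
    return(mt_volume(array(1, dim(vol$data)), vol$voxel, vol$origin))
  }
  bin <- (lp >= threshold * max(lp)) * 1
  if (sum(bin) == 0) stop("threshold too high: empty mask")
  sigma <- smooth / sqrt(2 * log(2))   # HWHM -> Gaussian sigma
  d <- dim(bin)
  f1 <- fft_freq(d[1], vol$voxel); f2 <- fft_freq(d[2], vol$voxel)
  f3 <- fft_freq(d[3], vol$voxel)
  s2 <- outer(outer(f1^2, f2^2, `+`), f3^2, `+`)
  g <- exp(-2 * pi^2 * sigma^2 * s2)
  sm <- Re(fft(fft(bin) * g, inverse = TRUE)) / length(bin)
  mt_volume(pmin(pmax(sm, 0), 1), vol$voxel, vol$origin)
}

#' Fourier shell correlation between two half-maps
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients,
#' with shells one Fourier pixel wide up to Nyquist. An optional soft
#' mask is applied to both maps first.
#'
#' @param mapA,mapB [mt_volume()]s on the same grid.
#' @param mask optional mask ([mt_volume()] or array) applied to both.
#' @return object of class `fsc_curve`: data.frame with `shell_freq`
#'   (1/Angstrom, strictly increasing) and `correlation`.
#' @export
fsc <- function(mapA, mapB, mask = NULL) {
  stopifnot(identical(dim(mapA$data), dim(mapB$data)),
            abs(mapA$voxel - mapB$voxel) < 1e-9)
  a <- mapA$data; b <- mapB$data
  if (!is.null(mask)) {
    m <- if (inherits(mask, "mt_volume")) mask$data else mask
    a <- a * m; b <- b * m
  }
  d <- dim(a)
  FA <- fft(a); FB <- fft(b)
  f1 <- fft_freq(d[1], mapA$voxel); f2 <- fft_freq(d[2], mapA$voxel)
  f3 <- fft_freq(d[3], mapA$voxel)
  s <- sqrt(outer(outer(f1^2, f2^2, `+`), f3^2, `+`))
  nyq <- 1 / (2 * mapA$voxel)
  df <- 1 / (d[1] * mapA$voxel)            # shell width: one Fourier pixel
  shell <- pmin(floor(s / df), floor(nyq / df))
  nsh <- floor(nyq / df)
  idx <- as.vector(shell) + 1
  keep <- idx <= nsh                        # drop DC's own shell? keep 0 shell
  num <- rowsum(as.vector(Re(FA * Conj(FB))), idx)
  pa <- rowsum(as.vector(Mod(FA)^2), idx)
  pb <- rowsum(as.vector(Mod(FB)^2), idx)
  sh <- as.integer(rownames(num))
  ok <- sh >= 1 & sh <= nsh
  corr <- num[ok] / sqrt(pa[ok] * pb[ok])
  freq <- (sh[ok] - 0.5) * df               # shell-center frequency
  o <- order(freq)
  structure(data.frame(shell_freq = freq[o], correlation = corr[o]),
            class = c("fsc_curve", "data.frame"))
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the first downward crossing of the threshold, linearly
#' interpolated between shells (the conventional 0.143 criterion by
#' default). If the curve never drops below the threshold the Nyquist
#' resolution is returned with attribute `no_crossing = TRUE`.
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold FSC threshold (default 0.143).
#' @return resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  f <- curve$shell_freq; cc <- curve$correlation
  below <- which(cc < threshold)
  if (length(below) == 0) {
    res <- 1 / max(f)
    attr(res, "no_crossing") <- TRUE
    return(res)
  }
  i <- below[1]
  if (i == 1) return(1 / f[1])
  fcross <- f[i - 1] + (f[i] - f[i - 1]) *
    (cc[i - 1] - threshold) / (cc[i - 1] - cc[i])
  1 / fcross
}
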