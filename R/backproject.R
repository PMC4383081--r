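# 3D reconstruction by direct Fourier insertion of central slices with
# trilinear gridding and simple overlap-weight normalization. The
# insertion grid is laterally oversampled (zero-padded) by the same factor
# as the projector so that slice interpolation and insertion are adjoint
# to working precision for near-edge-on views.

#' Back-project a segment stack into half-maps
#'
#' Each box is unshifted (Fourier phase ramps), rotated to zero in-plane
#' angle, and its 2D transform inserted as a central slice at the record's
#' orientation with trilinear gridding weights; accumulated coefficients
#' are normalized by the accumulated weights. Halves are split by even/odd
#' repeat index (`half = repeat_index %% 2`).
#'
#' @param stack an [mt_segment_stack()]; box size must equal the target
#'   grid dimension.
#' @param records data.frame, one row per box: `rot`, `tilt`, `psi`,
#'   `dr`, `dc` (pixel shifts), `polarity`, `repeat_index`.
#' @param n target cubic grid dimension (default: box size).
#' @param split `"halves"` for (A, B) half-maps, `"full"` for one map.
#' @param pad lateral oversampling factor of the insertion grid.
#' @return list with `A` and `B` half-map [mt_volume()]s (or `full`).
#' @export
backproject <- function(stack, records, n = NULL, split = "halves", pad = 2) {
  nb <- length(stack$boxes)
  stopifnot(nb >= 1, nrow(records) == nb)
  box <- dim(stack$boxes[[1]])[1]
  if (is.null(n)) n <- box
  stopifnot(n == box)  # matched grids keep the insertion exact
  a <- stack$pixel_size
  half_of <- records$repeat_index %% 2
  if (split == "halves" && (all(half_of == 0) || all(half_of == 1)))
    stop("one half-set is empty; cannot split")
  fr <- fft_freq(box, a)
  FR <- matrix(fr, box, box); FC <- matrix(fr, box, box, byrow = TRUE)
  cen2 <- (box - 1) / 2
  pn <- pad * n
  lo <- floor((pn - n) / 2)
  accum <- function(sel) {
    num <- complex(real = numeric(pn * pn * n))
    den <- numeric(pn * pn * n)
    for (i in which(sel)) {
      r <- records[i, ]
      img <- stack$boxes[[i]]
      if (abs(r$dr) > 1e-9 || abs(r$dc) > 1e-9)
        img <- fourier_shift(img, -r$dr, -r$dc)
      if (abs(r$psi) > 1e-9) img <- rotate_image(img, -r$psi)
      F2 <- fft(img) * exp(2i * pi * (FR * a * cen2 + FC * a * cen2))
      vb <- view_basis(r$rot, r$tilt, 0, as.character(r$polarity))
      u1 <- (FC * vb$ex[1] + FR * vb$ey[1]) * pn * a
      u2 <- (FC * vb$ex[2] + FR * vb$ey[2]) * pn * a
      u3 <- (FC * vb$ex[3] + FR * vb$ey[3]) * n * a
      i1 <- floor(u1); i2 <- floor(u2); i3 <- floor(u3)
      f1 <- u1 - i1; f2 <- u2 - i2; f3 <- u3 - i3
      val <- as.vector(F2)
      for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
        w <- as.vector((if (c1 == 1) f1 else 1 - f1) *
                       (if (c2 == 1) f2 else 1 - f2) *
                       (if (c3 == 1) f3 else 1 - f3))
        j1 <- (as.vector(i1 + c1) %% pn)
        j2 <- (as.vector(i2 + c2) %% pn)
        j3 <- (as.vector(i3 + c3) %% n)
        lin <- 1 + j1 + pn * (j2 + pn * j3)
        sre <- rowsum(w * Re(val), lin)
        sim <- rowsum(w * Im(val), lin)
        sw <- rowsum(w, lin)
        at <- as.integer(rownames(sre))
        num[at] <- num[at] + complex(real = sre, imaginary = sim)
        den[at] <- den[at] + sw
      }
    }
    Fv <- array(num / pmax(den, 1e-3), dim = c(pn, pn, n))
    Fv[den == 0] <- 0
    # restore the center phase (object centered in the padded grid)
    cenp <- c((n - 1) / 2 + lo, (n - 1) / 2 + lo, (n - 1) / 2)
    pxy <- exp(-2i * pi * fft_freq(pn) * cenp[1])
    pz <- exp(-2i * pi * fft_freq(n) * cenp[3])
    Fv <- Fv * (pxy %o% pxy %o% pz)
    v <- Re(fft(Fv, inverse = TRUE)) / (pn * pn * n)
    v <- v[lo + seq_len(n), lo + seq_len(n), , drop = FALSE] * pad^2
    mt_volume(v, a)
  }
  if (split == "full") {
    list(full = accum(rep(TRUE, nb)))
  } else {
    list(A = accum(half_of == 0), B = accum(half_of == 1))
  }
}
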