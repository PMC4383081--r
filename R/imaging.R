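#' Imaging parameters for the synthetic microscope
#'
#' Defaults follow low-dose direct-detector data collection on a 300 kV
#' instrument: 1.99 Angstrom effective pixel, ~15 electrons per square
#' Angstrom distributed over 15 movie frames, defocus near 1.5 micrometer.
#' Spherical aberration defaults to 2.7 mm (typical FEG instrument value;
#' configurable). Astigmatism is not modeled.
#'
#' @param pixel_size Angstrom per pixel.
#' @param voltage accelerating voltage, kV.
#' @param spherical_aberration Cs, mm.
#' @param amplitude_contrast fraction in `[0, 1]`.
#' @param defocus underfocus (positive), micrometer.
#' @param total_dose electrons per square Angstrom over the whole movie.
#' @param n_frames number of movie frames (>= 1).
#' @param drift_per_frame `n_frames` x 2 matrix of absolute per-frame
#'   (row, col) shifts in pixels; default all zero.
#' @param noise_sigma additive Gaussian noise sd per frame, grey levels.
#' @param ctf logical: apply CTF modulation.
#' @param seed integer seed for frame noise.
#' @return object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 1.99, voltage = 300,
                           spherical_aberration = 2.7,
                           amplitude_contrast = 0.07, defocus = 1.5,
                           total_dose = 15, n_frames = 15,
                           drift_per_frame = NULL, noise_sigma = 0,
                           ctf = TRUE, seed = 1L) {
  stopifnot(pixel_size > 0, n_frames >= 1, defocus > 0, noise_sigma >= 0)
  n_frames <- as.integer(n_frames)
  if (is.null(drift_per_frame)) drift_per_frame <- matrix(0, n_frames, 2)
  drift_per_frame <- as.matrix(drift_per_frame)
  stopifnot(nrow(drift_per_frame) == n_frames, ncol(drift_per_frame) == 2)
  structure(list(pixel_size = pixel_size, voltage = voltage,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast, defocus = defocus,
                 total_dose = total_dose, n_frames = n_frames,
                 drift_per_frame = drift_per_frame,
                 noise_sigma = noise_sigma, ctf = ctf,
                 seed = as.integer(seed)),
            class = "imaging_params")
}

#' Relativistic electron wavelength
#' @param voltage_kv accelerating voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2643 / sqrt(v * (1 + 0.978476e-6 * v))
}

#' Evaluate the contrast transfer function
#'
#' Standard phase function with positive underfocus:
#' `chi(s) = pi * lambda * dz * s^2 - (pi/2) * Cs * lambda^3 * s^4`,
#' `CTF(s) = -(sqrt(1 - A^2) sin chi + A cos chi)`.
#'
#' @param s spatial frequency (scalar, vector or matrix), 1/Angstrom.
#' @param imaging an [imaging_params()].
#' @return CTF values with the same shape as `s`.
#' @export
ctf_eval <- function(s, imaging) {
  lambda <- electron_wavelength(imaging$voltage)
  dz <- imaging$defocus * 1e4           # um -> Angstrom
  cs <- imaging$spherical_aberration * 1e7  # mm -> Angstrom
  A <- imaging$amplitude_contrast
  chi <- pi * lambda * dz * s^2 - (pi / 2) * cs * lambda^3 * s^4
  -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
}

# multiply an image's Fourier transform by the CTF at its frequency grid
apply_ctf <- function(img, imaging) {
  d <- dim(img)
  s <- freq_grid_2d(d[1], d[2], imaging$pixel_size)$s
  Re(fft(fft(img) * ctf_eval(s, imaging), inverse = TRUE)) / length(img)
}

#' Simulate a low-dose movie of a projected volume
#'
#' Projects the volume along the requested view, applies CTF modulation
#' (unless disabled), then emits `n_frames` frames each shifted by its
#' absolute drift and corrupted by additive Gaussian noise (the Gaussian
#' approximation of shot noise at the stated dose). The ground truth
#' (view, per-frame shifts, defocus) is returned alongside.
#'
#' @param vol an [mt_volume()]; its voxel size must equal the imaging
#'   pixel size.
#' @param imaging an [imaging_params()].
#' @param view numeric `(rot, tilt, psi)` in degrees.
#' @param box image edge in pixels (default: volume x dimension).
#' @param polarity `"+"` or `"-"`.
#' @return list with `movie` ([mt_movie()]) and `truth` (list: `view`,
#'   `polarity`, `shifts` matrix, `defocus`, `noise_sigma`, `seed`).
#' @export
simulate_movie <- function(vol, imaging, view = c(0, 90, 0), box = dim(vol$data)[1],
                           polarity = "+") {
  stopifnot(inherits(vol, "mt_volume"), inherits(imaging, "imaging_params"))
  if (abs(vol$voxel - imaging$pixel_size) > 1e-9)
    stop("volume voxel size must match imaging pixel size")
  proj <- project_volume(vol, view[1], view[2], view[3], polarity, box = box)
  if (imaging$ctf) proj <- apply_ctf(proj, imaging)
  set.seed(imaging$seed)
  frames <- vector("list", imaging$n_frames)
  for (i in seq_len(imaging$n_frames)) {
    dft <- imaging$drift_per_frame[i, ]
    f <- if (all(dft == 0)) proj else fourier_shift(proj, dft[1], dft[2])
    if (imaging$noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), sd = imaging$noise_sigma),
                      nrow(f), ncol(f))
    frames[[i]] <- f
  }
  movie <- mt_movie(frames, imaging$pixel_size,
                    imaging$total_dose / imaging$n_frames)
  truth <- list(view = view, polarity = polarity,
                shifts = imaging$drift_per_frame,
                defocus = imaging$defocus,
                noise_sigma = imaging$noise_sigma, seed = imaging$seed)
  list(movie = movie, truth = truth)
}
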