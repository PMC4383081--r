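#' 3D density volume
#'
#' A cubic (or rectangular) voxel grid holding an EM density map. Data are
#' stored as a numeric 3D array indexed `[x, y, z]`; the filament axis is by
#' convention the z axis. `voxel` is the isotropic voxel edge in Angstrom and
#' `origin` the physical coordinate (Angstrom) of the *center* of voxel
#' `[1, 1, 1]`.
#'
#' @param data numeric 3D array.
#' @param voxel voxel size in Angstrom (> 0).
#' @param origin numeric length-3, Angstrom coordinate of the first voxel
#'   center. Default places the grid center at the physical origin.
#' @return an object of class `mt_volume`.
#' @export
mt_volume <- function(data, voxel, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.numeric(voxel), voxel > 0)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxel
  stopifnot(length(origin) == 3)
  structure(list(data = data, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)),
            class = "mt_volume")
}

#' @export
print.mt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mt_volume> %d x %d x %d voxels, %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel))
  cat(sprintf("  density range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) A\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Physical coordinates of voxel centers along each axis
#' @param vol an `mt_volume`.
#' @return list of numeric vectors `x`, `y`, `z` (Angstrom).
#' @keywords internal
volume_axes <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$voxel,
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$voxel,
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$voxel)
}

#' Multi-frame micrograph movie
#'
#' @param frames list of numeric matrices, identical dimensions. Image
#'   matrices are indexed `[row, col]`; the filament axis at zero in-plane
#'   angle runs along increasing row index (the image "column axis").
#' @param pixel_size pixel size in Angstrom.
#' @param dose_per_frame electrons per square Angstrom per frame.
#' @return object of class `mt_movie`.
#' @export
mt_movie <- function(frames, pixel_size, dose_per_frame = NA_real_) {
  stopifnot(is.list(frames), length(frames) >= 1, pixel_size > 0)
  d1 <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d1), logical(1))
  if (!all(ok)) stop("all movie frames must have identical dimensions")
  structure(list(frames = frames, pixel_size = as.numeric(pixel_size),
                 dose_per_frame = dose_per_frame),
            class = "mt_movie")
}

#' @export
print.mt_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<mt_movie> %d frames of %d x %d px, %.4g A/px\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Stack of boxed filament segments
#'
#' @param boxes list of square numeric matrices (uniform size).
#' @param pixel_size pixel size in Angstrom.
#' @param source_positions two-column matrix of (row, col) box-center
#'   positions on the source micrograph, 1-based pixel units.
#' @param box_step spacing between consecutive box centers in Angstrom.
#' @param meta optional data.frame of per-box metadata (filament id, repeat
#'   index, ...).
#' @return object of class `mt_segment_stack`.
#' @export
mt_segment_stack <- function(boxes, pixel_size, source_positions = NULL,
                             box_step = NA_real_, meta = NULL) {
  stopifnot(is.list(boxes), pixel_size > 0)
  if (length(boxes) > 0) {
    d1 <- dim(boxes[[1]])
    stopifnot(d1[1] == d1[2])
    ok <- vapply(boxes, function(b) identical(dim(b), d1), logical(1))
    if (!all(ok)) stop("all boxes must be square and the same size")
  }
  structure(list(boxes = boxes, pixel_size = as.numeric(pixel_size),
                 source_positions = source_positions, box_step = box_step,
                 meta = meta),
            class = "mt_segment_stack")
}

#' @export
print.mt_segment_stack <- function(x, ...) {
  n <- length(x$boxes)
  sz <- if (n) dim(x$boxes[[1]])[1] else 0
  cat(sprintf("<mt_segment_stack> %d boxes of %d x %d px, %.4g A/px\n",
              n, sz, sz, x$pixel_size))
  invisible(x)
}

#' @export
length.mt_segment_stack <- function(x) length(x$boxes)
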