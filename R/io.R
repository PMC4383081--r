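# File formats: MRC2014 maps (hand-written reader/writer; no installed R
# package covers MRC), PDB atomic models via bio3d, CSV tables for
# alignments and FSC curves, JSON for rigid transforms.

#' Write a volume or image as MRC2014 (mode 2, float)
#'
#' Voxel size is stored in the cell dimensions (`CELLA = n * voxel`) and
#' the physical origin in the MRC2014 origin words. Images are written as
#' single-section volumes.
#'
#' @param vol an [mt_volume()] or a numeric matrix (with `pixel_size`).
#' @param path output file path.
#' @param pixel_size required when `vol` is a bare matrix.
#' @return the path, invisibly.
#' @export
write_mrc <- function(vol, path, pixel_size = NULL) {
  if (is.matrix(vol)) {
    stopifnot(!is.null(pixel_size))
    vol <- mt_volume(array(vol, dim = c(dim(vol), 1)), pixel_size)
  }
  stopifnot(inherits(vol, "mt_volume"))
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2)                       # MODE 2: float32
  wi(c(0, 0, 0))              # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * vol$voxel)           # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))
  wi(1)                       # ISPG
  wi(0)                       # NSYMBT
  wi(rep(0, 25))              # EXTRA (words 25-49, 0-based)
  wf(vol$origin)              # ORIGIN (words 49-51, 0-based)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vol$data))     # RMS
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32); other modes raise
#' an explicit error. Axis order is taken as stored (MAPC/MAPR/MAPS =
#' 1/2/3 is assumed and checked).
#'
#' @param path MRC file path.
#' @return an [mt_volume()].
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("not an MRC file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                       # nstart
  m <- ri(3)                  # MX MY MZ
  cella <- rf(3)
  rf(3)                       # cellb
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order (MAPC/MAPR/MAPS = ",
         paste(mapcrs, collapse = "/"), ")")
  rf(3)                       # dmin dmax dmean
  ri(1); ri(1)                # ispg nsymbt
  seek(con, 4 * 49)
  origin <- rf(3)
  voxel <- if (m[1] > 0) cella[1] / m[1] else 1
  seek(con, 1024)
  nvox <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1,
                             signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    stop("unknown MRC mode: ", mode))
  if (length(data) < nvox) stop("truncated MRC data block in ", path)
  mt_volume(array(data, dim = d), voxel, origin)
}

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over bio3d's parser: keeps ATOM/HETATM records, resolves
#' alternate locations by highest occupancy, tolerates missing side-chain
#' atoms.
#'
#' @param path PDB file path.
#' @param model_id identifier stored with the model.
#' @return object of class `atomic_model`: data.frame `atoms` with
#'   columns `chain`, `resno`, `insert`, `resid`, `elety`, `element`,
#'   `x`, `y`, `z`, `occ`, `b`.
#' @export
read_model <- function(path, model_id = basename(path)) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep the highest-occupancy conformer per atom
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ii) {
    ii[which.max(at$o[ii])]
  }), use.names = FALSE)
  at <- at[sort(keep), ]
  atomic_model(data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z, occ = at$o, b = at$b,
    stringsAsFactors = FALSE), model_id = model_id)
}

#' Construct an atomic model
#'
#' @param atoms data.frame with at least `chain`, `resno`, `elety`, `x`,
#'   `y`, `z` (plus optional `insert`, `resid`, `element`, `occ`, `b`).
#' @param model_id identifier.
#' @return an `atomic_model`.
#' @export
atomic_model <- function(atoms, model_id = "model") {
  need <- c("chain", "resno", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$element))
    atoms$element <- substr(trimws(atoms$elety), 1, 1)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate (chain, residue, atom) keys")
  structure(list(atoms = atoms, model_id = model_id),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %s: %d atoms, %d residues, chains %s\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

#' Write an atomic model as PDB
#' @param model an `atomic_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, o = a$occ, b = a$b)
  invisible(path)
}

#' Coordinates of (a selection of) an atomic model
#'
#' @param model an `atomic_model`.
#' @param chain optional chain filter.
#' @param resno_range optional inclusive residue-number range `c(lo, hi)`.
#' @param elety optional atom-name filter (e.g. backbone
#'   `c("N","CA","C","O")`).
#' @return list with `coords` (n x 3 matrix) and `index` (row indices).
#' @export
model_selection <- function(model, chain = NULL, resno_range = NULL,
                            elety = NULL) {
  a <- model$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(resno_range))
    sel <- sel & a$resno >= resno_range[1] & a$resno <= resno_range[2]
  if (!is.null(elety)) sel <- sel & trimws(a$elety) %in% elety
  idx <- which(sel)
  list(coords = as.matrix(a[idx, c("x", "y", "z")]), index = idx)
}

#' Write / read an alignment record table as CSV
#' @param records alignment data.frame.
#' @param path file path.
#' @export
write_alignment_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment_csv
#' @export
read_alignment_csv <- function(path) utils::read.csv(path)

#' Write an FSC curve as a two-column CSV
#' @param curve an `fsc_curve`.
#' @param path file path.
#' @export
write_fsc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a rigid transform as JSON
#'
#' Rotation stored row-major plus the translation vector.
#' @param transform list with `rotation` (3x3) and `translation`
#'   (length 3).
#' @param path file path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.vector(t(transform$rotation)),
                            translation = transform$translation),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
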