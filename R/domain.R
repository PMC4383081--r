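# Rigid-body analysis of conformational change between atomic models:
# least-squares superposition, axis-angle / screw decomposition, backbone
# RMSD, hydrogen-bond network checks and steric-clash scanning.

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 vector, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            abs(det(rotation) - 1) < 1e-6)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- axis_angle(x)
  cat(sprintf("<rigid_transform> angle %.3f deg about (%.3f, %.3f, %.3f)\n",
              aa$angle, aa$axis[1], aa$axis[2], aa$axis[3]))
  invisible(x)
}

# apply a rigid transform to an n x 3 coordinate matrix
apply_transform <- function(transform, coords) {
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

# pair atoms of two models by (chain, resno, insert, atom name)
pair_atoms <- function(A, B, chain = NULL, resno_range = NULL,
                       elety = NULL) {
  sa <- model_selection(A, chain, resno_range, elety)
  sb <- model_selection(B, chain, resno_range, elety)
  ka <- with(A$atoms[sa$index, ], paste(chain, resno, insert, trimws(elety)))
  kb <- with(B$atoms[sb$index, ], paste(chain, resno, insert, trimws(elety)))
  common <- intersect(ka, kb)
  list(A = sa$coords[match(common, ka), , drop = FALSE],
       B = sb$coords[match(common, kb), , drop = FALSE],
       n = length(common),
       missing_A = setdiff(kb, ka), missing_B = setdiff(ka, kb))
}

# Kabsch: optimal proper rotation/translation mapping X onto Y
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  rigid_transform(R, t)
}

#' Least-squares superposition of two atomic models
#'
#' Pairs atoms by (chain, residue, atom name) over the selection and
#' computes the optimal proper rotation and translation mapping `A` onto
#' `B` (Kabsch). Unpaired atoms are reported; fewer than 3 pairs is an
#' error.
#'
#' @param A,B `atomic_model`s sharing a numbering scheme.
#' @param chain,resno_range,elety selection filters (see
#'   [model_selection()]).
#' @return list with `transform` ([rigid_transform()]), `rmsd` (Angstrom,
#'   over the selection after superposition), `n_pairs`, `missing`.
#' @export
superpose <- function(A, B, chain = NULL, resno_range = NULL, elety = NULL) {
  p <- pair_atoms(A, B, chain, resno_range, elety)
  if (p$n < 3) stop("need at least 3 paired atoms, have ", p$n)
  # collinearity guard
  if (min(svd(sweep(p$A, 2, colMeans(p$A)))$d) < 1e-8)
    stop("paired atoms are collinear; superposition is degenerate")
  tr <- kabsch(p$A, p$B)
  fitted <- apply_transform(tr, p$A)
  rmsd <- sqrt(mean(rowSums((fitted - p$B)^2)))
  list(transform = tr, rmsd = rmsd, n_pairs = p$n,
       missing = c(p$missing_A, p$missing_B))
}

#' Axis-angle (screw) decomposition of a rigid transform
#'
#' Rotation angle in `[0, 180]` degrees from the matrix trace; the axis
#' sign is chosen so the angle is non-negative. The screw point is the
#' point on the axis with minimal displacement (least-squares solution of
#' `(I - R) p = t_perp`). Angles below 0.1 degree leave the axis
#' undefined (flagged).
#'
#' @param transform a [rigid_transform()].
#' @return list: `angle` (degrees), `axis` (unit 3-vector), `point`
#'   (screw point), `defined` (logical).
#' @export
axis_angle <- function(transform) {
  R <- transform$rotation
  tr <- sum(diag(R))
  ang <- acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
  if (ang < 0.1) {
    return(list(angle = ang, axis = c(NA, NA, NA), point = c(NA, NA, NA),
                defined = FALSE))
  }
  if (ang < 179.9) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    ax <- ax / sqrt(sum(ax^2))
  } else {
    # near 180 degrees: axis from the eigenvector of R with eigenvalue +1
    ev <- eigen(R)
    i <- which.min(abs(Re(ev$values) - 1))
    ax <- Re(ev$vectors[, i])
    ax <- ax / sqrt(sum(ax^2))
  }
  t <- transform$translation
  t_perp <- t - sum(t * ax) * ax
  # least-squares point on the axis: (I - R) p = t_perp, minimal norm
  M <- diag(3) - R
  sv <- svd(M)
  dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
  p <- sv$v %*% (dinv * crossprod(sv$u, t_perp))
  list(angle = ang, axis = ax, point = as.vector(p), defined = TRUE)
}

#' Default motor-domain subdomain definitions
#'
#' Residue ranges splitting the kinesin motor domain into N-terminal,
#' upper and lower subdomains by dividing the central beta sheet between
#' the P-loop-anchoring and switch-II-anchoring strands. The exact
#' boundaries are a calibrated package default (the division is
#' structural, not a published residue table) and should be re-calibrated
#' against known rotation magnitudes before use on new models.
#'
#' @param chain chain identifier of the motor domain.
#' @return named list of data.frames (`chain`, `start`, `end`).
#' @export
default_subdomains <- function(chain = "K") {
  rng <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(chain = chain, start = m[, 1], end = m[, 2])
  }
  list(
    # P-loop half of the sheet plus helices alpha-1/alpha-2 and alpha-6
    n_terminal = rng(1, 90, 100, 150, 300, 340),
    # switch-I side: L7/L8 lobe and helix alpha-3
    upper = rng(151, 235),
    # switch II cluster: loop L11, helix alpha-4, L12, alpha-5
    lower = rng(236, 299)
  )
}

#' Per-subdomain rigid-body rotations between two states
#'
#' Both states are first superposed on a common frame selection (e.g.
#' tubulin, or the lower subdomain); each subdomain is then superposed
#' individually and its rotation reported as axis-angle. Subdomains with
#' fewer than 10 paired backbone atoms are excluded.
#'
#' @param stateA,stateB `atomic_model`s sharing numbering.
#' @param defs list of subdomain definitions (data.frames with `chain`,
#'   `start`, `end`), as from [default_subdomains()].
#' @param frame list with `chain` and/or `resno_range` defining the
#'   common reference frame; NULL superposes on all shared atoms.
#' @param elety atom names used for the fits (default CA).
#' @return data.frame: subdomain, angle (degrees), axis components,
#'   n_atoms, rmsd.
#' @export
subdomain_rotations <- function(stateA, stateB, defs = default_subdomains(),
                                frame = NULL, elety = "CA") {
  # align B onto A over the frame selection
  sp <- superpose(stateB, stateA,
                  chain = frame$chain, resno_range = frame$resno_range,
                  elety = elety)
  B2 <- stateB
  B2$atoms[, c("x", "y", "z")] <-
    apply_transform(sp$transform,
                    as.matrix(stateB$atoms[, c("x", "y", "z")]))
  out <- list()
  for (nm in names(defs)) {
    def <- defs[[nm]]
    pA <- NULL; pB <- NULL
    for (i in seq_len(nrow(def))) {
      p <- pair_atoms(stateA, B2, chain = def$chain[i],
                      resno_range = c(def$start[i], def$end[i]),
                      elety = elety)
      pA <- rbind(pA, p$A); pB <- rbind(pB, p$B)
    }
    if (is.null(pA) || nrow(pA) < 10) next
    tr <- kabsch(pA, pB)
    aa <- axis_angle(tr)
    rmsd <- sqrt(mean(rowSums((apply_transform(tr, pA) - pB)^2)))
    out[[nm]] <- data.frame(subdomain = nm, angle = aa$angle,
                            axis_x = aa$axis[1], axis_y = aa$axis[2],
                            axis_z = aa$axis[3], n_atoms = nrow(pA),
                            rmsd = rmsd)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Backbone RMSD between two models over a residue range
#'
#' Pairs backbone atoms (N, CA, C, O), superposes over the same
#' selection, and reports the post-fit RMSD.
#'
#' @param A,B `atomic_model`s.
#' @param resno_range inclusive residue range `c(lo, hi)`.
#' @param chain optional chain filter.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(A, B, resno_range = NULL, chain = NULL) {
  sp <- superpose(A, B, chain = chain, resno_range = resno_range,
                  elety = c("N", "CA", "C", "O"))
  sp$rmsd
}

#' Default closed switch-loop hydrogen-bond roster
#'
#' Signature interactions of the closed nucleotide-pocket network
#' (Y138, R203, E236, E250, N255) plus the K91 P-loop contact. Atom
#' choices are documented package defaults for heavy-atom criteria.
#'
#' @param chain motor-domain chain id.
#' @return data.frame of donor/acceptor atom pairs.
#' @export
default_hbond_network <- function(chain = "K") {
  data.frame(
    donor_chain = chain,
    donor_resno = c(138, 203, 255, 91),
    donor_atom = c("OH", "NH1", "ND2", "NZ"),
    acceptor_chain = chain,
    acceptor_resno = c(250, 236, 236, 231),
    acceptor_atom = c("OE1", "OE1", "O", "OD1"),
    label = c("Y138-E250", "R203-E236", "N255-E236bb", "K91-D231"),
    stringsAsFactors = FALSE)
}

#' Check hydrogen bonds between named donor/acceptor atom pairs
#'
#' A bond is present when the heavy-atom donor-acceptor distance is at
#' most `d_max` and, when an antecedent atom for the donor is available
#' in the model (the donor's bonded heavy atom, e.g. CZ for NH1), the
#' antecedent-donor-acceptor angle is at least `angle_min`. Pairs with
#' missing atoms are skipped and listed.
#'
#' @param model an `atomic_model`.
#' @param pairs data.frame as from [default_hbond_network()].
#' @param d_max maximum donor-acceptor distance, Angstrom.
#' @param angle_min minimum donor angle, degrees.
#' @return data.frame with distance, angle (NA if no antecedent),
#'   `present`, plus a `skipped` attribute naming unmatched pairs.
#' @export
hbond_check <- function(model, pairs = default_hbond_network(),
                        d_max = 3.5, angle_min = 120) {
  a <- model$atoms
  find_atom <- function(ch, rn, at) {
    i <- which(a$chain == ch & a$resno == rn & trimws(a$elety) == at)
    if (length(i)) i[1] else NA_integer_
  }
  # antecedent heavy atom of common donors (for the angle proxy)
  antecedent <- c(OH = "CZ", NH1 = "CZ", NH2 = "CZ", NE = "CD",
                  ND2 = "CG", NE2 = "CD", NZ = "CE", OG = "CB",
                  OG1 = "CB", N = "CA")
  out <- list(); skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    di <- find_atom(p$donor_chain, p$donor_resno, p$donor_atom)
    ai <- find_atom(p$acceptor_chain, p$acceptor_resno, p$acceptor_atom)
    if (is.na(di) || is.na(ai)) {
      skipped <- c(skipped, p$label)
      next
    }
    dxyz <- as.numeric(a[di, c("x", "y", "z")])
    axyz <- as.numeric(a[ai, c("x", "y", "z")])
    dist <- sqrt(sum((dxyz - axyz)^2))
    ang <- NA_real_
    ante <- antecedent[p$donor_atom]
    if (!is.na(ante)) {
      ci <- find_atom(p$donor_chain, p$donor_resno, unname(ante))
      if (!is.na(ci)) {
        cxyz <- as.numeric(a[ci, c("x", "y", "z")])
        v1 <- cxyz - dxyz; v2 <- axyz - dxyz
        ang <- acos(pmin(pmax(sum(v1 * v2) /
          sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      }
    }
    present <- dist <= d_max && (is.na(ang) || ang >= angle_min)
    out[[length(out) + 1]] <- data.frame(
      label = p$label, distance = dist, angle = ang, present = present)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(label = character(0), distance = numeric(0),
               angle = numeric(0), present = logical(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

# standard van der Waals radii by element (Angstrom)
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           MG = 1.73, F = 1.47, CL = 1.75)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Scan for steric clashes between two models
#'
#' Lists every inter-model atom pair whose van der Waals overlap
#' (`r_i + r_j - d`) is at least `overlap_threshold`, with per-residue
#' aggregation. A spatial cell grid accelerates the scan; `method =
#' "all"` forces the brute-force all-pairs reference path.
#'
#' @param mobile,fixed `atomic_model`s in a common frame.
#' @param overlap_threshold minimum overlap counted as a clash, Angstrom.
#' @param method `"grid"` (cell list) or `"all"` (all pairs).
#' @return list with `pairs` (data.frame) and `by_residue` (aggregated
#'   overlap per mobile residue).
#' @export
clash_scan <- function(mobile, fixed, overlap_threshold = 0.4,
                       method = c("grid", "all")) {
  method <- match.arg(method)
  am <- mobile$atoms; af <- fixed$atoms
  rm_ <- vdw_radius(am$element); rf <- vdw_radius(af$element)
  cut <- max(rm_) + max(rf)    # largest possible clash distance
  Xm <- as.matrix(am[, c("x", "y", "z")])
  Xf <- as.matrix(af[, c("x", "y", "z")])
  hits <- NULL
  if (method == "all") {
    for (i in seq_len(nrow(Xm))) {
      d2 <- rowSums(sweep(Xf, 2, Xm[i, ])^2)
      ov <- rm_[i] + rf - sqrt(d2)
      j <- which(ov >= overlap_threshold)
      if (length(j))
        hits <- rbind(hits, data.frame(i = i, j = j, overlap = ov[j]))
    }
  } else {
    cell <- cut
    key <- function(X) {
      k <- floor(sweep(X, 2, apply(rbind(Xm, Xf), 2, min)) / cell)
      paste(k[, 1], k[, 2], k[, 3])
    }
    kf <- key(Xf)
    cells <- split(seq_len(nrow(Xf)), kf)
    km <- floor(sweep(Xm, 2, apply(rbind(Xm, Xf), 2, min)) / cell)
    for (i in seq_len(nrow(Xm))) {
      neigh <- expand.grid(km[i, 1] + (-1:1), km[i, 2] + (-1:1),
                           km[i, 3] + (-1:1))
      ks <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
      j <- unlist(cells[intersect(ks, names(cells))], use.names = FALSE)
      if (!length(j)) next
      d2 <- rowSums(sweep(Xf[j, , drop = FALSE], 2, Xm[i, ])^2)
      ov <- rm_[i] + rf[j] - sqrt(d2)
      sel <- which(ov >= overlap_threshold)
      if (length(sel))
        hits <- rbind(hits, data.frame(i = i, j = j[sel],
                                       overlap = ov[sel]))
    }
  }
  if (is.null(hits)) {
    return(list(pairs = data.frame(), by_residue = data.frame()))
  }
  pairs <- data.frame(
    mobile_chain = am$chain[hits$i], mobile_resno = am$resno[hits$i],
    mobile_atom = trimws(am$elety[hits$i]),
    fixed_chain = af$chain[hits$j], fixed_resno = af$resno[hits$j],
    fixed_atom = trimws(af$elety[hits$j]),
    overlap = hits$overlap)
  o <- order(pairs$mobile_resno, pairs$fixed_resno)
  pairs <- pairs[o, ]
  rownames(pairs) <- NULL
  agg <- stats::aggregate(overlap ~ mobile_chain + mobile_resno, pairs,
                          function(v) c(n = length(v), max = max(v)))
  by_res <- data.frame(chain = agg$mobile_chain, resno = agg$mobile_resno,
                       n_clashes = agg$overlap[, "n"],
                       max_overlap = agg$overlap[, "max"])
  list(pairs = pairs, by_residue = by_res)
}
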