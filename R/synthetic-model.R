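# Synthetic coordinate models with known subdomain structure. These are
# package-generated stand-ins (clearly labelled synthetic) used to
# exercise and calibrate the rigid-body and flexible-fitting machinery
# with exactly known ground truth.

#' Build a synthetic motor-domain model
#'
#' A CA-only model of a motor-domain-sized fold (~340 residues, chain
#' `"K"`) whose residues are arranged in compact helical bundles grouped
#' into the three subdomain residue ranges of [default_subdomains()],
#' optionally anchored to a short fixed "tubulin" chain `"T"` that serves
#' as the common reference frame. Entirely synthetic: the geometry is a
#' convenient rigid scaffold, not a real structure.
#'
#' @param chain motor chain id.
#' @param with_anchor include the fixed anchor chain `"T"`.
#' @param seed integer seed for small coordinate jitter (makes the
#'   scaffold non-degenerate).
#' @return an `atomic_model`.
#' @export
synthetic_motor_model <- function(chain = "K", with_anchor = TRUE,
                                  seed = 7L) {
  set.seed(seed)
  helix <- function(n, origin, axis, radius = 2.3, rise = 1.5,
                    per_turn = 3.6) {
    axis <- axis / sqrt(sum(axis^2))
    # orthonormal frame around the axis
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2],
           axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    t <- seq_len(n)
    ang <- 2 * pi * t / per_turn
    ctr <- matrix(origin, n, 3, byrow = TRUE) + outer(t * rise, axis)
    ctr + radius * (outer(cos(ang), u) + outer(sin(ang), v))
  }
  defs <- default_subdomains(chain)
  centers <- list(n_terminal = c(0, 0, 0), upper = c(34, 12, 14),
                  lower = c(16, -32, 24))
  axes <- list(n_terminal = c(1, 0.2, 0.1), upper = c(0.2, 1, 0.3),
               lower = c(-0.3, 0.4, 1))
  rows <- list()
  for (nm in names(defs)) {
    def <- defs[[nm]]
    bundle_j <- 0
    for (i in seq_len(nrow(def))) {
      res <- def$start[i]:def$end[i]
      # compact antiparallel helix bundle: 18-residue helices side by side
      for (c0 in split(res, ceiling(seq_along(res) / 18))) {
        n <- length(c0)
        side <- c((bundle_j %% 3) * 6, ((bundle_j %/% 3) %% 3) * 6, 0)
        dirn <- if (bundle_j %% 2 == 0) 1 else -1
        xyz <- helix(n, centers[[nm]] + side + stats::rnorm(3, sd = 0.5),
                     dirn * (axes[[nm]] + stats::rnorm(3, sd = 0.05)))
        rows[[length(rows) + 1]] <- data.frame(
          chain = chain, resno = c0, insert = "", resid = "ALA",
          elety = "CA", element = "C",
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
          stringsAsFactors = FALSE)
        bundle_j <- bundle_j + 1
      }
    }
  }
  if (with_anchor) {
    xyz <- helix(60, c(-10, -45, -5), c(1, 0, 0), radius = 4, rise = 1.5)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "T", resno = 1:60, insert = "", resid = "GLY",
      elety = "CA", element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
      stringsAsFactors = FALSE)
  }
  atomic_model(do.call(rbind, rows), model_id = "synthetic_motor")
}

#' Rotate a subdomain of a model by a known angle
#'
#' Applies a rotation of `angle` degrees about `axis` through the
#' subdomain's centroid (or a supplied center) to the atoms in the
#' definition's residue ranges; all other atoms are untouched. Used to
#' construct states with exactly known subdomain motions.
#'
#' @param model an `atomic_model`.
#' @param def subdomain definition data.frame (`chain`, `start`, `end`).
#' @param angle rotation angle, degrees.
#' @param axis rotation axis (3-vector, normalized internally).
#' @param center rotation center (default: subdomain centroid).
#' @return the edited `atomic_model`.
#' @export
rotate_subdomain <- function(model, def, angle, axis = c(0, 0, 1),
                             center = NULL) {
  a <- model$atoms
  sel <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(def)))
    sel <- sel | (a$chain == def$chain[i] & a$resno >= def$start[i] &
                    a$resno <= def$end[i])
  X <- as.matrix(a[sel, c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(X)
  axis <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  Xr <- sweep(sweep(X, 2, center) %*% t(R), 2, center, "+")
  a[sel, c("x", "y", "z")] <- Xr
  m <- model
  m$atoms <- a
  m
}
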