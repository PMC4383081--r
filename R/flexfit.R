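# Density-steered flexible fitting: a coarse restrained-dynamics engine
# in reduced units (thermal energy k_BT = 1, lengths in Angstrom).
# Stereochemistry is maintained by harmonic restraints to the starting
# local geometry (chain bonds and next-neighbor distances, optionally an
# elastic network); the EM map enters as a steering energy
# E = -xi(t) * w * Phi(x) applied to a selected subset of atoms
# (backbone by default), with xi following a linear ramp from zero.

#' Build a steering potential from a density map
#'
#' Low-pass filters the map (6 Angstrom cutoff by default, suppressing
#' noise beyond the resolution support), clamps negative values to zero
#' and rescales to `[0, 1]`. The steering energy of an atom at `x` is
#' `-xi * w * Phi(x)`.
#'
#' @param map an [mt_volume()].
#' @param cutoff low-pass cutoff, Angstrom (>= 2 voxels).
#' @return object of class `potential_grid`.
#' @export
build_density_potential <- function(map, cutoff = 6) {
  stopifnot(inherits(map, "mt_volume"))
  if (max(abs(map$data)) == 0) stop("all-zero map")
  if (cutoff < 2 * map$voxel)
    stop("cutoff must be at least twice the voxel size")
  d <- lowpass_field(map$data, map$voxel, cutoff)
  d[d < 0] <- 0
  d <- d / max(d)
  structure(list(data = d, voxel = map$voxel, origin = map$origin),
            class = "potential_grid")
}

#' Evaluate a potential grid and its gradient
#'
#' Trilinear interpolation of the value and its analytic gradient at
#' arbitrary points; both are zero outside the grid interior.
#'
#' @param pot a `potential_grid`.
#' @param coords n x 3 matrix, Angstrom.
#' @return list with `value` (n) and `gradient` (n x 3, per Angstrom).
#' @export
potential_eval <- function(pot, coords) {
  coords <- as.matrix(coords)
  d <- dim(pot$data)
  g <- sweep(coords, 2, pot$origin) / pot$voxel + 1  # fractional index
  i0 <- floor(g)
  f <- g - i0
  n <- nrow(coords)
  val <- numeric(n)
  grad <- matrix(0, n, 3)
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  if (any(ok)) {
    ii <- i0[ok, , drop = FALSE]; ff <- f[ok, , drop = FALSE]
    c_ <- function(dx, dy, dz)
      pot$data[cbind(ii[, 1] + dx, ii[, 2] + dy, ii[, 3] + dz)]
    v000 <- c_(0, 0, 0); v100 <- c_(1, 0, 0)
    v010 <- c_(0, 1, 0); v110 <- c_(1, 1, 0)
    v001 <- c_(0, 0, 1); v101 <- c_(1, 0, 1)
    v011 <- c_(0, 1, 1); v111 <- c_(1, 1, 1)
    fx <- ff[, 1]; fy <- ff[, 2]; fz <- ff[, 3]
    # interpolate along x, then y, then z
    c00 <- v000 * (1 - fx) + v100 * fx
    c10 <- v010 * (1 - fx) + v110 * fx
    c01 <- v001 * (1 - fx) + v101 * fx
    c11 <- v011 * (1 - fx) + v111 * fx
    c0 <- c00 * (1 - fy) + c10 * fy
    c1 <- c01 * (1 - fy) + c11 * fy
    val[ok] <- c0 * (1 - fz) + c1 * fz
    dx00 <- v100 - v000; dx10 <- v110 - v010
    dx01 <- v101 - v001; dx11 <- v111 - v011
    gx <- ((dx00 * (1 - fy) + dx10 * fy) * (1 - fz) +
           (dx01 * (1 - fy) + dx11 * fy) * fz) / pot$voxel
    gy <- ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / pot$voxel
    gz <- (c1 - c0) / pot$voxel
    grad[ok, 1] <- gx; grad[ok, 2] <- gy; grad[ok, 3] <- gz
  }
  list(value = val, gradient = grad, inside = ok)
}

#' Linear coupling ramp schedule
#'
#' `xi(step) = xi_max * step / ramp_steps` (capped at `xi_max`): the
#' coupling starts at zero and increases linearly over the ramp.
#'
#' @param xi_max final coupling (reduced units, energy per unit
#'   normalized density).
#' @param ramp_steps steps over which the ramp rises.
#' @param dt integration time step (reduced units).
#' @return object of class `steering_schedule`.
#' @export
steering_schedule <- function(xi_max = 20, ramp_steps = 5000, dt = 0.01) {
  stopifnot(xi_max >= 0, ramp_steps >= 1, dt > 0)
  structure(list(xi_max = xi_max, ramp_steps = as.integer(ramp_steps),
                 dt = dt),
            class = "steering_schedule")
}

#' @export
print.steering_schedule <- function(x, ...) {
  cat(sprintf("<steering_schedule> linear ramp 0 -> %.3g over %d steps (dt %.3g)\n",
              x$xi_max, x$ramp_steps, x$dt))
  invisible(x)
}

#' Remove ligands and delete residue ranges from a model
#'
#' @param model an `atomic_model`.
#' @param remove_ligands residue names (e.g. `"ATP"`, `"MG"`) to remove.
#' @param delete_ranges list of lists with `chain`, `start`, `end`
#'   (inclusive residue numbers) to delete.
#' @return edited `atomic_model`; remaining numbering untouched.
#' @export
prepare_model <- function(model, remove_ligands = character(0),
                          delete_ranges = list()) {
  a <- model$atoms
  for (lig in remove_ligands) {
    hit <- a$resid == lig
    if (!any(hit)) stop("ligand not present in model: ", lig)
    a <- a[!hit, ]
  }
  for (rg in delete_ranges) {
    hit <- a$chain == rg$chain & a$resno >= rg$start & a$resno <= rg$end
    if (!any(hit))
      stop(sprintf("no residues %d-%d in chain %s", rg$start, rg$end,
                   rg$chain))
    a <- a[!hit, ]
  }
  rownames(a) <- NULL
  atomic_model(a, model_id = model$model_id)
}

# build the stereochemical pair list: consecutive (i, i+1) and
# next-neighbor (i, i+2) restraints within each chain, plus an optional
# elastic network (all pairs within en_cutoff at start) that maintains
# local tertiary geometry; all restrained to the starting distances
stereo_pairs <- function(model, k_bond = 50, k_angle = 10,
                         en_cutoff = 0, k_en = 2) {
  a <- model$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  pairs <- NULL
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    idx <- idx[order(a$resno[idx])]
    n <- length(idx)
    if (n >= 2)
      pairs <- rbind(pairs, cbind(idx[1:(n - 1)], idx[2:n], k_bond))
    if (n >= 3)
      pairs <- rbind(pairs, cbind(idx[1:(n - 2)], idx[3:n], k_angle))
  }
  if (en_cutoff > 0) {
    cut2 <- en_cutoff^2
    for (i in seq_len(nrow(X) - 1)) {
      d2 <- rowSums(sweep(X[(i + 1):nrow(X), , drop = FALSE], 2,
                          X[i, ])^2)
      j <- which(d2 <= cut2) + i
      j <- j[j > i + 2]   # chain terms already present
      if (length(j))
        pairs <- rbind(pairs, cbind(i, j, k_en))
    }
  }
  d0 <- sqrt(rowSums((X[pairs[, 1], ] - X[pairs[, 2], ])^2))
  list(i = pairs[, 1], j = pairs[, 2], k = pairs[, 3], d0 = d0)
}

#' Density-steered ramped fitting
#'
#' Overdamped Langevin dynamics on the model coordinates under the sum of
#' (i) harmonic stereochemical restraints to the starting local geometry,
#' (ii) optional positional restraints, and (iii) the EM steering energy
#' `-xi(t) * Phi(x)` applied only to the steering selection (protein
#' backbone atoms by default). The coupling follows the linear ramp of
#' the schedule. Fully seeded and deterministic.
#'
#' @param model starting `atomic_model`.
#' @param potential a `potential_grid`.
#' @param schedule a [steering_schedule()].
#' @param steer_selection atom names feeling the steering force (default
#'   backbone + CA-only models).
#' @param positional optional list with `index` (atom rows) and `k`
#'   (spring constant) and optionally `ref` (reference coords; default
#'   start).
#' @param temperature reduced temperature (k_BT units; 0 for pure
#'   descent).
#' @param gamma friction coefficient.
#' @param record_every record a trajectory frame every this many steps.
#' @param n_steps total steps (default: ramp length).
#' @param seed integer seed for the thermal noise.
#' @param k_bond,k_angle stereochemical spring constants.
#' @param en_cutoff elastic-network cutoff (Angstrom; 0 disables) and
#'   `k_en` its spring constant -- local tertiary restraints to the
#'   starting geometry.
#' @return object of class `fit_trajectory`: `frames` (list of coordinate
#'   matrices), `xi` (per frame), `energy` (per frame), `step` (frame
#'   step numbers), `model`, `aborted`.
#' @export
ramped_fit <- function(model, potential, schedule = steering_schedule(),
                       steer_selection = c("N", "CA", "C", "O"),
                       positional = NULL, temperature = 1, gamma = 1,
                       record_every = 50, n_steps = NULL, seed = 1L,
                       k_bond = 20, k_angle = 5, en_cutoff = 8, k_en = 1) {
  a <- model$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  X0 <- X
  if (is.null(n_steps)) n_steps <- schedule$ramp_steps
  sp <- stereo_pairs(model, k_bond, k_angle, en_cutoff, k_en)
  steer <- trimws(a$elety) %in% steer_selection
  if (!any(steer)) stop("empty steering selection")
  pos_idx <- positional$index
  pos_k <- positional$k
  pos_ref <- if (!is.null(positional$ref)) positional$ref else
    X0[pos_idx, , drop = FALSE]
  dt <- schedule$dt
  set.seed(seed)
  frames <- list(); xis <- numeric(0); energies <- numeric(0)
  steps <- integer(0)
  aborted <- FALSE
  sqrt_term <- sqrt(2 * dt * temperature / gamma)
  for (s in seq_len(n_steps)) {
    xi <- schedule$xi_max * min(s / schedule$ramp_steps, 1)
    # stereochemical forces
    dvec <- X[sp$i, ] - X[sp$j, ]
    dlen <- sqrt(rowSums(dvec^2))
    fmag <- -sp$k * (dlen - sp$d0) / pmax(dlen, 1e-9)
    fpair <- dvec * fmag
    F <- matrix(0, nrow(X), 3)
    for (cc in 1:3) {
      acc <- numeric(nrow(X))
      s1 <- rowsum(fpair[, cc], sp$i)
      acc[as.integer(rownames(s1))] <- s1
      s2 <- rowsum(-fpair[, cc], sp$j)
      acc[as.integer(rownames(s2))] <- acc[as.integer(rownames(s2))] + s2
      F[, cc] <- acc
    }
    e_stereo <- 0.5 * sum(sp$k * (dlen - sp$d0)^2)
    e_pos <- 0
    if (!is.null(pos_idx) && length(pos_idx)) {
      dpos <- X[pos_idx, , drop = FALSE] - pos_ref
      F[pos_idx, ] <- F[pos_idx, ] - pos_k * dpos
      e_pos <- 0.5 * pos_k * sum(dpos^2)
    }
    e_em <- 0
    if (xi > 0) {
      pe <- potential_eval(potential, X[steer, , drop = FALSE])
      if (!all(pe$inside)) {
        warning("steered atom left the potential grid at step ", s,
                "; aborting fit")
        aborted <- TRUE
        break
      }
      F[steer, ] <- F[steer, ] + xi * pe$gradient
      e_em <- -xi * sum(pe$value)
    }
    X <- X + dt * F / gamma
    if (temperature > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = sqrt_term),
                      nrow(X), 3)
    etot <- e_stereo + e_pos + e_em
    if (!is.finite(etot) || etot > 1e12) {
      warning("energy diverged at step ", s, "; aborting fit")
      aborted <- TRUE
      break
    }
    if (s %% record_every == 0 || s == n_steps) {
      frames[[length(frames) + 1]] <- X
      xis <- c(xis, xi)
      energies <- c(energies, etot)
      steps <- c(steps, s)
    }
  }
  structure(list(frames = frames, xi = xis, energy = energies,
                 step = steps, model = model, dt = dt,
                 steer = which(steer), aborted = aborted),
            class = "fit_trajectory")
}

#' @export
print.fit_trajectory <- function(x, ...) {
  cat(sprintf("<fit_trajectory> %d frames (%d steps, dt %.3g), xi %.3g -> %.3g%s\n",
              length(x$frames), max(x$step), x$dt,
              if (length(x$xi)) x$xi[1] else NA,
              if (length(x$xi)) x$xi[length(x$xi)] else NA,
              if (x$aborted) " [aborted]" else ""))
  invisible(x)
}

#' Per-group RMSD convergence curves of a trajectory
#'
#' Backbone RMSD of each frame against a reference model, computed
#' separately for named atom groups, in the absolute frame (no
#' re-superposition) by default -- appropriate when part of the system is
#' positionally restrained.
#'
#' @param traj a `fit_trajectory`.
#' @param reference reference `atomic_model` (default: the trajectory's
#'   starting model).
#' @param groups named list of atom row-index vectors.
#' @return data.frame: `frame`, `step`, `xi`, one RMSD column per group.
#' @export
convergence_curves <- function(traj, reference = traj$model,
                               groups = list(all = seq_len(nrow(traj$model$atoms)))) {
  Xr <- as.matrix(reference$atoms[, c("x", "y", "z")])
  out <- data.frame(frame = seq_along(traj$frames), step = traj$step,
                    xi = traj$xi)
  for (nm in names(groups)) {
    g <- groups[[nm]]
    out[[nm]] <- vapply(traj$frames, function(Xf)
      sqrt(mean(rowSums((Xf[g, , drop = FALSE] -
                         Xr[g, , drop = FALSE])^2))), numeric(1))
  }
  out
}

#' Select the fitted frame from convergence curves
#'
#' Smooths the RMSD curve (5-frame moving average), computes its
#' derivative, and returns the first frame after the initial rapid
#' transition: the first frame where the derivative falls below 10
#' percent of its peak and stays below for a window (10 percent of the
#' trajectory). Flat curves return the first frame, flagged; curves that
#' never plateau return the last frame, flagged.
#'
#' @param curve numeric RMSD series (one group's column from
#'   [convergence_curves()]).
#' @param window plateau window length in frames (default 10 percent).
#' @param smooth moving-average half-width in frames.
#' @return list with `frame`, `flag` (NA, `"flat"`, or `"no_plateau"`).
#' @export
select_fit_frame <- function(curve, window = max(2, round(0.1 * length(curve))),
                             smooth = 5) {
  n <- length(curve)
  if (n < 4) return(list(frame = 1L, flag = "flat"))
  sm <- stats::filter(curve, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- curve[is.na(sm)]
  dv <- abs(diff(sm))
  peak <- max(dv)
  if (peak < 1e-9 * max(abs(curve), 1e-12)) {
    return(list(frame = 1L, flag = "flat"))
  }
  thr <- 0.1 * peak
  below <- dv < thr
  ipeak <- which.max(dv)
  for (i in (ipeak + 1):length(below)) {
    if (i + window - 1 > length(below)) break
    if (all(below[i:(i + window - 1)])) {
      return(list(frame = i + 1L, flag = NA_character_))
    }
  }
  list(frame = as.integer(n), flag = "no_plateau")
}

#' Restrained follow-up (stability) run
#'
#' Continues dynamics from a fitted model with the steering potential
#' switched off and positional restraints on a selection (e.g. tubulin
#' residues 1-380, leaving the motor-binding helices free). Reports the
#' final backbone RMSD from the fitted model and the per-bond persistence
#' of a supplied interaction list.
#'
#' @param fitted fitted `atomic_model`.
#' @param restrain_index atom rows under positional restraint.
#' @param k_pos positional spring constant (default 20, the
#'   kcal/mol/Angstrom-tier restraint expressed in reduced units).
#' @param n_steps run length.
#' @param bonds optional data.frame of atom index pairs `i`, `j` with
#'   `cutoff` (Angstrom) whose persistence is monitored.
#' @param ... further arguments to [ramped_fit()].
#' @return list with `trajectory`, `drift` (final RMSD vs fitted, all
#'   atoms), `bond_persistence` (fraction of frames each bond holds).
#' @export
stability_run <- function(fitted, restrain_index, k_pos = 20,
                          n_steps = 2000, bonds = NULL, ...) {
  sched <- steering_schedule(xi_max = 0, ramp_steps = n_steps)
  dummy_pot <- structure(list(data = array(1, c(2, 2, 2)), voxel = 1,
                              origin = c(0, 0, 0)),
                         class = "potential_grid")
  traj <- ramped_fit(fitted, dummy_pot, sched,
                     positional = list(index = restrain_index, k = k_pos),
                     n_steps = n_steps, ...)
  X0 <- as.matrix(fitted$atoms[, c("x", "y", "z")])
  Xf <- traj$frames[[length(traj$frames)]]
  drift <- sqrt(mean(rowSums((Xf - X0)^2)))
  pers <- NULL
  if (!is.null(bonds)) {
    pers <- vapply(seq_len(nrow(bonds)), function(b) {
      mean(vapply(traj$frames, function(X)
        sqrt(sum((X[bonds$i[b], ] - X[bonds$j[b], ])^2)) <= bonds$cutoff[b],
        logical(1)))
    }, numeric(1))
  }
  list(trajectory = traj, drift = drift, bond_persistence = pers)
}
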