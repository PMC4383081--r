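# Stopped-flow mant-ADP release kinetics: simulation of single-exponential
# fluorescence decays whose observed rate saturates hyperbolically with
# microtubule concentration, and the corresponding two-stage fit
# (per-trace exponential, then hyperbola across concentrations).

#' Ground-truth kinetic parameters
#'
#' The hyperbolic rate law is
#' `k_obs([MT]) = k_basal + k_max * [MT] / (K_half + [MT])`.
#' Defaults are the microtubule-stimulated mant-ADP release parameters
#' measured for the N255K motor construct: `k_max` 0.26 1/s and `K_half`
#' 21.3 micromolar.
#'
#' @param k_max maximal stimulated release rate, 1/s.
#' @param K_half apparent half-saturation microtubule concentration, uM.
#' @param k_basal basal release rate, 1/s (default 0).
#' @param amplitude fluorescence decay amplitude, a.u.
#' @param offset fluorescence offset, a.u.
#' @return object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(k_max = 0.26, K_half = 21.3, k_basal = 0,
                          amplitude = 1, offset = 0.2) {
  stopifnot(k_max > 0, K_half > 0, k_basal >= 0)
  structure(list(k_max = k_max, K_half = K_half, k_basal = k_basal,
                 amplitude = amplitude, offset = offset),
            class = "kinetic_truth")
}

#' Observed rate at a microtubule concentration
#' @param truth a [kinetic_truth()].
#' @param mt_conc microtubule concentration(s), uM.
#' @return k_obs in 1/s.
#' @export
k_obs_true <- function(truth, mt_conc) {
  truth$k_basal + truth$k_max * mt_conc / (truth$K_half + mt_conc)
}

#' Simulate a stopped-flow kinetics dataset
#'
#' Each trace is `offset + amplitude * exp(-k_obs([MT]) * t)` plus additive
#' Gaussian noise; fully seeded and reproducible.
#'
#' @param truth a [kinetic_truth()].
#' @param mt_concs microtubule concentrations, uM (>= 0).
#' @param t_grid strictly increasing time points, s.
#' @param noise_sigma Gaussian noise sd in fluorescence a.u. (>= 0).
#' @param n_reps replicates per concentration.
#' @param seed integer seed.
#' @return object of class `kinetic_dataset`: data.frame `traces` with
#'   columns `mt_conc_uM`, `replicate`, `time_s`, `fluorescence`, plus the
#'   generating `truth`.
#' @export
simulate_kinetics <- function(truth, mt_concs, t_grid, noise_sigma = 0,
                              n_reps = 1, seed = 1L) {
  stopifnot(inherits(truth, "kinetic_truth"), all(mt_concs >= 0),
            all(diff(t_grid) > 0))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  set.seed(seed)
  out <- list(); i <- 0L
  for (conc in mt_concs) {
    k <- k_obs_true(truth, conc)
    for (rep in seq_len(n_reps)) {
      i <- i + 1L
      y <- truth$offset + truth$amplitude * exp(-k * t_grid)
      if (noise_sigma > 0) y <- y + stats::rnorm(length(y), sd = noise_sigma)
      out[[i]] <- data.frame(mt_conc_uM = conc, replicate = rep,
                             time_s = t_grid, fluorescence = y)
    }
  }
  structure(list(traces = do.call(rbind, out), truth = truth),
            class = "kinetic_dataset")
}

#' Write / read a kinetics dataset as CSV
#' @param dataset a `kinetic_dataset` (or its `traces` data.frame).
#' @param path file path.
#' @return `read_kinetics` returns a `kinetic_dataset` (truth unknown).
#' @export
write_kinetics <- function(dataset, path) {
  tr <- if (inherits(dataset, "kinetic_dataset")) dataset$traces else dataset
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("mt_conc_uM", "replicate", "time_s", "fluorescence")
  if (!all(need %in% names(tr)))
    stop("kinetics CSV must have columns: ", paste(need, collapse = ", "))
  structure(list(traces = tr, truth = NULL), class = "kinetic_dataset")
}

#' Fit a single-exponential decay to one fluorescence trace
#'
#' Model: `F(t) = offset + amplitude * exp(-k * t)`, nonlinear least
#' squares with starting values from a log-linear regression of the
#' baseline-subtracted trace.
#'
#' @param time_s time points, s.
#' @param fluorescence fluorescence values, a.u.
#' @return list with `k_obs`, `amplitude`, `offset`, `stderr_k`,
#'   `converged`, `flag` (NA or a character diagnostic).
#' @export
fit_exponential <- function(time_s, fluorescence) {
  stopifnot(length(time_s) == length(fluorescence), length(time_s) >= 10)
  y <- fluorescence; t <- time_s
  off0 <- min(y)
  amp0 <- max(y) - off0
  flag <- NA_character_
  if (amp0 <= .Machine$double.eps * max(abs(y), 1) ||
      stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    return(list(k_obs = NA_real_, amplitude = 0, offset = mean(y),
                stderr_k = NA_real_, converged = FALSE,
                flag = "unidentifiable: constant trace"))
  }
  ypos <- pmax(y - off0 + 0.05 * amp0, 1e-12)
  k0 <- unname(-stats::coef(stats::lm(log(ypos) ~ t))[2])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amplitude * exp(-k * t),
                      start = list(offset = off0, amplitude = amp0, k = k0),
                      lower = c(-Inf, 0, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(k_obs = NA_real_, amplitude = NA_real_, offset = NA_real_,
                stderr_k = NA_real_, converged = FALSE,
                flag = "non-convergence"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  if (cf["k"] <= 2e-8) flag <- "rate at lower bound"
  if (cf["amplitude"] < 1e-6 * max(abs(y)))
    flag <- "unidentifiable: near-zero amplitude"
  list(k_obs = unname(cf["k"]), amplitude = unname(cf["amplitude"]),
       offset = unname(cf["offset"]), stderr_k = unname(se),
       converged = TRUE, flag = flag)
}

#' Fit the hyperbolic microtubule dependence of the observed rate
#'
#' Least-squares fit of `k_obs = k_basal + k_max * [MT] / (K_half + [MT])`
#' to a table of per-trace rates. `k_basal` is fixed at 0 by default.
#'
#' @param mt_conc microtubule concentrations, uM.
#' @param k_obs observed rates, 1/s.
#' @param fit_basal logical: also fit `k_basal` (default FALSE).
#' @return object of class `kinetic_fit` with fields `k_max`, `K_half`,
#'   `k_basal`, `stderr` (named vector), `flags`, `data`, and the `nls`
#'   fit object.
#' @export
fit_hyperbola <- function(mt_conc, k_obs, fit_basal = FALSE) {
  ok <- is.finite(mt_conc) & is.finite(k_obs)
  mt <- mt_conc[ok]; ko <- k_obs[ok]
  if (length(unique(mt)) < 3) stop("need k_obs at >= 3 distinct concentrations")
  kmax0 <- max(ko)
  kh0 <- stats::median(mt)
  flags <- character(0)
  if (fit_basal) {
    fit <- minpack.lm::nlsLM(
      ko ~ kb + kmax * mt / (kh + mt),
      start = list(kb = max(min(ko), 1e-6), kmax = kmax0, kh = kh0),
      lower = c(0, 1e-10, 1e-10))
    cf <- stats::coef(fit)
    kb <- unname(cf["kb"])
  } else {
    fit <- minpack.lm::nlsLM(
      ko ~ kmax * mt / (kh + mt),
      start = list(kmax = kmax0, kh = kh0),
      lower = c(1e-10, 1e-10))
    cf <- stats::coef(fit)
    kb <- 0
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (max(mt) < unname(cf["kh"]))
    flags <- c(flags, "K_half poorly determined: all concentrations below K_half")
  structure(list(k_max = unname(cf["kmax"]), K_half = unname(cf["kh"]),
                 k_basal = kb,
                 stderr = c(k_max = unname(se["kmax"]),
                            K_half = unname(se["kh"])),
                 flags = flags,
                 data = data.frame(mt_conc_uM = mt, k_obs = ko),
                 fit = fit),
            class = "kinetic_fit")
}

#' Fit a whole kinetics dataset
#'
#' Runs [fit_exponential()] on every trace, then [fit_hyperbola()] on the
#' per-trace rates.
#'
#' @param dataset a `kinetic_dataset`.
#' @param fit_basal passed to [fit_hyperbola()].
#' @return a `kinetic_fit` with an extra `per_trace` data.frame.
#' @export
fit_kinetics <- function(dataset, fit_basal = FALSE) {
  tr <- dataset$traces
  key <- interaction(tr$mt_conc_uM, tr$replicate, drop = TRUE)
  rows <- lapply(split(tr, key), function(d) {
    f <- fit_exponential(d$time_s, d$fluorescence)
    data.frame(mt_conc_uM = d$mt_conc_uM[1], replicate = d$replicate[1],
               k_obs = f$k_obs, amplitude = f$amplitude, offset = f$offset,
               flag = ifelse(is.na(f$flag), "", f$flag))
  })
  per_trace <- do.call(rbind, rows)
  rownames(per_trace) <- NULL
  hf <- fit_hyperbola(per_trace$mt_conc_uM, per_trace$k_obs,
                      fit_basal = fit_basal)
  hf$per_trace <- per_trace
  hf
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Hyperbolic microtubule-activation fit\n")
  cat(sprintf("  k_max  = %.4g +/- %.2g 1/s\n", x$k_max, x$stderr["k_max"]))
  cat(sprintf("  K_half = %.4g +/- %.2g uM\n", x$K_half, x$stderr["K_half"]))
  if (x$k_basal != 0) cat(sprintf("  k_basal = %.4g 1/s\n", x$k_basal))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(k_max = object$k_max, K_half = object$K_half, k_basal = object$k_basal)
}

#' @export
predict.kinetic_fit <- function(object, mt_conc, ...) {
  object$k_basal + object$k_max * mt_conc / (object$K_half + mt_conc)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  d <- x$data
  plot(d$mt_conc_uM, d$k_obs, xlab = "[MT] (uM)",
       ylab = expression(k[obs] ~ (s^-1)), pch = 19, ...)
  cs <- seq(0, max(d$mt_conc_uM) * 1.05, length.out = 200)
  graphics::lines(cs, predict(x, cs), col = "red3")
  invisible(x)
}
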