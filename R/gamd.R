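#' Estimate boost parameters from unbiased potential-energy samples
#'
#' From the statistics (`Vmax`, `Vmin`, `Vmean`, `sigmaV`) of an unbiased
#' run, the effective harmonic constant is `k = k0 / (Vmax - Vmin)` with
#' `k0 = min(1, (sigma0 / sigmaV) * (Vmax - Vmin) / (Vmax - Vmean))`, which
#' caps the predicted boost standard deviation
#' `k * (E_threshold - Vmean) * sigmaV` at the user limit `sigma0`. The
#' energy threshold defaults to the conservative lower bound
#' `E_threshold = Vmax`; the upper-bound variant `Vmin + 1/k` is available
#' via `threshold = "upper"`.
#'
#' @param v_samples unbiased potential energies (kcal/mol), length >= 2
#' @param sigma0 user cap on the boost standard deviation (kcal/mol)
#' @param threshold `"lower"` (`E = Vmax`) or `"upper"` (`E = Vmin + 1/k`)
#' @return object of class `boost_parameters`
#' @export
estimate_boost_params <- function(v_samples, sigma0 = 6,
                                  threshold = c("lower", "upper")) {
  threshold <- match.arg(threshold)
  if (length(v_samples) < 2) stop("need at least 2 potential samples")
  vmax <- max(v_samples); vmin <- min(v_samples); vmean <- mean(v_samples)
  sv <- stats::sd(v_samples)
  if (vmax == vmin) stop("degenerate statistics: Vmax equals Vmin")
  if (sv == 0) stop("degenerate statistics: zero potential variance")
  if (sigma0 < 0) stop("sigma0 must be >= 0")
  k0 <- min(1, (sigma0 / sv) * (vmax - vmin) / (vmax - vmean))
  k <- k0 / (vmax - vmin)
  E <- if (threshold == "lower" || k == 0) vmax else vmin + 1 / k
  p <- structure(list(Vmax = vmax, Vmin = vmin, Vmean = vmean, sigmaV = sv,
                      sigma0 = sigma0, k0 = k0, k = k, E_threshold = E),
                 class = "boost_parameters")
  validate_boost_params(p)
  p
}

validate_boost_params <- function(p) {
  stopifnot(p$Vmin <= p$Vmean, p$Vmean <= p$Vmax,
            p$k0 >= 0, p$k0 <= 1,
            p$k <= 1 / (p$Vmax - p$Vmin) + 1e-12)
  if (p$k > 0)
    stopifnot(p$E_threshold >= p$Vmax - 1e-9,
              p$E_threshold <= p$Vmin + 1 / p$k + 1e-9)
  # predicted boost spread stays under the user cap
  stopifnot(p$k * (p$E_threshold - p$Vmean) * p$sigmaV <= p$sigma0 + 1e-9)
  invisible(p)
}

#' @export
print.boost_parameters <- function(x, ...) {
  cat(sprintf(paste0("boost_parameters: k0 = %.4f, k = %.4g 1/(kcal/mol), ",
                     "E = %.3f kcal/mol\n  V in [%.3f, %.3f], mean %.3f, sd %.3f, sigma0 = %.2f\n"),
              x$k0, x$k, x$E_threshold, x$Vmin, x$Vmax, x$Vmean, x$sigmaV,
              x$sigma0))
  invisible(x)
}

#' Apply the boost potential to potential energies
#'
#' Below the threshold the boost is the harmonic fill
#' `0.5 k (E_threshold - V)^2`; at or above the threshold it is zero and the
#' potential is untouched.
#'
#' @param v potential energies (kcal/mol), vectorised
#' @param params a `boost_parameters` object
#' @return list with `V_updated` and `V_boost`
#' @export
gamd_boost <- function(v, params) {
  below <- v < params$E_threshold
  vb <- ifelse(below, 0.5 * params$k * (params$E_threshold - v)^2, 0)
  list(V_updated = v + vb, V_boost = vb)
}

#' Run Gaussian-accelerated Langevin dynamics
#'
#' If `params` is omitted, an unbiased pre-stage of
#' `ceiling(cmd_fraction * n_steps)` steps is run first, boost parameters are
#' estimated from its potential-energy trace, and production starts from its
#' final configuration; re-estimation is disabled once production starts.
#' With explicit `params` the production run starts from the system's
#' reference coordinates, so `k0 = 0` reproduces [run_cmd()] exactly at equal
#' seed.
#'
#' @param system a `toy_system`
#' @param config an [integrator_config()]
#' @param params optional `boost_parameters`
#' @param sigma0 boost-spread cap used when estimating parameters
#' @param cmd_fraction pre-stage length as a fraction of `n_steps`
#' @return a `trajectory_ensemble` with provenance `"GaMD"` and per-frame
#'   boost potentials; the parameters used are attached as attribute
#'   `boost_params`
#' @export
run_gamd <- function(system, config, params = NULL, sigma0 = 6,
                     cmd_fraction = 0.2) {
  pack <- engine_pack(system)
  set.seed(config$seed)
  x0 <- system$pos
  if (is.null(params)) {
    pre_steps <- as.integer(ceiling(cmd_fraction * config$n_steps))
    pre <- cpp_run_dynamics(pack, x0, config$timestep, config$friction,
                            config$temperature, pre_steps,
                            config$save_stride, 0L, list())
    params <- estimate_boost_params(pre$V, sigma0 = sigma0)
    x0 <- matrix(pre$coords[nrow(pre$coords), ], ncol = 3, byrow = TRUE)
  }
  res <- cpp_run_dynamics(pack, x0, config$timestep, config$friction,
                          config$temperature, config$n_steps,
                          config$save_stride, 1L,
                          list(E = params$E_threshold, k = params$k))
  traj <- trajectory_ensemble(unflatten_coords(res$coords, nrow(system$pos)),
                              res$V, res$Vboost, timestep = config$timestep,
                              temperature = config$temperature,
                              seed = config$seed, provenance = "GaMD")
  attr(traj, "boost_params") <- params
  traj
}

# shared binning for the reweighting estimators
bin_landscape <- function(rc_values, v_boost, bin_edges) {
  if (is.list(bin_edges)) {
    rc_values <- as.matrix(rc_values)
    stopifnot(ncol(rc_values) == length(bin_edges))
  } else {
    rc_values <- matrix(rc_values, ncol = 1)
    bin_edges <- list(bin_edges)
  }
  stopifnot(nrow(rc_values) == length(v_boost))
  nd <- length(bin_edges)
  nb <- vapply(bin_edges, function(e) length(e) - 1L, integer(1))
  idx <- matrix(0L, nrow(rc_values), nd)
  for (d in seq_len(nd)) {
    idx[, d] <- findInterval(rc_values[, d], bin_edges[[d]],
                             rightmost.closed = TRUE)
    idx[idx[, d] < 1L | idx[, d] > nb[d], d] <- NA_integer_
  }
  ok <- !apply(is.na(idx), 1, any)
  lin <- if (nd == 1) idx[ok, 1] else (idx[ok, 1] - 1L) * nb[2] + idx[ok, 2]
  list(lin = lin, vb = v_boost[ok], nb = nb, nd = nd, edges = bin_edges)
}

finish_landscape <- function(bl, log_w, temperature, estimator, flags = NULL) {
  M <- prod(bl$nb)
  counts <- tabulate(bl$lin, nbins = M)
  p_prime <- counts / sum(counts)
  occ <- counts > 0
  lw <- rep(NA_real_, M)
  lw[occ] <- log_w[occ]
  # normalise over occupied bins only
  lp <- rep(NA_real_, M)
  lp[occ] <- log(p_prime[occ]) + lw[occ]
  lp[occ] <- lp[occ] - max(lp[occ])
  p <- rep(NA_real_, M)
  p[occ] <- exp(lp[occ]) / sum(exp(lp[occ]))
  shape_it <- function(v) if (bl$nd == 1) v else matrix(v, bl$nb[1], bl$nb[2], byrow = TRUE)
  ls <- structure(list(
    edges = bl$edges, counts = shape_it(counts),
    p_prime = shape_it(p_prime), p = shape_it(p), F = NULL,
    M = M, temperature = temperature, estimator = estimator,
    low_confidence = if (is.null(flags)) NULL else shape_it(flags)),
    class = "free_energy_landscape")
  landscape_free_energy(ls)
}

#' Reweight a boosted run onto the canonical ensemble (exponential average)
#'
#' The biased bin probability `p'` is multiplied by the per-bin average of
#' `exp(V_boost / kB T)` and renormalised over the occupied bins. Empty bins
#' carry no probability and are excluded from the normalisation sum.
#'
#' @param rc_values reaction-coordinate values per frame: a vector (1-D) or
#'   an n x 2 matrix (2-D landscape)
#' @param v_boost per-frame boost potentials (kcal/mol)
#' @param bin_edges numeric vector of bin edges, or a list of two such
#'   vectors for a 2-D landscape
#' @param temperature K
#' @return a `free_energy_landscape` with `p_prime`, `p` and `F` filled
#' @export
reweight_exponential <- function(rc_values, v_boost, bin_edges, temperature) {
  bl <- bin_landscape(rc_values, v_boost, bin_edges)
  beta <- 1 / (kB_KCAL * temperature)
  M <- prod(bl$nb)
  log_w <- rep(NA_real_, M)
  for (j in unique(bl$lin)) {
    z <- beta * bl$vb[bl$lin == j]
    mz <- max(z)
    log_w[j] <- mz + log(mean(exp(z - mz)))
  }
  finish_landscape(bl, log_w, temperature, "exponential")
}

#' Reweight via the second-order cumulant expansion
#'
#' Replaces the per-bin exponential average by
#' `exp(beta * mean(dV) + beta^2 * var(dV) / 2)`, the Gaussian-limit
#' identity, which is far less noise-sensitive than the raw exponential
#' estimator. Bins holding a single sample get a zero variance term and are
#' flagged low-confidence.
#'
#' @inheritParams reweight_exponential
#' @export
reweight_cumulant2 <- function(rc_values, v_boost, bin_edges, temperature) {
  bl <- bin_landscape(rc_values, v_boost, bin_edges)
  beta <- 1 / (kB_KCAL * temperature)
  M <- prod(bl$nb)
  log_w <- rep(NA_real_, M)
  flags <- rep(FALSE, M)
  for (j in unique(bl$lin)) {
    z <- bl$vb[bl$lin == j]
    if (length(z) < 2) {
      log_w[j] <- beta * mean(z)
      flags[j] <- TRUE
    } else {
      log_w[j] <- beta * mean(z) + beta^2 * stats::var(z) / 2
    }
  }
  finish_landscape(bl, log_w, temperature, "cumulant2", flags)
}

#' Fill the free-energy surface of a landscape
#'
#' `F = -kB T log p`, shifted so that the occupied-bin minimum is zero.
#' Bins with no samples keep `NA`.
#'
#' @param landscape a `free_energy_landscape` with `p` filled
#' @export
landscape_free_energy <- function(landscape) {
  p <- landscape$p
  f <- -kB_KCAL * landscape$temperature * log(p)
  f <- f - min(f, na.rm = TRUE)
  landscape$F <- f
  landscape
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("free_energy_landscape (%s): %s bins, T = %g K, %d occupied\n",
              x$estimator, paste(dim(as.matrix(x$p_prime)), collapse = " x "),
              x$temperature, sum(!is.na(x$p))))
  invisible(x)
}

#' Bin mid-points of a landscape dimension
#' @param landscape a `free_energy_landscape`
#' @param dim dimension index
#' @export
landscape_mids <- function(landscape, dim = 1) {
  e <- landscape$edges[[dim]]
  (e[-1] + e[-length(e)]) / 2
}
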