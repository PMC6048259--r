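#' Collective variables over bead groups
#'
#' A collective variable is defined by up to four anchor groups of beads
#' (T, U, W, X). The distance variable is the separation between
#' V = CoM(T u U) and Y = CoM(W u X); the angle variable is the angle at the
#' centre of U formed by the centres of T, U and Y; the torsion variable is
#' the dihedral over the four group centres (degrees, cis = 0, range
#' (-180, 180]).
#'
#' @param kind `"distance"`, `"angle"` or `"torsion"`
#' @param T,U,W,X bead index vectors (1-based); must be non-empty and
#'   pairwise disjoint
#' @export
collective_variable <- function(kind = c("distance", "angle", "torsion"),
                                T, U, W, X) {
  kind <- match.arg(kind)
  groups <- list(T = T, U = U, W = W, X = X)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("anchor groups must be non-empty")
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx)) stop("anchor groups must be disjoint")
  structure(c(list(kind = kind), groups), class = "collective_variable")
}

group_com <- function(coords, idx, masses) {
  m <- masses[idx]
  colSums(coords[idx, , drop = FALSE] * m) / sum(m)
}

#' Evaluate a collective variable on a configuration
#'
#' @param coords n x 3 coordinate matrix
#' @param cv a [collective_variable()]
#' @param masses bead masses (for group centres of mass)
#' @return distance in Angstrom, or angle/torsion in degrees
#' @export
eval_cv <- function(coords, cv, masses) {
  if (cv$kind == "distance") {
    v <- group_com(coords, c(cv$T, cv$U), masses)
    y <- group_com(coords, c(cv$W, cv$X), masses)
    d <- sqrt(sum((v - y)^2))
    if (d < 1e-9) stop("undefined CV: coincident group centres")
    return(d)
  }
  if (cv$kind == "angle") {
    a <- group_com(coords, cv$T, masses)
    b <- group_com(coords, cv$U, masses)
    y <- group_com(coords, c(cv$W, cv$X), masses)
    u <- a - b; v <- y - b
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    if (lu < 1e-9 || lv < 1e-9) stop("undefined CV: coincident group centres")
    cth <- max(-1, min(1, sum(u * v) / (lu * lv)))
    return(acos(cth) * 180 / pi)
  }
  p1 <- group_com(coords, cv$T, masses); p2 <- group_com(coords, cv$U, masses)
  p3 <- group_com(coords, cv$W, masses); p4 <- group_com(coords, cv$X, masses)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  lb2 <- sqrt(sum(b2^2))
  if (lb2 < 1e-9) stop("undefined CV: degenerate torsion geometry")
  b2h <- b2 / lb2
  # project bond vectors onto the plane perpendicular to the central bond
  u <- b1 - sum(b1 * b2h) * b2h
  w <- b3 - sum(b3 * b2h) * b2h
  if (sum(u^2) < 1e-12 || sum(w^2) < 1e-12)
    stop("undefined CV: degenerate torsion geometry")
  x <- -sum(u * w)
  y <- sum(crossprod_vec(b2h, u) * w)
  atan2(y, x) * 180 / pi
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Evaluate a collective variable over every frame of an ensemble
#' @param traj a `trajectory_ensemble`
#' @param cv a [collective_variable()]
#' @param system the `toy_system` the frames belong to
#' @export
eval_cv_frames <- function(traj, cv, system) {
  vapply(seq_len(n_frames(traj)),
         function(f) eval_cv(frame_coords(traj, f), cv, system$mass),
         numeric(1))
}

#' Adaptive-bias grid state
#'
#' Holds the accumulated flooding bias on a regular grid over one or two
#' collective variables. The deposition kernel is a biweight (quartic) bump
#' of half-width `halfwidth_cells` grid cells and weight `dt / tau` per
#' deposit.
#'
#' @param lo,hi grid range per CV (vectors of length 1 or 2)
#' @param ncells cells per CV
#' @param tau flooding timescale (ps)
#' @param halfwidth_cells kernel half-width in cells
#' @export
bias_state <- function(lo, hi, ncells, tau = 5, halfwidth_cells = 4) {
  nd <- length(lo)
  stopifnot(nd %in% c(1L, 2L), length(hi) == nd, length(ncells) == nd,
            all(hi > lo), all(ncells >= 4), tau > 0)
  h <- (hi - lo) / ncells
  bias <- if (nd == 1) numeric(ncells) else matrix(0, ncells[1], ncells[2])
  structure(list(lo = lo, hi = hi, ncells = as.integer(ncells), h = h,
                 tau = tau, halfwidth = halfwidth_cells * h, bias = bias,
                 n_deposits = 0L, converged = NA, snapshots = list()),
            class = "bias_state")
}

#' Node (cell-centre) positions of a bias grid dimension
#' @param state a [bias_state()]
#' @param dim dimension index
#' @export
bias_nodes <- function(state, dim = 1) {
  state$lo[dim] + (seq_len(state$ncells[dim]) - 0.5) * state$h[dim]
}

#' Deposit one bias kernel
#'
#' @param state a [bias_state()]
#' @param cv_value CV value(s) at which to deposit; must lie inside the grid
#' @param dt time credited to this deposit (ps); the kernel weight is
#'   `dt / tau`
#' @return the updated state
#' @export
deposit_bias <- function(state, cv_value, dt) {
  nd <- length(state$lo)
  stopifnot(length(cv_value) == nd)
  if (any(cv_value < state$lo | cv_value > state$hi))
    stop("cv value outside the bias grid")
  w <- dt / state$tau
  # kernel mass clipped by a grid edge is mirrored back inside, so edge
  # nodes accumulate at the same rate as interior nodes
  kern <- function(d) {
    centres <- cv_value[d]
    if (cv_value[d] - state$lo[d] < state$halfwidth[d])
      centres <- c(centres, 2 * state$lo[d] - cv_value[d])
    if (state$hi[d] - cv_value[d] < state$halfwidth[d])
      centres <- c(centres, 2 * state$hi[d] - cv_value[d])
    nodes <- bias_nodes(state, d)
    out <- 0
    for (cc in centres) {
      u <- (nodes - cc) / state$halfwidth[d]
      out <- out + ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    }
    out
  }
  if (nd == 1) {
    state$bias <- state$bias + w * kern(1)
  } else {
    state$bias <- state$bias + w * outer(kern(1), kern(2))
  }
  state$n_deposits <- state$n_deposits + 1L
  state
}

#' Run adaptive-bias Langevin dynamics along one or two collective variables
#'
#' The engine evaluates the CVs each step, applies the bias force by the
#' chain rule through the group centres, confines the CVs to the grid with
#' harmonic walls, and deposits a biweight kernel of weight
#' `timestep * dep_stride / tau` every `dep_stride` steps. Convergence is
#' declared when the aligned free-energy estimates of the final two 10%-run
#' snapshots differ by less than `conv_tol` on nodes touched by both.
#'
#' @param system a `toy_system`
#' @param cvs a list of one or two [collective_variable()]s
#' @param config an [integrator_config()]
#' @param lo,hi,ncells grid definition per CV
#' @param tau flooding timescale (ps)
#' @param halfwidth_cells kernel half-width in grid cells
#' @param wall_k harmonic wall constant confining the CVs to the grid
#'   (kcal/mol per squared CV unit); 0 disables
#' @param dep_stride deposit every this many steps
#' @param conv_tol convergence tolerance (kcal/mol)
#' @return list with `bias` (a [bias_state()] with `converged` flag and
#'   snapshot history) and `traj` (a `trajectory_ensemble`, provenance
#'   `"ABMD"`, with per-frame CV values as attribute `cv_values`)
#' @export
run_abmd <- function(system, cvs, config, lo, hi, ncells, tau = 5,
                     halfwidth_cells = 4, wall_k = 10, dep_stride = 1L,
                     conv_tol = 0.2) {
  if (inherits(cvs, "collective_variable")) cvs <- list(cvs)
  stopifnot(length(cvs) %in% c(1L, 2L))
  state <- bias_state(lo, hi, ncells, tau, halfwidth_cells)
  kindcode <- c(distance = 0L, angle = 1L, torsion = 2L)
  cvl <- lapply(cvs, function(cv) list(
    kind = kindcode[[cv$kind]],
    T = as.integer(cv$T - 1L), U = as.integer(cv$U - 1L),
    W = as.integer(cv$W - 1L), X = as.integer(cv$X - 1L)))
  pack <- engine_pack(system)
  set.seed(config$seed)
  res <- cpp_run_dynamics(pack, system$pos, config$timestep, config$friction,
                          config$temperature, config$n_steps,
                          config$save_stride, 2L,
                          list(cvs = cvl, lo = lo, hi = hi,
                               ncells = as.integer(ncells),
                               halfwidth = state$halfwidth,
                               tau = tau * 1000,  # ps -> fs
                               wall_k = wall_k,
                               dep_stride = as.integer(dep_stride)))
  shape_it <- function(v) {
    if (length(state$lo) == 1) as.numeric(v)
    else matrix(v, state$ncells[1], state$ncells[2], byrow = TRUE)
  }
  state$bias <- shape_it(res$bias)
  state$n_deposits <- config$n_steps %/% dep_stride
  state$snapshots <- lapply(res$snapshots, shape_it)
  ns <- length(state$snapshots)
  if (ns >= 2) {
    a <- -state$snapshots[[ns - 1]]; b <- -state$snapshots[[ns]]
    occ <- state$snapshots[[ns - 1]] > 0 & state$snapshots[[ns]] > 0
    if (any(occ)) {
      d <- (b - a) - mean((b - a)[occ])
      state$converged <- max(abs(d[occ])) < conv_tol
    } else state$converged <- FALSE
  } else state$converged <- FALSE
  traj <- trajectory_ensemble(unflatten_coords(res$coords, nrow(system$pos)),
                              res$V, NULL, timestep = config$timestep,
                              temperature = config$temperature,
                              seed = config$seed, provenance = "ABMD")
  attr(traj, "cv_values") <- res$cv
  list(bias = state, traj = traj)
}

#' Potential of mean force from a converged flooding bias
#'
#' At convergence the accumulated bias mirrors the negative free energy, so
#' `F = -bias`, shifted to a zero minimum over the visited region. Once the
#' bias is full it fluctuates around the negated free energy at the scale of
#' single deposits, so by default the estimate uses the bias averaged over
#' the final tenth of the run (recorded during sampling) rather than the
#' final instantaneous surface; `estimate = "final"` selects the latter.
#'
#' @param state a [bias_state()]
#' @param temperature K (stored on the landscape for downstream Boltzmann
#'   integrals)
#' @param estimate `"window_mean"` (bias averaged over the last 10% of the
#'   run, when available) or `"final"` (instantaneous final bias)
#' @return a `free_energy_landscape` with `F` (and the implied Boltzmann
#'   `p`) filled; nodes the dynamics never touched carry `NA`
#' @export
pmf_from_bias <- function(state, temperature = 310,
                          estimate = c("window_mean", "final")) {
  estimate <- match.arg(estimate)
  b <- state$bias
  if (estimate == "window_mean" && length(state$snapshots) > 0)
    b <- state$snapshots[[length(state$snapshots)]]
  f <- -b
  visited <- state$bias > 0 | state$n_deposits == 0L
  f[!visited] <- NA
  f <- f - min(f, na.rm = TRUE)
  edges <- lapply(seq_along(state$lo), function(d)
    seq(state$lo[d], state$hi[d], length.out = state$ncells[d] + 1L))
  p <- exp(-f / (kB_KCAL * temperature))
  p <- p / sum(p, na.rm = TRUE)
  structure(list(edges = edges, counts = NULL, p_prime = NULL, p = p, F = f,
                 M = prod(state$ncells), temperature = temperature,
                 estimator = "abmd", low_confidence = NULL,
                 converged = state$converged),
            class = "free_energy_landscape")
}

#' Binding free energy from a 1-D potential of mean force
#'
#' `dG = -kB T log( I_bound / I_unbound )` with
#' `I = sum exp(-F/kB T) h` over the bins whose mid-points fall in the
#' window. No standard-state volume correction is applied (an explicit
#' choice, exposed through the window widths).
#'
#' @param pmf a 1-D `free_energy_landscape`
#' @param bound_window,unbound_window `c(lo, hi)` intervals on the CV;
#'   must be disjoint
#' @param temperature K; defaults to the landscape's
#' @return binding free energy (kcal/mol)
#' @export
binding_dg <- function(pmf, bound_window, unbound_window,
                       temperature = pmf$temperature) {
  stopifnot(length(pmf$edges) == 1)
  if (max(bound_window[1], unbound_window[1]) <
      min(bound_window[2], unbound_window[2]))
    stop("bound and unbound windows must be disjoint")
  mids <- landscape_mids(pmf, 1)
  h <- diff(pmf$edges[[1]])[1]
  beta <- 1 / (kB_KCAL * temperature)
  win_int <- function(w) {
    inw <- mids >= w[1] & mids <= w[2] & !is.na(pmf$F)
    if (!any(inw)) stop("empty window: no sampled bins in [",
                        w[1], ", ", w[2], "]")
    sum(exp(-beta * pmf$F[inw]) * h)
  }
  -log(win_int(bound_window) / win_int(unbound_window)) / beta
}

#' Block-averaged binding free energy over flooding windows
#'
#' Once the bias has filled the landscape it fluctuates around the negated
#' free energy at the single-deposit scale, so a single end-of-run estimate
#' carries that noise. This estimator evaluates [binding_dg()] on the
#' window-averaged bias of every recorded 10%-run window after an initial
#' fill fraction and returns their mean and spread.
#'
#' @param state a [bias_state()] with snapshot history (from [run_abmd()])
#' @param bound_window,unbound_window CV intervals as in [binding_dg()]
#' @param temperature K
#' @param discard fraction of leading windows treated as fill-in and skipped
#' @return list with `dg` (mean over windows), `se` (sd across windows) and
#'   the per-window estimates `windows`
#' @export
binding_dg_windows <- function(state, bound_window, unbound_window,
                               temperature = 310, discard = 0.3) {
  ns <- length(state$snapshots)
  if (ns < 2) stop("bias state carries no snapshot history")
  use <- seq.int(max(2L, floor(ns * discard) + 1L), ns)
  dgs <- vapply(use, function(i) {
    st <- state
    st$bias <- state$snapshots[[i]]
    st$snapshots <- list()
    binding_dg(pmf_from_bias(st, temperature), bound_window, unbound_window,
               temperature)
  }, numeric(1))
  list(dg = mean(dgs), se = stats::sd(dgs), windows = dgs)
}

#' Restraint setup for binding potential-of-mean-force runs
#'
#' Prepares a dimer for adaptive-bias unbinding along the chain-chain
#' distance: the receptor backbone is held near its reference position
#' (defining the laboratory frame) and the ligand backbone is confined
#' laterally -- in the two axes orthogonal to the interface axis -- while
#' the binding axis stays free, a funnel-style setup that keeps the
#' unbinding pathway one-dimensional and avoids rebinding hysteresis in
#' misaligned poses.
#'
#' @param system a `toy_system` from [build_toy_dimer()]
#' @param k_receptor isotropic restraint on receptor backbone beads
#'   (kcal/mol/A^2)
#' @param k_lateral lateral (x, z) confinement on ligand backbone beads
#' @param k_axial optional soft tether along the binding axis (y); zero for
#'   unbinding runs, small and non-zero to keep equilibrium landscape runs
#'   from drifting irreversibly into the unbound vacuum
#' @return the restrained system
#' @export
pmf_restraints <- function(system, k_receptor = 2, k_lateral = 1,
                           k_axial = 0) {
  if (is.null(system$interface)) stop("system has no interface annotation")
  recB <- system$interface$rec_B
  system$restraints <- rbind(system$restraints,
    data.frame(bead = recB, k = k_receptor,
               x = system$pos[recB, 1], y = system$pos[recB, 2],
               z = system$pos[recB, 3]))
  ligB <- system$interface$lig_B
  system$external <- c(system$external, lapply(ligB, function(b)
    list(type = "harmonic", bead = b, k = c(k_lateral, k_axial, k_lateral),
         center = system$pos[b, ])))
  system
}

#' Mutant-minus-wild-type binding free energy difference
#'
#' @param dg_mut,dg_wt binding free energies (kcal/mol)
#' @param se_mut,se_wt their uncertainties; propagated in quadrature
#' @return list with `ddg` and `se`
#' @export
delta_delta_g <- function(dg_mut, dg_wt, se_mut = 0, se_wt = 0) {
  list(ddg = dg_mut - dg_wt, se = sqrt(se_mut^2 + se_wt^2))
}

#' Fold-change in dissociation constant implied by a binding penalty
#'
#' `Kd_mut / Kd_wt = exp(ddG / kB T)`.
#'
#' @param ddg kcal/mol
#' @param temperature K
#' @export
kd_ratio <- function(ddg, temperature = 310) {
  stopifnot(temperature > 0)
  exp(ddg / (kB_KCAL * temperature))
}

#' One-sided significance of a positive binding penalty
#'
#' Tests whether replicate ddG values are larger than zero, by a one-sample
#' one-sided t-test (default) or a sign-flip permutation test.
#'
#' @param replicate_ddgs ddG values from independent replicates/blocks
#' @param method `"t"` or `"permutation"`
#' @param n_perm permutation count
#' @return one-sided p-value
#' @export
significance_ddg <- function(replicate_ddgs, method = c("t", "permutation"),
                             n_perm = 10000) {
  method <- match.arg(method)
  x <- replicate_ddgs
  if (method == "t") {
    if (stats::sd(x) == 0) return(if (mean(x) > 0) 0 else 1)
    return(stats::t.test(x, mu = 0, alternative = "greater")$p.value)
  }
  obs <- mean(x)
  signs <- matrix(sample(c(-1, 1), n_perm * length(x), replace = TRUE),
                  n_perm, length(x))
  perm <- rowMeans(signs * rep(abs(x), each = n_perm))
  (sum(perm >= obs) + 1) / (n_perm + 1)
}

#' Bundle replicate binding estimates into a comparative result
#'
#' @param dg_wt,dg_mut vectors of per-replicate binding free energies
#' @param temperature K
#' @param method label, e.g. `"ABMD"` or `"MMPBSA"`
#' @return list of class `binding_result` with per-variant means and
#'   replicate-spread uncertainties, the propagated ddG and the Kd ratio
#' @export
binding_result <- function(dg_wt, dg_mut, temperature = 310,
                           method = "ABMD") {
  se <- function(x) if (length(x) > 1) stats::sd(x) else 0
  dd <- delta_delta_g(mean(dg_mut), mean(dg_wt), se(dg_mut), se(dg_wt))
  structure(list(dG_WT = mean(dg_wt), dG_WT_se = se(dg_wt),
                 dG_MUT = mean(dg_mut), dG_MUT_se = se(dg_mut),
                 ddG = dd$ddg, ddG_se = dd$se,
                 kd_ratio = kd_ratio(dd$ddg, temperature),
                 temperature = temperature, method = method,
                 replicates_wt = dg_wt, replicates_mut = dg_mut),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("binding_result [%s] at %g K\n", x$method, x$temperature))
  cat(sprintf("  dG_WT  = %8.2f +/- %.2f kcal/mol\n", x$dG_WT, x$dG_WT_se))
  cat(sprintf("  dG_MUT = %8.2f +/- %.2f kcal/mol\n", x$dG_MUT, x$dG_MUT_se))
  cat(sprintf("  ddG    = %8.2f +/- %.2f kcal/mol, Kd ratio = %.2f\n",
              x$ddG, x$ddG_se, x$kd_ratio))
  invisible(x)
}
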