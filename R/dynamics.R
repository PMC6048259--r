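#' Integrator configuration
#'
#' Canonical-ensemble Langevin (BAOAB) sampling parameters. The defaults
#' adopt a 2 ps^-1 collision frequency and a 310 K target temperature.
#'
#' @param timestep fs
#' @param friction collision frequency, 1/ps
#' @param temperature K
#' @param n_steps number of integration steps
#' @param save_stride save every `save_stride`-th step (the initial frame is
#'   always saved, so a run yields `n_steps / save_stride + 1` frames)
#' @param seed RNG seed
#' @export
integrator_config <- function(n_steps, timestep = 2, friction = 2,
                              temperature = 310, save_stride = 10L,
                              seed = 1L) {
  stopifnot(timestep > 0, temperature >= 0, save_stride >= 1, n_steps >= 0)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = "integrator_config")
}

# Flatten a toy_system into the plain-array form the compiled engine takes.
engine_pack <- function(system) {
  n <- nrow(system$pos)
  up <- which(upper.tri(system$eps) & !system$excl, arr.ind = TRUE)
  qq <- COULOMB_KCAL * system$charge[up[, 1]] * system$charge[up[, 2]] /
    system$dielectric
  keep <- system$eps[up] != 0 | qq != 0
  up <- up[keep, , drop = FALSE]; qq <- qq[keep]
  ext <- matrix(0, 0, 8)
  for (e in system$external) {
    row <- numeric(8)
    if (e$type == "harmonic") {
      row[1] <- 1; row[2] <- e$bead - 1L
      row[3:5] <- rep(e$k, length.out = 3); row[6:8] <- rep(e$center, length.out = 3)
    } else if (e$type == "double_well") {
      row[1] <- 2; row[2] <- e$bead - 1L
      row[3] <- e$axis - 1L; row[4] <- e$h; row[5] <- e$a
    } else stop("unknown external potential type: ", e$type)
    ext <- rbind(ext, row)
  }
  list(n = n, mass = system$mass,
       bond_i = system$bonds$i - 1L, bond_j = system$bonds$j - 1L,
       bond_k = system$bonds$k, bond_r0 = system$bonds$r0,
       pair_i = as.integer(up[, 1] - 1L), pair_j = as.integer(up[, 2] - 1L),
       pair_eps = system$eps[up], pair_sig = system$sigma[up], pair_qq = qq,
       screen = system$screen_length,
       restr_bead = system$restraints$bead - 1L,
       restr_k = system$restraints$k,
       restr_x = system$restraints$x, restr_y = system$restraints$y,
       restr_z = system$restraints$z,
       ext = ext, frozen = system$frozen)
}

#' Potential energy of a configuration
#'
#' Pure-R evaluation of the toy force field: harmonic bonds
#' (`0.5 k (r - r0)^2`), a Lennard-Jones-style pair term
#' (`4 eps [(sigma/r)^12 - (sigma/r)^6]`), screened Coulomb
#' electrostatics (`332.0637 q_i q_j exp(-r/lambda) / (eps_r r)`),
#' positional restraints, and any external potentials. The compiled engine
#' implements the same terms; the two routes are cross-checked in the test
#' suite.
#'
#' @param system a `toy_system`
#' @param coords optional n x 3 matrix (defaults to reference coordinates)
#' @return list with `total` (kcal/mol) and the per-term `terms` breakdown
#' @export
potential_energy <- function(system, coords = NULL) {
  if (is.null(coords)) coords <- system$pos
  if (!all(is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  b <- system$bonds
  dvec <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  e_bond <- sum(0.5 * b$k * (r - b$r0)^2)

  up <- which(upper.tri(system$eps) & !system$excl, arr.ind = TRUE)
  e_vdw <- 0; e_coul <- 0
  if (nrow(up)) {
    dv <- coords[up[, 1], , drop = FALSE] - coords[up[, 2], , drop = FALSE]
    r2 <- rowSums(dv^2)
    if (any(r2 < 1e-12)) stop("singularity: beads overlap at zero distance")
    r <- sqrt(r2)
    eps <- system$eps[up]; sig <- system$sigma[up]
    sr6 <- (sig / r)^6
    e_vdw <- sum(4 * eps * (sr6^2 - sr6))
    qq <- COULOMB_KCAL * system$charge[up[, 1]] * system$charge[up[, 2]] /
      system$dielectric
    e_coul <- sum(qq * exp(-r / system$screen_length) / r)
  }
  e_restr <- 0
  if (nrow(system$restraints)) {
    rs <- system$restraints
    dv <- coords[rs$bead, , drop = FALSE] - cbind(rs$x, rs$y, rs$z)
    e_restr <- sum(0.5 * rs$k * rowSums(dv^2))
  }
  e_ext <- 0
  for (e in system$external) {
    if (e$type == "harmonic") {
      d <- coords[e$bead, ] - rep(e$center, length.out = 3)
      e_ext <- e_ext + sum(0.5 * rep(e$k, length.out = 3) * d^2)
    } else if (e$type == "double_well") {
      u <- coords[e$bead, e$axis] / e$a
      e_ext <- e_ext + e$h * (u^2 - 1)^2
    }
  }
  terms <- c(bond = e_bond, vdw = e_vdw, coulomb = e_coul,
             restraint = e_restr, external = e_ext)
  list(total = sum(terms), terms = terms)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param system a `toy_system`
#' @param temperature K
#' @return n x 3 velocity matrix (Angstrom/fs)
#' @export
init_velocities <- function(system, temperature) {
  n <- nrow(system$pos)
  sd <- sqrt(kB_KCAL * temperature * ACC_CONV / system$mass)
  v <- matrix(stats::rnorm(3 * n), n, 3, byrow = TRUE) * sd
  v[system$frozen, ] <- 0
  v
}

#' One BAOAB Langevin step (reference implementation)
#'
#' Splitting: half kick, half drift, full Ornstein-Uhlenbeck velocity
#' update, half drift, force refresh, half kick. This R implementation
#' mirrors the compiled engine step-for-step (including the order in which
#' Gaussian variates are consumed) and is used as its cross-check.
#'
#' @param state list with `pos` (n x 3), `vel` (n x 3) and optionally
#'   `forces`; as returned by a previous call
#' @param system a `toy_system`
#' @param config an [integrator_config()]
#' @return updated state list with `pos`, `vel`, `forces`, `potential`
#' @export
langevin_step <- function(state, system, config) {
  pack <- engine_pack(system)
  n <- nrow(state$pos)
  dt <- config$timestep
  mobile <- !system$frozen
  if (is.null(state$forces)) {
    ef <- cpp_energy(pack, state$pos)
    state$forces <- ef$forces
  }
  a <- 0.5 * dt * ACC_CONV / system$mass
  v <- state$vel; x <- state$pos
  v[mobile, ] <- v[mobile, ] + a[mobile] * state$forces[mobile, , drop = FALSE]
  x[mobile, ] <- x[mobile, ] + 0.5 * dt * v[mobile, , drop = FALSE]
  gamma <- config$friction * 1e-3
  c1 <- exp(-gamma * dt)
  c2 <- sqrt((1 - c1^2) * kB_KCAL * config$temperature * ACC_CONV / system$mass)
  noise <- matrix(stats::rnorm(3 * n), n, 3, byrow = TRUE)
  v[mobile, ] <- c1 * v[mobile, , drop = FALSE] + c2[mobile] * noise[mobile, , drop = FALSE]
  x[mobile, ] <- x[mobile, ] + 0.5 * dt * v[mobile, , drop = FALSE]
  ef <- cpp_energy(pack, x)
  if (!all(is.finite(ef$forces))) stop("NaN force encountered; aborting")
  v[mobile, ] <- v[mobile, ] + a[mobile] * ef$forces[mobile, , drop = FALSE]
  list(pos = x, vel = v, forces = ef$forces, potential = ef$energy)
}

# reshape the engine's frame-major coordinate matrix into frames x beads x 3
unflatten_coords <- function(mat, n_beads) {
  nf <- nrow(mat)
  aperm(array(t(mat), dim = c(3, n_beads, nf)), c(3, 2, 1))
}

#' Run unbiased Langevin dynamics
#'
#' @param system a `toy_system`
#' @param config an [integrator_config()]
#' @return a `trajectory_ensemble` with provenance `"cMD"`, per-frame
#'   potential energies filled and zero boost
#' @export
run_cmd <- function(system, config) {
  pack <- engine_pack(system)
  set.seed(config$seed)
  res <- cpp_run_dynamics(pack, system$pos, config$timestep, config$friction,
                          config$temperature, config$n_steps,
                          config$save_stride, 0L, list())
  trajectory_ensemble(unflatten_coords(res$coords, nrow(system$pos)),
                      res$V, NULL, timestep = config$timestep,
                      temperature = config$temperature, seed = config$seed,
                      provenance = "cMD")
}

#' Drop an initial equilibration window from an ensemble
#'
#' @param traj a `trajectory_ensemble`
#' @param fraction fraction of leading frames to discard (default 10%)
#' @export
discard_equilibration <- function(traj, fraction = 0.1) {
  nf <- n_frames(traj)
  drop <- floor(nf * fraction)
  if (drop == 0) return(traj)
  keep <- (drop + 1):nf
  trajectory_ensemble(traj$coords[keep, , , drop = FALSE],
                      traj$potential[keep], traj$boost[keep],
                      traj$timestep, traj$temperature, traj$seed,
                      traj$provenance)
}

#' Minimal free-bead systems for analytic benchmarks
#'
#' Builds a `toy_system` consisting of unbonded beads with no pair
#' interactions, suitable for attaching external potentials (harmonic wells,
#' double wells) and running the same engine that samples the toy dimers.
#'
#' @param pos n x 3 reference coordinates
#' @param mass bead masses (amu)
#' @param external list of external potential terms, e.g.
#'   `list(type = "double_well", bead = 1, axis = 1, h = 3, a = 1.5)` or
#'   `list(type = "harmonic", bead = 1, k = c(0, 50, 50), center = c(0, 0, 0))`
#' @param frozen logical vector; frozen beads do not move
#' @export
bead_system <- function(pos, mass = rep(40, nrow(pos)), external = list(),
                        frozen = rep(FALSE, nrow(pos))) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  structure(list(
    pos = pos, mass = mass, charge = numeric(n), radius = rep(1, n),
    bead_name = rep("CA", n), residue_id = seq_len(n),
    residue_chain = rep("A", n), residue_number = seq_len(n),
    residue_name = rep("RES", n),
    bonds = data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric()),
    eps = matrix(0, n, n), sigma = matrix(2, n, n),
    excl = matrix(TRUE, n, n),
    dielectric = 1, screen_length = 8,
    donors = matrix(integer(), 0, 2), acceptors = integer(),
    restraints = data.frame(bead = integer(), k = numeric(),
                            x = numeric(), y = numeric(), z = numeric()),
    frozen = frozen, external = external,
    variant = "WT", seed = 0L, mutated_params = NULL,
    interface = NULL), class = "toy_system")
}
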