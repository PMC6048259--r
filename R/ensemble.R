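#' Trajectory ensembles
#'
#' A `trajectory_ensemble` bundles a stack of frames with per-frame potential
#' energies and (for boosted runs) per-frame boost potentials. Synthetic
#' ensembles are geometry-only: their energy traces are zero.
#'
#' @param coords numeric array, frames x beads x 3 (Angstrom)
#' @param potential per-frame potential energy (kcal/mol)
#' @param boost per-frame boost potential (kcal/mol, >= 0)
#' @param timestep fs (NA for synthetic ensembles)
#' @param temperature K
#' @param seed integer RNG seed the frames were generated under
#' @param provenance one of `"cMD"`, `"GaMD"`, `"ABMD"`, `"synthetic"`
#' @return object of class `trajectory_ensemble`
#' @export
trajectory_ensemble <- function(coords, potential = NULL, boost = NULL,
                                timestep = NA_real_, temperature = NA_real_,
                                seed = NA_integer_,
                                provenance = c("cMD", "GaMD", "ABMD", "synthetic")) {
  provenance <- match.arg(provenance)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x beads x 3 array")
  nf <- dim(coords)[1]
  if (nf < 1L) stop("ensemble must contain at least one frame")
  if (is.null(potential)) potential <- numeric(nf)
  if (is.null(boost)) boost <- numeric(nf)
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (any(boost < 0)) stop("frame boost must be >= 0 everywhere")
  stopifnot(length(potential) == nf, length(boost) == nf)
  structure(list(coords = coords, potential = potential, boost = boost,
                 timestep = timestep, temperature = temperature,
                 seed = seed, provenance = provenance),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble [%s]: %d frames x %d beads\n",
              x$provenance, dim(x$coords)[1], dim(x$coords)[2]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param traj a `trajectory_ensemble`
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame coordinates as a beads x 3 matrix
#' @param traj a `trajectory_ensemble`
#' @param i frame index
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Specification of a synthetic interface ensemble
#'
#' Prescribes per-residue-pair contact probabilities and per-site
#' hydrogen-bond probabilities that [make_interface_ensemble()] realises
#' empirically. Contact prescriptions address (receptor residue, ligand
#' residue) pairs by per-chain numbering; hydrogen-bond prescriptions address
#' (donor residue on the receptor, acceptor residue on the ligand). Any
#' ligand residue may appear in at most one prescription so prescriptions can
#' be realised independently.
#'
#' @param n_frames number of frames (>= 1)
#' @param contact_probs data frame with columns `res_i` (receptor residue
#'   number), `res_j` (ligand residue number), `p` in `[0, 1]`
#' @param hbond_probs data frame with columns `donor_res` (receptor residue
#'   number), `acceptor_res` (ligand residue number), `p` in `[0, 1]`
#' @param noise isotropic Gaussian jitter applied to all beads (Angstrom)
#' @param seed RNG seed
#' @export
ensemble_spec <- function(n_frames, contact_probs = NULL, hbond_probs = NULL,
                          noise = 0.05, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  empty_c <- data.frame(res_i = integer(), res_j = integer(), p = numeric())
  empty_h <- data.frame(donor_res = integer(), acceptor_res = integer(), p = numeric())
  if (is.null(contact_probs)) contact_probs <- empty_c
  if (is.null(hbond_probs)) hbond_probs <- empty_h
  if (any(contact_probs$p < 0 | contact_probs$p > 1) ||
      any(hbond_probs$p < 0 | hbond_probs$p > 1))
    stop("prescribed probabilities must lie in [0, 1]")
  used <- c(contact_probs$res_j, hbond_probs$acceptor_res)
  if (anyDuplicated(used))
    stop("each ligand residue may appear in at most one prescription")
  structure(list(n_frames = as.integer(n_frames),
                 contact_probs = contact_probs, hbond_probs = hbond_probs,
                 noise = noise, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a synthetic ensemble with prescribed interface statistics
#'
#' Frames are built from the reference coordinates plus isotropic jitter.
#' For every contact-prescribed residue pair a Bernoulli draw decides whether
#' the ligand residue is placed with its centre of mass within the 6 Angstrom
#' contact criterion (distance drawn in `[3, 5.5]`) or outside it
#' (`[6.8, 12]`). For every hydrogen-bond-prescribed pair a draw decides
#' whether the acceptor is placed to satisfy the 3.0 Angstrom / >= 135 degree
#' criterion (collinear donor-H-acceptor at 2.6-2.95 A) or to violate it by
#' distance or by angle. Frame energies are zero: synthetic ensembles are
#' geometry-only.
#'
#' @param system a `toy_system`
#' @param spec an [ensemble_spec()]
#' @return a `trajectory_ensemble` with provenance `"synthetic"`
#' @export
make_interface_ensemble <- function(system, spec) {
  stopifnot(inherits(system, "toy_system"), inherits(spec, "ensemble_spec"))
  nf <- spec$n_frames
  n <- nrow(system$pos)
  rec_res <- which(system$residue_chain == "A")
  lig_res <- which(system$residue_chain == "B")
  res_global <- function(chain, num) {
    id <- which(system$residue_chain == chain & system$residue_number == num)
    if (length(id) != 1L) stop("no such residue: ", chain, num)
    id
  }
  donors <- system$donors
  donor_of_res <- function(resid) {
    hit <- which(system$residue_id[donors[, 1]] == resid)
    if (length(hit) < 1L) stop("residue has no donor site: ", resid)
    donors[hit[1L], ]
  }
  coords <- array(NA_real_, dim = c(nf, n, 3))
  set.seed(spec$seed)
  cp <- spec$contact_probs
  hp <- spec$hbond_probs
  for (f in seq_len(nf)) {
    x <- system$pos + matrix(stats::rnorm(3 * n, sd = spec$noise), n, 3)
    if (nrow(cp)) for (r in seq_len(nrow(cp))) {
      ri <- res_global("A", cp$res_i[r]); rj <- res_global("B", cp$res_j[r])
      bi <- residue_beads(system, ri); bj <- residue_beads(system, rj)
      com_i <- residue_com_coords(x, bi, system$mass)
      com_j <- residue_com_coords(x, bj, system$mass)
      u <- com_j - com_i
      nu <- sqrt(sum(u^2)); u <- if (nu > 1e-9) u / nu else c(0, 1, 0)
      d <- if (stats::runif(1) < cp$p[r]) stats::runif(1, 3.0, 5.5)
           else stats::runif(1, 6.8, 12)
      shift <- (com_i + d * u) - com_j
      x[bj, ] <- sweep(x[bj, , drop = FALSE], 2, shift, `+`)
    }
    if (nrow(hp)) for (r in seq_len(nrow(hp))) {
      ri <- res_global("A", hp$donor_res[r]); rj <- res_global("B", hp$acceptor_res[r])
      dh <- donor_of_res(ri)
      D <- x[dh[1], ]
      bj <- residue_beads(system, rj)
      acc <- intersect(bj, system$acceptors)
      if (length(acc) < 1L) stop("residue has no acceptor bead: ", rj)
      acc <- acc[1L]
      u <- x[acc, ] - D
      nu <- sqrt(sum(u^2)); u <- if (nu > 1e-9) u / nu else c(0, 1, 0)
      bond <- stats::runif(1) < hp$p[r]
      if (bond) {
        d <- stats::runif(1, 2.6, 2.95)
        x[dh[2], ] <- D + 1.0 * u          # H collinear: angle 180 deg
      } else if (stats::runif(1) < 0.5) {
        d <- stats::runif(1, 3.3, 6.0)     # distance violation
        x[dh[2], ] <- D + 1.0 * u
      } else {
        d <- stats::runif(1, 2.6, 2.95)    # angle violation: H off-axis
        v <- u - c(u[2], -u[1], 0); v <- v - sum(v * u) * u
        nv <- sqrt(sum(v^2))
        if (nv < 1e-6) { v <- c(0, 0, 1) - u[3] * u; nv <- sqrt(sum(v^2)) }
        x[dh[2], ] <- D + v / nv
      }
      shift <- (D + d * u) - x[acc, ]
      x[bj, ] <- sweep(x[bj, , drop = FALSE], 2, shift, `+`)
    }
    coords[f, , ] <- x
  }
  trajectory_ensemble(coords, timestep = NA_real_, temperature = NA_real_,
                      seed = spec$seed, provenance = "synthetic")
}

# mass-weighted centre of a bead subset (internal; see residue_com for the
# exported per-residue interface)
residue_com_coords <- function(coords, beads, mass) {
  m <- mass[beads]
  colSums(coords[beads, , drop = FALSE] * m) / sum(m)
}

.DTJ_MAGIC <- charToRaw("DTJ1")
.DTJ_PROV <- c(cMD = 1L, GaMD = 2L, ABMD = 3L, synthetic = 4L)

#' Read and write the binary trajectory container
#'
#' A self-describing little-endian binary format: a 4-byte magic tag, format
#' version, frame/bead counts, then double-precision coordinates and the
#' per-frame potential and boost traces. Round-trips are lossless.
#'
#' @param traj a `trajectory_ensemble`
#' @param path file path (conventional extension `.dtj`)
#' @export
write_traj <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(.DTJ_MAGIC, con)
  nf <- n_frames(traj); nb <- dim(traj$coords)[2]
  writeBin(c(1L, nf, nb, .DTJ_PROV[[traj$provenance]],
             as.integer(ifelse(is.na(traj$seed), -1L, traj$seed))),
           con, size = 4L, endian = "little")
  writeBin(as.double(c(traj$timestep, traj$temperature)), con,
           endian = "little")
  writeBin(as.double(aperm(traj$coords, c(3, 2, 1))), con, endian = "little")
  writeBin(as.double(traj$potential), con, endian = "little")
  writeBin(as.double(traj$boost), con, endian = "little")
  invisible(path)
}

#' @rdname write_traj
#' @export
read_traj <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 40) stop("not a trajectory file (truncated header): ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .DTJ_MAGIC)) stop("bad magic: not a trajectory file")
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stop("unsupported trajectory format version: ", hdr[1])
  nf <- hdr[2]; nb <- hdr[3]
  expected <- 4 + 5 * 4 + 2 * 8 + 8 * (3 * nb * nf + 2 * nf)
  if (sz != expected)
    stop(sprintf("trajectory shape mismatch: file has %d bytes, header implies %d",
                 sz, expected))
  tt <- readBin(con, "double", 2L, endian = "little")
  xs <- readBin(con, "double", 3 * nb * nf, endian = "little")
  pot <- readBin(con, "double", nf, endian = "little")
  boo <- readBin(con, "double", nf, endian = "little")
  coords <- aperm(array(xs, dim = c(3, nb, nf)), c(3, 2, 1))
  trajectory_ensemble(coords, pot, boo, timestep = tt[1], temperature = tt[2],
                      seed = if (hdr[5] < 0) NA_integer_ else hdr[5],
                      provenance = names(.DTJ_PROV)[hdr[4]])
}
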