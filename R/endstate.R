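#' End-state energetics configuration
#'
#' @param gamma surface tension for the nonpolar solvation term
#'   (kcal/mol/A^2)
#' @param probe solvent probe radius (Angstrom)
#' @param ionic ionic strength of the solvent, mol/L
#' @param eps_in,eps_out interior and exterior (solvent) dielectric constants
#' @param temperature K
#' @param sasa_points sphere quadrature points per bead (deterministic
#'   spiral point set)
#' @export
endstate_config <- function(gamma = 0.0072, probe = 1.4, ionic = 0.150,
                            eps_in = 1, eps_out = 80, temperature = 310,
                            sasa_points = 960L) {
  if (gamma < 0) stop("surface tension must be >= 0")
  if (eps_in <= 0 || eps_out <= 0) stop("dielectrics must be > 0")
  if (ionic < 0) stop("ionic strength must be >= 0")
  structure(list(gamma = gamma, probe = probe, ionic = ionic,
                 eps_in = eps_in, eps_out = eps_out,
                 temperature = temperature,
                 sasa_points = as.integer(sasa_points)),
            class = "endstate_config")
}

#' Gas-phase molecular-mechanics energy terms of a bead selection
#'
#' `E_internal` collects the bonded terms whose beads all lie in the
#' selection; `E_electrostatics` is the unscreened vacuum Coulomb energy
#' (`332.0637 q_i q_j / r`); `E_vdw` is the Lennard-Jones-style pair term.
#' Pairs excluded by the topology (1-2, 1-3) are excluded here too.
#'
#' @param system a `toy_system`
#' @param coords n x 3 coordinates
#' @param selection bead indices (defaults to all beads)
#' @return named vector with `internal`, `electrostatics`, `vdw` (kcal/mol)
#' @export
mm_terms <- function(system, coords, selection = seq_len(nrow(system$pos))) {
  stopifnot(all(selection >= 1), all(selection <= nrow(system$pos)))
  insel <- logical(nrow(system$pos)); insel[selection] <- TRUE
  b <- system$bonds
  keep <- insel[b$i] & insel[b$j]
  e_int <- 0
  if (any(keep)) {
    dv <- coords[b$i[keep], , drop = FALSE] - coords[b$j[keep], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    e_int <- sum(0.5 * b$k[keep] * (r - b$r0[keep])^2)
  }
  e_ele <- 0; e_vdw <- 0
  if (length(selection) > 1) {
    pr <- mm_pair_terms(system, coords, selection, selection)
    e_ele <- sum(pr$ele) / 2; e_vdw <- sum(pr$vdw) / 2  # both orderings listed
  }
  c(internal = e_int, electrostatics = e_ele, vdw = e_vdw)
}

# pairwise gas-phase terms between two selections (each unordered pair once
# when the selections are disjoint; both orderings when identical)
mm_pair_terms <- function(system, coords, sel_a, sel_b) {
  pairs <- expand.grid(i = sel_a, j = sel_b)
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  pairs <- pairs[!system$excl[cbind(pairs$i, pairs$j)], , drop = FALSE]
  if (!nrow(pairs)) return(list(i = integer(), j = integer(),
                                ele = numeric(), vdw = numeric()))
  dv <- coords[pairs$i, , drop = FALSE] - coords[pairs$j, , drop = FALSE]
  r2 <- rowSums(dv^2)
  if (any(r2 < 1e-12)) stop("singularity: beads overlap at zero distance")
  r <- sqrt(r2)
  ele <- COULOMB_KCAL * system$charge[pairs$i] * system$charge[pairs$j] / r
  eps <- system$eps[cbind(pairs$i, pairs$j)]
  sig <- system$sigma[cbind(pairs$i, pairs$j)]
  sr6 <- (sig / r)^6
  vdw <- 4 * eps * (sr6^2 - sr6)
  list(i = pairs$i, j = pairs$j, ele = ele, vdw = vdw)
}

# deterministic spiral (generalized Fibonacci) unit sphere point set
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each bead's accessible sphere (radius + probe) is sampled with a
#' deterministic spiral point set; points inside any other selected bead's
#' accessible sphere are buried.
#'
#' @param system a `toy_system`
#' @param coords n x 3 coordinates
#' @param selection bead indices forming the molecule
#' @param probe probe radius (Angstrom)
#' @param n_points quadrature points per bead
#' @param per_bead return the per-bead area vector instead of the total
#' @return area in A^2
#' @export
sasa <- function(system, coords, selection = seq_len(nrow(system$pos)),
                 probe = 1.4, n_points = 960L, per_bead = FALSE) {
  if (any(system$radius[selection] <= 0)) stop("zero bead radius")
  pts <- sphere_points(n_points)
  rr <- system$radius[selection] + probe
  xyz <- coords[selection, , drop = FALSE]
  ns <- length(selection)
  areas <- numeric(ns)
  for (a in seq_len(ns)) {
    p <- sweep(pts * rr[a], 2, xyz[a, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (b in seq_len(ns)) {
      if (b == a) next
      d2 <- (xyz[b, 1] - xyz[a, 1])^2 + (xyz[b, 2] - xyz[a, 2])^2 +
        (xyz[b, 3] - xyz[a, 3])^2
      if (d2 >= (rr[a] + rr[b])^2) next
      dd <- (p[, 1] - xyz[b, 1])^2 + (p[, 2] - xyz[b, 2])^2 +
        (p[, 3] - xyz[b, 3])^2
      exposed <- exposed & dd > rr[b]^2
      if (!any(exposed)) break
    }
    areas[a] <- 4 * pi * rr[a]^2 * sum(exposed) / n_points
  }
  if (per_bead) areas else sum(areas)
}

#' Nonpolar solvation free energy from surface area
#'
#' @param area A^2
#' @param gamma surface tension (kcal/mol/A^2)
#' @export
nonpolar_g <- function(area, gamma = 0.0072) gamma * area

# Debye screening parameter (1/Angstrom) for a 1:1 salt
debye_kappa <- function(ionic, eps_out, temperature) {
  if (ionic == 0) return(0)
  lb <- COULOMB_KCAL / (eps_out * kB_KCAL * temperature)  # Bjerrum length, A
  rho <- ionic * 6.02214076e-4                            # ions/A^3 per species
  sqrt(8 * pi * lb * rho)
}

#' Polar solvation energy (generalized-Born-style surrogate)
#'
#' A pairwise Born/Still model standing in for a grid Poisson-Boltzmann
#' solver: effective radii are the bead radii,
#' `f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j)))`, and the solvent
#' term is Debye-screened at the configured ionic strength,
#' `G = -166.03 (1/eps_in - exp(-kappa f_GB)/eps_out) sum q_i q_j / f_GB`
#' (self terms included). For an isolated bead this reduces to the Born
#' self-energy; at infinite separation pair terms vanish.
#'
#' @param system a `toy_system`
#' @param coords n x 3 coordinates
#' @param selection bead indices forming the molecule
#' @param config an [endstate_config()]
#' @export
polar_g <- function(system, coords, selection = seq_len(nrow(system$pos)),
                    config = endstate_config()) {
  sum(polar_g_pairs(system, coords, selection, config)$g)
}

# pairwise + self GB terms; returns beads i, j and energy per (i <= j) pair
polar_g_pairs <- function(system, coords, selection, config) {
  q <- system$charge[selection]
  a <- system$radius[selection]
  xyz <- coords[selection, , drop = FALSE]
  kappa <- debye_kappa(config$ionic, config$eps_out, config$temperature)
  ns <- length(selection)
  pre <- -0.5 * COULOMB_KCAL
  ii <- jj <- integer(); gg <- numeric()
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      if (q[i] == 0 || q[j] == 0) next
      r2 <- sum((xyz[i, ] - xyz[j, ])^2)
      ab <- a[i] * a[j]
      fgb <- sqrt(r2 + ab * exp(-r2 / (4 * ab)))
      diel <- 1 / config$eps_in - exp(-kappa * fgb) / config$eps_out
      mult <- if (i == j) 1 else 2
      ii <- c(ii, selection[i]); jj <- c(jj, selection[j])
      gg <- c(gg, pre * diel * mult * q[i] * q[j] / fgb)
    }
  }
  list(i = ii, j = jj, g = gg)
}

#' Single-trajectory end-state binding free energy over frames
#'
#' For every frame the complex, receptor and ligand energies are evaluated
#' on the same coordinates (single-trajectory approximation), giving per
#' frame `dE_MM = dE_internal + dE_electrostatics + dE_vdw`,
#' `dG_sol = dG_PB + dG_SA`, and
#' `dG_binding = dE_MM + dG_sol - T dS` with the entropy term fixed at zero
#' and flagged not-computed. Under the single-trajectory approximation the
#' bonded terms cancel exactly, so `dE_internal` is asserted to vanish.
#'
#' @param traj a `trajectory_ensemble`
#' @param system the `toy_system` the frames belong to
#' @param receptor_sel,ligand_sel bead selections partitioning the complex
#' @param config an [endstate_config()]
#' @return object of class `energy_decomposition`: per-frame term matrix,
#'   aggregate means with standard errors, and per-residue contributions
#' @export
binding_dg_frames <- function(traj, system,
                              receptor_sel = chain_beads(system, "A"),
                              ligand_sel = chain_beads(system, "B"),
                              config = endstate_config()) {
  stopifnot(length(intersect(receptor_sel, ligand_sel)) == 0)
  stopifnot(setequal(c(receptor_sel, ligand_sel), seq_len(nrow(system$pos))))
  nf <- n_frames(traj)
  nres <- length(system$residue_chain)
  terms <- matrix(NA_real_, nf, 6,
                  dimnames = list(NULL, c("internal", "electrostatics", "vdw",
                                          "pb", "sa", "total")))
  res_contrib <- matrix(0, nf, nres)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    # cross-chain MM pair terms are the whole of dE_MM in single-trajectory
    pr <- mm_pair_terms(system, x, receptor_sel, ligand_sel)
    d_ele <- sum(pr$ele); d_vdw <- sum(pr$vdw)
    # GB: self and within-chain terms cancel; cross-chain pairs remain
    gbc <- polar_g_pairs(system, x, sort(c(receptor_sel, ligand_sel)), config)
    inr <- logical(nrow(system$pos)); inr[receptor_sel] <- TRUE
    cross <- inr[gbc$i] != inr[gbc$j]
    d_pb <- sum(gbc$g[cross])
    # SA: buried area, per bead
    sa_c <- sasa(system, x, probe = config$probe,
                 n_points = config$sasa_points, per_bead = TRUE)
    sa_r <- sasa(system, x, receptor_sel, probe = config$probe,
                 n_points = config$sasa_points, per_bead = TRUE)
    sa_l <- sasa(system, x, ligand_sel, probe = config$probe,
                 n_points = config$sasa_points, per_bead = TRUE)
    d_sa_bead <- numeric(nrow(system$pos))
    d_sa_bead[receptor_sel] <- sa_c[receptor_sel] - sa_r
    d_sa_bead[ligand_sel] <- sa_c[ligand_sel] - sa_l
    d_sa <- nonpolar_g(sum(d_sa_bead), config$gamma)
    terms[f, ] <- c(0, d_ele, d_vdw, d_pb, d_sa,
                    d_ele + d_vdw + d_pb + d_sa)
    # residue split: pair terms half-and-half, SA by owning bead
    rid <- system$residue_id
    pair_e <- pr$ele + pr$vdw
    for (p in seq_along(pair_e)) {
      res_contrib[f, rid[pr$i[p]]] <- res_contrib[f, rid[pr$i[p]]] + pair_e[p] / 2
      res_contrib[f, rid[pr$j[p]]] <- res_contrib[f, rid[pr$j[p]]] + pair_e[p] / 2
    }
    gcross <- which(cross)
    for (p in gcross) {
      res_contrib[f, rid[gbc$i[p]]] <- res_contrib[f, rid[gbc$i[p]]] + gbc$g[p] / 2
      res_contrib[f, rid[gbc$j[p]]] <- res_contrib[f, rid[gbc$j[p]]] + gbc$g[p] / 2
    }
    sa_res <- tapply(nonpolar_g(d_sa_bead, config$gamma), rid, sum)
    res_contrib[f, as.integer(names(sa_res))] <-
      res_contrib[f, as.integer(names(sa_res))] + as.numeric(sa_res)
  }
  mean_se <- function(v) c(mean = mean(v),
                           se = stats::sd(v) / sqrt(max(1, length(v))))
  agg <- apply(terms, 2, mean_se)
  structure(list(
    frames = terms, aggregate = agg,
    dG_binding = agg["mean", "total"], dG_se = agg["se", "total"],
    TdS = 0, TdS_computed = FALSE,
    residue_contrib = res_contrib,
    residue_chain = system$residue_chain,
    residue_number = system$residue_number,
    config = config), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("energy_decomposition over %d frames: dG = %.3f +/- %.3f kcal/mol\n",
              nrow(x$frames), x$dG_binding, x$dG_se))
  cat(sprintf("  dE_ele %.3f  dE_vdw %.3f  dG_PB %.3f  dG_SA %.3f  (-TdS %s)\n",
              x$aggregate["mean", "electrostatics"],
              x$aggregate["mean", "vdw"], x$aggregate["mean", "pb"],
              x$aggregate["mean", "sa"],
              if (x$TdS_computed) sprintf("%.3f", -x$TdS) else "not computed"))
  invisible(x)
}

#' Per-residue contributions to the binding free energy
#'
#' Pair energies are split half-and-half between the partner residues and
#' the buried-area term is assigned to the residue owning each bead, so the
#' residue sums reproduce the frame totals exactly.
#'
#' @param decomp an `energy_decomposition` from [binding_dg_frames()]
#' @return data frame: residue chain, number, mean contribution and
#'   standard error (kcal/mol)
#' @export
per_residue_decomposition <- function(decomp) {
  m <- colMeans(decomp$residue_contrib)
  se <- apply(decomp$residue_contrib, 2, stats::sd) /
    sqrt(nrow(decomp$residue_contrib))
  data.frame(chain = decomp$residue_chain,
             residue = decomp$residue_number,
             mean = m, se = se)
}
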