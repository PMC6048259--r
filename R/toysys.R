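#' Coarse-grained receptor-ligand toy systems
#'
#' A `toy_system` is a bead model of a two-chain complex: chain A is the
#' receptor, chain B the ligand. Each residue carries a backbone bead and an
#' interface-facing side-chain bead; hydrogen-bond donor residues carry an
#' explicit hydrogen bead bonded to the side chain. The force field is
#' harmonic bonds + a Lennard-Jones-style pair term + screened Coulomb
#' electrostatics. The `MUT` variant differs from `WT` only in a declared set
#' of interface parameters: the "deleted" residue loses its attractive well
#' and charge and its two sequence neighbours have their interface well
#' depths halved, emulating the way a single-residue deletion degrades an
#' activator-binding interface.
#'
#' @param n_receptor_res number of receptor (chain A) residues, >= 1
#' @param n_ligand_res number of ligand (chain B) residues, >= 1
#' @param variant `"WT"` or `"MUT"`
#' @param seed integer; perturbs the reference coordinates by a tiny jitter so
#'   replicate systems start from distinct but equivalent configurations.
#'   Geometry is identical between `WT` and `MUT` at equal seed.
#' @return an object of class `toy_system`
#' @export
build_toy_dimer <- function(n_receptor_res, n_ligand_res,
                            variant = c("WT", "MUT"), seed = 0L) {
  variant <- match.arg(variant)
  if (!is.numeric(n_receptor_res) || length(n_receptor_res) != 1L ||
      n_receptor_res < 1 || n_receptor_res != round(n_receptor_res)) {
    stop("sizing error: n_receptor_res must be a positive integer")
  }
  if (!is.numeric(n_ligand_res) || length(n_ligand_res) != 1L ||
      n_ligand_res < 1 || n_ligand_res != round(n_ligand_res)) {
    stop("sizing error: n_ligand_res must be a positive integer")
  }
  n_receptor_res <- as.integer(n_receptor_res)
  n_ligand_res <- as.integer(n_ligand_res)

  spacing <- 4.0     # backbone spacing along x
  d0 <- 6.8          # backbone-to-backbone interface separation (y)
  # align the ligand chain residue-on-residue against the receptor chain
  off_x <- floor((n_receptor_res - n_ligand_res) / 2) * spacing

  pos <- NULL; mass <- c(); charge <- c(); radius <- c()
  bead_name <- c(); res_of_bead <- c()
  res_chain <- c(); res_number <- c(); res_name <- c()
  bonds <- list()
  donors <- list()       # (donor bead, hydrogen bead) pairs
  acceptors <- integer() # acceptor bead indices

  add_bead <- function(p, m, q, r, nm, res) {
    pos <<- rbind(pos, p)
    mass <<- c(mass, m); charge <<- c(charge, q); radius <<- c(radius, r)
    bead_name <<- c(bead_name, nm); res_of_bead <<- c(res_of_bead, res)
    nrow(pos)
  }

  mut_res <- (n_receptor_res + 1L) %/% 2L  # receptor residue whose parameters MUT deletes
  res_id <- 0L
  rec_B <- integer(n_receptor_res); rec_S <- integer(n_receptor_res)
  for (i in seq_len(n_receptor_res)) {
    res_id <- res_id + 1L
    res_chain[res_id] <- "A"; res_number[res_id] <- i
    res_name[res_id] <- if (i == mut_res) "GLX" else if (i %% 2L == 1L) "DON" else "RES"
    x <- (i - 1L) * spacing
    rec_B[i] <- add_bead(c(x, 0, 0), 40, 0, 2.0, "CA", res_id)
    rec_S[i] <- add_bead(c(x, 2, 0), 30, 0, 1.7, "CB", res_id)
    bonds[[length(bonds) + 1L]] <- c(rec_B[i], rec_S[i], 10, 2)
    if (i > 1L) bonds[[length(bonds) + 1L]] <- c(rec_B[i - 1L], rec_B[i], 10, spacing)
    if (i %% 2L == 1L) {  # donor residue: explicit hydrogen on the side chain
      h <- add_bead(c(x, 3, 0), 3, 0, 1.0, "HD", res_id)
      bonds[[length(bonds) + 1L]] <- c(rec_S[i], h, 25, 1)
      donors[[length(donors) + 1L]] <- c(rec_S[i], h)
    }
  }
  lig_B <- integer(n_ligand_res); lig_S <- integer(n_ligand_res)
  for (j in seq_len(n_ligand_res)) {
    res_id <- res_id + 1L
    res_chain[res_id] <- "B"; res_number[res_id] <- j
    res_name[res_id] <- "LIG"
    x <- off_x + (j - 1L) * spacing
    lig_B[j] <- add_bead(c(x, d0, 0), 40, 0, 2.0, "CA", res_id)
    lig_S[j] <- add_bead(c(x, d0 - 2, 0), 30, 0, 1.7, "CB", res_id)
    bonds[[length(bonds) + 1L]] <- c(lig_B[j], lig_S[j], 10, 2)
    if (j > 1L) bonds[[length(bonds) + 1L]] <- c(lig_B[j - 1L], lig_B[j], 10, spacing)
    if (j %% 2L == 1L) acceptors <- c(acceptors, lig_S[j])
  }
  n <- nrow(pos)
  dimnames(pos) <- NULL
  bonds <- do.call(rbind, bonds)
  bonds <- data.frame(i = as.integer(bonds[, 1]), j = as.integer(bonds[, 2]),
                      k = bonds[, 3], r0 = bonds[, 4])

  # exclusions: 1-2 and 1-3 neighbours in the bond graph
  adj <- matrix(FALSE, n, n)
  adj[cbind(bonds$i, bonds$j)] <- TRUE
  adj <- adj | t(adj)
  excl <- adj | (adj %*% adj > 0)
  diag(excl) <- TRUE

  # pair parameters; hydrogen beads carry only a small repulsive core
  sigma <- outer(radius, radius, `+`)
  eps <- matrix(0.05, n, n)
  hmask <- bead_name == "HD"
  eps[hmask, ] <- 0.02; eps[, hmask] <- 0.02
  sigma[hmask, ] <- 1.6; sigma[, hmask] <- 1.6

  # interface pairing: ligand residue j binds the receptor residue facing it
  partner <- pmin(pmax(as.integer(off_x / spacing) + seq_len(n_ligand_res),
                       1L), n_receptor_res)
  eps_int <- 4.0
  sig_int <- 2.8 / 2^(1 / 6)  # well minimum at the 2.8 A interface gap
  interface_pairs <- cbind(rec_S[partner], lig_S)
  for (r in seq_len(nrow(interface_pairs))) {
    a <- interface_pairs[r, 1]; b <- interface_pairs[r, 2]
    eps[a, b] <- eps[b, a] <- eps_int
    sigma[a, b] <- sigma[b, a] <- sig_int
  }

  # hydrogen-bonding partial charges: donor side chains carry a -q/+q dipole
  # (side chain / hydrogen) and acceptor side chains carry -q balanced on the
  # backbone, so hydrogens orient electrostatically toward approaching
  # acceptors the way polar hydrogens do
  q_hb <- 0.65
  for (d in seq_along(donors)) {
    charge[donors[[d]][1]] <- -q_hb
    charge[donors[[d]][2]] <- +q_hb
  }
  acc_res <- res_of_bead[acceptors]
  charge[acceptors] <- -q_hb
  charge[lig_B[match(acc_res, res_of_bead[lig_B])]] <- +q_hb

  mutated <- NULL
  if (variant == "MUT") {
    # the "deleted" residue: attractive parameters removed, neighbours perturbed
    sm <- rec_S[mut_res]
    pl_idx <- which(partner == mut_res)
    mutated <- data.frame(
      what = "charge", i = sm, j = NA_integer_,
      wt = charge[sm], mut = 0, stringsAsFactors = FALSE)
    charge[sm] <- 0
    hm <- which(vapply(seq_len(nrow(pos))[hmask], function(b)
      res_of_bead[b] == res_of_bead[sm], logical(1)))
    hb_bead <- which(hmask)[hm]
    if (length(hb_bead)) {
      mutated <- rbind(mutated, data.frame(
        what = "charge", i = hb_bead, j = NA_integer_,
        wt = charge[hb_bead], mut = 0))
      charge[hb_bead] <- 0
    }
    for (pl in lig_S[pl_idx]) {
      mutated <- rbind(mutated, data.frame(
        what = "eps", i = sm, j = pl, wt = eps[sm, pl], mut = 0.05))
      eps[sm, pl] <- eps[pl, sm] <- 0.05
    }
    for (nb in c(mut_res - 1L, mut_res + 1L)) {
      if (nb >= 1L && nb <= n_receptor_res) {
        jl <- which(partner == nb)
        for (jj in jl) {
          a <- rec_S[nb]; b <- lig_S[jj]
          mutated <- rbind(mutated, data.frame(
            what = "eps", i = a, j = b, wt = eps[a, b], mut = eps[a, b] * 0.5))
          eps[a, b] <- eps[b, a] <- eps[a, b] * 0.5
        }
      }
    }
  }

  # replicate-to-replicate jitter (identical across variants at equal seed)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  pos <- pos + matrix(stats::rnorm(3 * n, sd = 0.01), n, 3)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  sys <- structure(list(
    pos = pos, mass = mass, charge = charge, radius = radius,
    bead_name = bead_name, residue_id = as.integer(res_of_bead),
    residue_chain = res_chain, residue_number = as.integer(res_number),
    residue_name = res_name,
    bonds = bonds, eps = eps, sigma = sigma, excl = excl,
    dielectric = 10, screen_length = 8,
    donors = if (length(donors)) do.call(rbind, donors) else matrix(integer(), 0, 2),
    acceptors = acceptors,
    restraints = data.frame(bead = integer(), k = numeric(),
                            x = numeric(), y = numeric(), z = numeric()),
    frozen = rep(FALSE, n),
    external = list(),
    variant = variant, seed = as.integer(seed),
    mutated_params = mutated,
    interface = list(mut_res = mut_res, partner = partner,
                     rec_S = rec_S, lig_S = lig_S, rec_B = rec_B, lig_B = lig_B)
  ), class = "toy_system")
  validate_toy_system(sys)
  sys
}

validate_toy_system <- function(sys) {
  n <- nrow(sys$pos)
  stopifnot(
    length(sys$mass) == n, length(sys$charge) == n, length(sys$radius) == n,
    all(sys$mass > 0), all(sys$radius > 0), all(sys$sigma > 0),
    length(sys$residue_id) == n,
    all(sys$residue_id >= 1), all(sys$residue_id <= length(sys$residue_chain)),
    all(sys$bonds$i >= 1), all(sys$bonds$i <= n),
    all(sys$bonds$j >= 1), all(sys$bonds$j <= n)
  )
  invisible(sys)
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system [%s]: %d beads, %d residues (%d receptor / %d ligand), %d bonds\n",
              x$variant, nrow(x$pos), length(x$residue_chain),
              sum(x$residue_chain == "A"), sum(x$residue_chain == "B"),
              nrow(x$bonds)))
  invisible(x)
}

#' Bead indices belonging to a chain or residue
#'
#' @param system a `toy_system`
#' @param chain `"A"` (receptor) or `"B"` (ligand)
#' @return integer bead indices
#' @export
chain_beads <- function(system, chain) {
  which(system$residue_chain[system$residue_id] == chain)
}

#' @param resid global residue id
#' @rdname chain_beads
#' @export
residue_beads <- function(system, resid) {
  which(system$residue_id == resid)
}

#' Declared parameter differences between two variants of a system
#'
#' Enumerates every bead/pair parameter (charges, pair well depths and
#' diameters, bond constants, masses, radii) and returns the entries on which
#' the two systems disagree. For a `WT`/`MUT` pair built with
#' [build_toy_dimer()] at equal seed, this is exactly the declared mutation
#' set.
#'
#' @param a,b two `toy_system` objects with identical topology
#' @return data frame with one row per differing parameter entry
#' @export
variant_parameter_diff <- function(a, b) {
  stopifnot(nrow(a$pos) == nrow(b$pos))
  out <- list()
  add <- function(what, i, j, va, vb) {
    out[[length(out) + 1L]] <<- data.frame(what = what, i = i, j = j,
                                           a = va, b = vb)
  }
  for (i in seq_along(a$charge)) {
    if (a$charge[i] != b$charge[i]) add("charge", i, NA_integer_, a$charge[i], b$charge[i])
    if (a$mass[i] != b$mass[i]) add("mass", i, NA_integer_, a$mass[i], b$mass[i])
    if (a$radius[i] != b$radius[i]) add("radius", i, NA_integer_, a$radius[i], b$radius[i])
  }
  n <- nrow(a$pos)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (a$eps[i, j] != b$eps[i, j]) add("eps", i, j, a$eps[i, j], b$eps[i, j])
    if (a$sigma[i, j] != b$sigma[i, j]) add("sigma", i, j, a$sigma[i, j], b$sigma[i, j])
  }
  if (!identical(dim(a$bonds), dim(b$bonds)) ||
      any(a$bonds != b$bonds)) add("bonds", NA_integer_, NA_integer_, NA_real_, NA_real_)
  if (length(out)) do.call(rbind, out) else
    data.frame(what = character(), i = integer(), j = integer(),
               a = numeric(), b = numeric())
}

#' Reference bound and dissociated configurations of a toy dimer
#'
#' Returns the as-built (bound) coordinates and a configuration with the
#' ligand chain translated away from the interface by `separation` Angstrom.
#'
#' @param system a `toy_system`
#' @param separation rigid displacement of the ligand along +y (Angstrom)
#' @return list with elements `bound` and `dissociated`, each an n x 3 matrix
#' @export
reference_configurations <- function(system, separation = 30) {
  bound <- system$pos
  diss <- bound
  lig <- chain_beads(system, "B")
  diss[lig, 2] <- diss[lig, 2] + separation
  list(bound = bound, dissociated = diss)
}
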