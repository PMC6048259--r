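# Shared builders for analytic benchmark systems.

# single bead in a 1-D double well (x axis) with harmonic confinement in y, z
double_well_system <- function(h = 3, a = 1.5, mass = 12, k_conf = 10) {
  bead_system(matrix(c(a, 0, 0), 1, 3), mass = mass,
              external = list(
                list(type = "double_well", bead = 1, axis = 1, h = h, a = a),
                list(type = "harmonic", bead = 1, k = c(0, k_conf, k_conf),
                     center = c(0, 0, 0))))
}

# frozen anchor pair + mobile bonded pair in a harmonic x-well: the distance
# CV between the pair centres is 20 + X with an analytic PMF kx * (cv - 20)^2
harmonic_cv_system <- function(kx = 0.25, k_conf = 10) {
  pos <- rbind(c(-20, 0.5, 0), c(-20, -0.5, 0), c(0, 0.5, 0), c(0, -0.5, 0))
  sys <- bead_system(pos, mass = c(40, 40, 12, 12),
    external = list(
      list(type = "harmonic", bead = 3, k = c(kx, k_conf, k_conf),
           center = c(0, 0.5, 0)),
      list(type = "harmonic", bead = 4, k = c(kx, k_conf, k_conf),
           center = c(0, -0.5, 0))),
    frozen = c(TRUE, TRUE, FALSE, FALSE))
  sys$bonds <- data.frame(i = 3L, j = 4L, k = 50, r0 = 1)
  sys
}

harmonic_cv <- function() {
  collective_variable("distance", T = 1, U = 2, W = 3, X = 4)
}

# dimer with every receptor-ligand interaction switched off (charges zeroed,
# cross-chain wells removed) and the ligand parked at a distance, held there
# by weak restraints -- the null construction for end-state energetics
decoupled_dimer <- function(seed = 1, separation = 25) {
  sys <- build_toy_dimer(5, 4, "WT", seed = seed)
  sys$charge[] <- 0
  rec <- chain_beads(sys, "A"); lig <- chain_beads(sys, "B")
  sys$eps[rec, lig] <- 0
  sys$eps[lig, rec] <- 0
  sys$pos[lig, 2] <- sys$pos[lig, 2] + separation
  all_b <- seq_len(nrow(sys$pos))
  sys$restraints <- data.frame(bead = all_b, k = 0.5,
                               x = sys$pos[all_b, 1], y = sys$pos[all_b, 2],
                               z = sys$pos[all_b, 3])
  sys
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max deviation %.3g (tol %.3g)",
                              max(abs(object - expected)), tol))
}
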