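test_that("gas-phase terms obey closed forms", {
  sys <- build_toy_dimer(3, 2, "WT", seed = 1)
  # a single bead carries no pair or bonded energy
  single <- mm_terms(sys, sys$pos, selection = 1L)
  expect_equal(unname(single), c(0, 0, 0))
  # two unit charges at 3.32 A: vacuum Coulomb constant closed form
  two <- bead_system(rbind(c(0, 0, 0), c(3.32, 0, 0)))
  two$charge <- c(1, 1)
  two$eps[] <- 0
  two$excl[] <- FALSE; diag(two$excl) <- TRUE
  got <- mm_terms(two, two$pos)
  expect_equal(got[["electrostatics"]], 332.0637 / 3.32, tolerance = 1e-12)
  expect_close(got[["electrostatics"]], 100.02, 0.01)
})

test_that("random selections match a brute-force pair summation", {
  set.seed(8)
  sys <- build_toy_dimer(4, 3, "MUT", seed = 8)
  coords <- sys$pos + matrix(rnorm(3 * nrow(sys$pos), sd = 0.3),
                             nrow(sys$pos), 3)
  sel <- sample(nrow(sys$pos), 8)
  got <- mm_terms(sys, coords, sel)
  e_ele <- 0; e_vdw <- 0; e_int <- 0
  for (a in 1:7) for (b in (a + 1):8) {
    i <- sel[a]; j <- sel[b]
    if (sys$excl[i, j]) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e_ele <- e_ele + 332.0637 * sys$charge[i] * sys$charge[j] / r
    sr6 <- (sys$sigma[i, j] / r)^6
    e_vdw <- e_vdw + 4 * sys$eps[i, j] * (sr6^2 - sr6)
  }
  for (b in seq_len(nrow(sys$bonds))) {
    if (!(sys$bonds$i[b] %in% sel) || !(sys$bonds$j[b] %in% sel)) next
    r <- sqrt(sum((coords[sys$bonds$i[b], ] - coords[sys$bonds$j[b], ])^2))
    e_int <- e_int + 0.5 * sys$bonds$k[b] * (r - sys$bonds$r0[b])^2
  }
  expect_equal(got[["electrostatics"]], e_ele, tolerance = 1e-10)
  expect_equal(got[["vdw"]], e_vdw, tolerance = 1e-10)
  expect_equal(got[["internal"]], e_int, tolerance = 1e-10)
})

test_that("surface areas match sphere closed forms", {
  lone <- bead_system(matrix(0, 1, 3))
  lone$radius <- 1.9
  a <- sasa(lone, lone$pos, probe = 1.4, n_points = 960)
  expect_close(a / (4 * pi * (1.9 + 1.4)^2), 1, 0.01)
  # a bead fully buried inside a larger sphere exposes nothing
  pair <- bead_system(rbind(c(0, 0, 0), c(0.2, 0, 0)))
  pair$radius <- c(0.5, 4)
  ab <- sasa(pair, pair$pos, probe = 1.4, n_points = 960, per_bead = TRUE)
  expect_equal(ab[1], 0)
  expect_error({ z <- pair; z$radius[1] <- 0; sasa(z, z$pos) }, "radius")
})

test_that("two-sphere overlap area matches a dense quadrature oracle", {
  pair <- bead_system(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  pair$radius <- c(1.6, 1.9)
  got <- sasa(pair, pair$pos, probe = 1.4, n_points = 960)
  # oracle: same geometry at a 20x denser, different point set cannot share
  # quadrature artefacts at this resolution
  dense <- sasa(pair, pair$pos, probe = 1.4, n_points = 19200)
  expect_close(got / dense, 1, 0.01)
  # analytic spherical-cap area for two intersecting accessible spheres
  r1 <- 3.0; r2 <- 3.3; d <- 2.5
  cap <- function(r, rr, dd) 2 * pi * r * (r - (dd^2 + r^2 - rr^2) / (2 * dd))
  exact <- 4 * pi * (r1^2 + r2^2) - cap(r1, r2, d) - cap(r2, r1, d)
  expect_close(got / exact, 1, 0.01)
})

test_that("the nonpolar term is linear in area", {
  expect_equal(nonpolar_g(100, 0.0072), 0.72)
  expect_equal(nonpolar_g(0, 0.0072), 0)
  expect_equal(nonpolar_g(140 + 60, 0.0072),
               nonpolar_g(140, 0.0072) + nonpolar_g(60, 0.0072))
})

test_that("the polar surrogate reduces to the Born self-energy", {
  one <- bead_system(matrix(0, 1, 3))
  one$charge <- -1; one$radius <- 2
  cfg <- endstate_config(ionic = 0, eps_in = 1, eps_out = 80)
  born <- -0.5 * (1 - 1 / 80) * 332.0637 / 2
  expect_equal(polar_g(one, one$pos, config = cfg), born, tolerance = 1e-12)
  # zero charges: zero polar energy
  sysn <- build_toy_dimer(2, 2, "WT", seed = 1)
  sysn$charge[] <- 0
  expect_equal(polar_g(sysn, sysn$pos), 0)
  expect_error(endstate_config(eps_out = -2), "dielectrics")
})

test_that("well-separated beads approach the sum of Born self-terms", {
  two <- bead_system(rbind(c(0, 0, 0), c(1e6, 0, 0)))
  two$charge <- c(1, -1); two$radius <- c(1.5, 2.5)
  cfg <- endstate_config(ionic = 0)
  self <- function(q, a) -0.5 * (1 / cfg$eps_in - 1 / cfg$eps_out) *
    332.0637 * q^2 / a
  total <- polar_g(two, two$pos, config = cfg)
  expect_close(total, self(1, 1.5) + self(-1, 2.5), 1e-3)
  # with salt: total still decomposes into the (screened) self terms
  cfg_salt <- endstate_config(ionic = 0.150)
  self_salt <- sum(vapply(1:2, function(i) {
    one <- bead_system(matrix(0, 1, 3))
    one$charge <- two$charge[i]; one$radius <- two$radius[i]
    polar_g(one, one$pos, config = cfg_salt)
  }, numeric(1)))
  expect_close(polar_g(two, two$pos, config = cfg_salt), self_salt, 1e-3)
})

test_that("frame-wise decomposition identities hold exactly", {
  sys <- build_toy_dimer(4, 3, "WT", seed = 6)
  traj <- make_interface_ensemble(sys, ensemble_spec(6, noise = 0.1, seed = 2))
  dec <- binding_dg_frames(traj, sys)
  fr <- dec$frames
  # dE_MM additivity and single-trajectory internal cancellation
  expect_true(all(fr[, "internal"] == 0))
  expect_close(fr[, "total"],
               fr[, "internal"] + fr[, "electrostatics"] + fr[, "vdw"] +
                 fr[, "pb"] + fr[, "sa"], 1e-8)
  # entropy carried as an explicit not-computed zero
  expect_identical(dec$TdS, 0)
  expect_false(dec$TdS_computed)
  # per-residue conservation: residue sums reproduce the frame totals
  expect_close(rowSums(dec$residue_contrib), fr[, "total"], 1e-6)
  pr <- per_residue_decomposition(dec)
  expect_equal(sum(pr$mean), dec$dG_binding, tolerance = 1e-6)
  expect_equal(nrow(pr), length(sys$residue_chain))
})

test_that("a two-residue complex splits its energy across both residues", {
  sys <- build_toy_dimer(1, 1, "WT", seed = 3)
  traj <- make_interface_ensemble(sys, ensemble_spec(4, noise = 0.05, seed = 4))
  dec <- binding_dg_frames(traj, sys)
  pr <- per_residue_decomposition(dec)
  expect_equal(nrow(pr), 2L)
  expect_equal(sum(pr$mean), dec$dG_binding, tolerance = 1e-9)
  expect_true(all(abs(pr$mean) > 0))
})

test_that("a fully decoupled dimer binds with zero free energy", {
  sys <- decoupled_dimer(seed = 4)
  traj <- discard_equilibration(
    run_cmd(sys, integrator_config(10000, save_stride = 50L, seed = 4)))
  dec <- binding_dg_frames(traj, sys)
  expect_lte(abs(dec$dG_binding), 3 * dec$dG_se + 1e-9)
})

test_that("the mutant binds more weakly than wild type by the end-state route", {
  dg <- sapply(c(101, 202), function(s) {
    sapply(c("WT", "MUT"), function(v) {
      sys <- build_toy_dimer(5, 4, v, seed = s)
      traj <- discard_equilibration(
        run_cmd(sys, integrator_config(12000, save_stride = 60L, seed = s)))
      binding_dg_frames(traj, sys)$dG_binding
    })
  })
  expect_true(all(dg["MUT", ] - dg["WT", ] > 0))
})
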