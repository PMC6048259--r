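test_that("minimal dimer construction assigns every bead to a chain", {
  sys <- build_toy_dimer(1, 1, "WT", seed = 0)
  expect_s3_class(sys, "toy_system")
  expect_equal(length(sys$residue_chain), 2L)
  chain_of_bead <- sys$residue_chain[sys$residue_id]
  expect_true(all(chain_of_bead %in% c("A", "B")))
  expect_setequal(unique(chain_of_bead), c("A", "B"))
})

test_that("non-positive residue counts are rejected with a sizing error", {
  expect_error(build_toy_dimer(0, 3), "sizing")
  expect_error(build_toy_dimer(3, -1), "sizing")
  expect_error(build_toy_dimer(2.5, 3), "sizing")
})

test_that("construction is deterministic and MUT differs only in the declared set", {
  wt1 <- build_toy_dimer(5, 4, "WT", seed = 7)
  wt2 <- build_toy_dimer(5, 4, "WT", seed = 7)
  expect_identical(wt1$pos, wt2$pos)
  expect_identical(wt1$eps, wt2$eps)

  mut <- build_toy_dimer(5, 4, "MUT", seed = 7)
  expect_identical(wt1$pos, mut$pos)  # parameter deletion, not topology surgery
  diff <- variant_parameter_diff(wt1, mut)
  # the declared set: the deleted residue's charges (side chain + hydrogen),
  # its interface well, and the two neighbours' halved wells
  expect_identical(sort(diff$what), sort(c("charge", "charge", "eps", "eps", "eps")))
  declared <- mut$mutated_params
  expect_equal(nrow(diff), nrow(declared))
  # every differing eps entry involves an interface side-chain bead
  eps_rows <- diff[diff$what == "eps", ]
  expect_true(all(eps_rows$i %in% wt1$interface$rec_S))
  expect_true(all(eps_rows$j %in% wt1$interface$lig_S))
})

test_that("the WT bound state is an energy minimum relative to dissociation", {
  sys <- build_toy_dimer(5, 4, "WT", seed = 7)
  ref <- reference_configurations(sys)
  # direct energy evaluation at the two reference configurations
  e_bound <- potential_energy(sys, ref$bound)$total
  e_diss <- potential_energy(sys, ref$dissociated)$total
  expect_lt(e_bound, e_diss)
  # the mutant interface is strictly weaker at identical geometry
  mut <- build_toy_dimer(5, 4, "MUT", seed = 7)
  expect_gt(potential_energy(mut, ref$bound)$total, e_bound)
})

test_that("ensemble specs validate probabilities and prescriptions", {
  expect_error(ensemble_spec(0), "n_frames")
  expect_error(ensemble_spec(10, contact_probs = data.frame(
    res_i = 1, res_j = 1, p = 1.2)), "probabilities")
  expect_error(ensemble_spec(10,
    contact_probs = data.frame(res_i = 1, res_j = 2, p = 0.5),
    hbond_probs = data.frame(donor_res = 3, acceptor_res = 2, p = 0.5)),
    "at most one prescription")
})

test_that("degenerate contact probabilities are realised exactly", {
  sys <- build_toy_dimer(5, 4, "WT", seed = 1)
  spec1 <- ensemble_spec(40, contact_probs = data.frame(
    res_i = c(2, 4), res_j = c(2, 4), p = c(1, 0)), seed = 3)
  ens <- make_interface_ensemble(sys, spec1)
  cm <- contact_map(ens, sys)
  expect_equal(unname(cm$freq["A2", "B2"]), 1)
  expect_equal(unname(cm$freq["A4", "B4"]), 0)
})

test_that("prescribed probabilities are recovered within 3 binomial SE", {
  sys <- build_toy_dimer(5, 4, "WT", seed = 1)
  n <- 5000
  spec <- ensemble_spec(n,
    contact_probs = data.frame(res_i = 2, res_j = 2, p = 0.3),
    hbond_probs = data.frame(donor_res = 3, acceptor_res = 3, p = 0.6),
    seed = 11)
  ens <- make_interface_ensemble(sys, spec)
  cm <- contact_map(ens, sys)
  se_c <- sqrt(0.3 * 0.7 / n)
  expect_close(unname(cm$freq["A2", "B2"]), 0.3, 3 * se_c)
  counts <- hbond_pair_counts(ens, sys)
  got <- counts$count[counts$pair == "A3-B3"]
  se_h <- sqrt(0.6 * 0.4 / n)
  expect_close(got / n, 0.6, 3 * se_h)
  # geometry-only: energies and boosts are zero
  expect_true(all(ens$potential == 0) && all(ens$boost == 0))
})

test_that("PDB round-trip preserves coordinates and labels to fixed precision", {
  sys <- build_toy_dimer(3, 2, "WT", seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys, path)
  got <- read_pdb(path)
  expect_equal(nrow(got$coords), nrow(sys$pos))
  expect_close(got$coords, sys$pos, 1e-3 + 1e-12)
  expect_identical(got$chain, sys$residue_chain[sys$residue_id])
  expect_identical(got$residue_number, sys$residue_number[sys$residue_id])
  expect_identical(got$atom_name, sys$bead_name)
})

test_that("PDB parser rejects truncated records naming the line", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK hand-made",
               "ATOM      1 CA  RES A   1       0.000"), path)
  expect_error(read_pdb(path), "line 2")
  # header-only files parse to an empty container
  writeLines(c("HEADER    SYNTHETIC MINIMAL ENTRY", "TITLE     NO ATOMS",
               "END"), path)
  got <- read_pdb(path)
  expect_equal(nrow(got$coords), 0L)
})

test_that("mismatched coordinate counts are rejected on write", {
  sys <- build_toy_dimer(2, 2, "WT", seed = 0)
  expect_error(write_pdb(sys, tempfile(), coords = sys$pos[-1, ]),
               "does not match")
})

test_that("trajectory container round-trips losslessly", {
  set.seed(5)
  coords <- array(rnorm(3 * 7 * 3), dim = c(3, 7, 3))
  tr <- trajectory_ensemble(coords, potential = rnorm(3), boost = runif(3),
                            timestep = 2, temperature = 310, seed = 9L,
                            provenance = "GaMD")
  path <- tempfile(fileext = ".dtj")
  write_traj(tr, path)
  got <- read_traj(path)
  expect_identical(got$coords, tr$coords)
  expect_identical(got$potential, tr$potential)
  expect_identical(got$boost, tr$boost)
  expect_identical(got$provenance, "GaMD")
  expect_identical(got$seed, 9L)
})

test_that("large trajectory round-trip is bit-exact", {
  set.seed(6)
  nf <- 10000
  coords <- array(rnorm(nf * 2 * 3), dim = c(nf, 2, 3))
  tr <- trajectory_ensemble(coords, potential = rnorm(nf),
                            provenance = "synthetic")
  path <- tempfile(fileext = ".dtj")
  write_traj(tr, path)
  got <- read_traj(path)
  expect_identical(sum(got$coords), sum(tr$coords))
  expect_identical(got$coords, tr$coords)
})

test_that("malformed trajectory files are rejected", {
  path <- tempfile(fileext = ".dtj")
  file.create(path)
  expect_error(read_traj(path), "truncated")
  writeBin(as.raw(1:200), path)
  expect_error(read_traj(path), "magic")
  # shape mismatch: truncate a valid file
  tr <- trajectory_ensemble(array(0, dim = c(2, 2, 3)))
  write_traj(tr, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:(length(raw) - 8)], path)
  expect_error(read_traj(path), "mismatch")
})

test_that("ensemble invariants are enforced", {
  expect_error(trajectory_ensemble(array(0, dim = c(1, 2, 3)),
                                   boost = c(-1)), "boost")
  expect_error(trajectory_ensemble(array(NA_real_, dim = c(1, 2, 3))),
               "finite")
})
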