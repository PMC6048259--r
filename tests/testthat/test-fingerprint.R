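test_that("residue centres of mass are mass-weighted means", {
  sys <- build_toy_dimer(2, 1, "WT", seed = 1)
  # single-bead case via a hand system
  one <- bead_system(matrix(c(1, 2, 3), 1, 3))
  expect_equal(residue_com(one, one$pos, 1), c(1, 2, 3))
  # equal masses: the midpoint
  pairsys <- bead_system(rbind(c(0, 0, 0), c(2, 4, 6)), mass = c(7, 7))
  pairsys$residue_id <- c(1L, 1L)
  pairsys$residue_chain <- "A"; pairsys$residue_number <- 1L
  expect_equal(residue_com(pairsys, pairsys$pos, 1), c(1, 2, 3))
  # random residue: direct sum(m x) / sum(m)
  b <- residue_beads(sys, 1)
  hand <- colSums(sys$pos[b, ] * sys$mass[b]) / sum(sys$mass[b])
  expect_equal(residue_com(sys, sys$pos, 1), hand)
})

test_that("the contact criterion is inclusive at 6 A on residue centres", {
  sys <- build_toy_dimer(1, 1, "WT", seed = 0)
  place <- function(d) {
    x <- sys$pos
    lig <- chain_beads(sys, "B")
    com_r <- residue_com(sys, x, 1)
    com_l <- residue_com(sys, x, 2)
    shift <- (com_r + c(0, d, 0)) - com_l
    x[lig, ] <- sweep(x[lig, , drop = FALSE], 2, shift, `+`)
    x
  }
  tr <- function(d) trajectory_ensemble(array(place(d), c(1, nrow(sys$pos), 3)),
                                        provenance = "synthetic")
  expect_equal(unname(contact_map(tr(5.9), sys)$freq[1, 1]), 1)
  expect_equal(unname(contact_map(tr(6.0), sys)$freq[1, 1]), 1)  # inclusive
  expect_equal(unname(contact_map(tr(6.1), sys)$freq[1, 1]), 0)
})

test_that("contact differences are signed mutant-minus-wild-type", {
  a <- structure(list(freq = matrix(c(1, 0.5, 0, 0.2), 2, 2)), class = "contact_map")
  b <- structure(list(freq = matrix(c(0, 0.5, 1, 0.9), 2, 2)), class = "contact_map")
  expect_equal(contact_difference(a, a), matrix(0, 2, 2))
  d <- contact_difference(b, a)
  expect_equal(d[1, 1], -1)       # lost interaction marks negative
  expect_equal(d, -contact_difference(a, b))
})

test_that("hydrogen-bond detection applies both geometric criteria", {
  sys <- build_toy_dimer(1, 1, "WT", seed = 0)
  D <- sys$donors[1, 1]; H <- sys$donors[1, 2]; A <- sys$acceptors[1]
  geom <- function(d_da, ang_deg) {
    x <- sys$pos
    x[D, ] <- c(0, 0, 0)
    x[H, ] <- c(1, 0, 0)
    # place the acceptor so the A-H-D angle at the hydrogen is exactly
    # ang_deg AND the D-A distance is exactly d_da
    phi <- (180 - ang_deg) * pi / 180
    L <- -cos(phi) + sqrt(cos(phi)^2 - 1 + d_da^2)
    x[A, ] <- c(1, 0, 0) + L * c(cos(phi), sin(phi), 0)
    x
  }
  # linear bond inside both cutoffs
  hb <- detect_hbonds(sys, geom(2.9, 180))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  # angle violation at short distance
  expect_equal(nrow(detect_hbonds(sys, geom(2.9, 120))), 0L)
  # distance violation at ideal angle
  expect_equal(nrow(detect_hbonds(sys, geom(3.1, 180))), 0L)
  # boundary cases are inclusive
  expect_equal(nrow(detect_hbonds(sys, geom(3.0, 135.001))), 1L)
})

test_that("subsampling keeps every stride-th frame from the first", {
  expect_equal(length(subsample(seq_len(45000), 10)), 4500)
  x <- seq_len(7)
  expect_identical(subsample(x, 1), x)
  expect_identical(subsample(x, 3), c(1L, 4L, 7L))
  # composition collapses to the product stride
  y <- seq_len(1200)
  expect_identical(subsample(subsample(y, 4), 3), subsample(y, 12))
})

test_that("pair counts include per-frame multiplicities", {
  sys <- build_toy_dimer(5, 4, "WT", seed = 1)
  # a frame geometry where two donor/acceptor channels bond simultaneously
  spec <- ensemble_spec(100,
    hbond_probs = data.frame(donor_res = c(1, 3), acceptor_res = c(1, 3),
                             p = c(1, 1)), noise = 0.02, seed = 9)
  ens <- make_interface_ensemble(sys, spec)
  counts <- hbond_pair_counts(ens, sys)
  expect_equal(sum(counts$count), 200)  # 2 bonds per frame over 100 frames
  totals <- hbond_counts_frames(ens, sys)
  expect_true(all(totals == 2L))
})

test_that("the ratio table reproduces every published row", {
  tab <- published_hbond_counts()
  expect_equal(nrow(tab), 30L)
  got <- hbr_table(tab$pair, tab$tlv, tab$tdelv, tab$tl, tab$tdel)
  digits_of <- function(s) {
    dot <- regexpr(".", s, fixed = TRUE)
    ifelse(dot < 0, 0L, nchar(s) - dot)
  }
  for (r in seq_len(30)) {
    d1 <- digits_of(tab$hbr1_printed[r])
    d2 <- digits_of(tab$hbr2_printed[r])
    expect_equal(round_half_down(got$hbr1[r], max(d1, 2)),
                 as.numeric(tab$hbr1_printed[r]), tolerance = 1e-9,
                 info = paste("HbR1", tab$pair[r]))
    expect_equal(round_half_down(got$hbr2[r], max(d2, 2)),
                 as.numeric(tab$hbr2_printed[r]), tolerance = 1e-9,
                 info = paste("HbR2", tab$pair[r]))
    expect_identical(got$flag[r], tab$flag_printed[r],
                     info = paste("flag", tab$pair[r]))
  }
})

test_that("ratio-table conventions cover degenerate counts", {
  t0 <- hbr_table("X-Y", 0, 0, 0, 0)
  expect_equal(t0$hbr1, 0)
  expect_equal(t0$hbr2, 0)
  expect_identical(t0$flag, "-")
  expect_error(hbr_table("X-Y", -1, 0, 0, 0), ">= 0")
  # display rounding: ties go toward zero, everything else to nearest
  expect_equal(round_half_down(0.375, 2), 0.37)
  expect_equal(round_half_down(2.846, 2), 2.85)
  expect_equal(round_half_down(0.93671, 3), 0.937)
})

test_that("count-difference significance is calibrated and powered", {
  set.seed(55)
  a <- rpois(800, 3)
  expect_equal(hbond_count_significance(a, a), 1)
  # a two-bond shift over 500-block-scale samples is overwhelmingly detected
  b <- rpois(5000, 3); c2 <- rpois(5000, 5)
  expect_lt(hbond_count_significance(b, c2), 1e-3)
  # null calibration: independent same-distribution draws give dispersed p
  ps <- replicate(100, hbond_count_significance(rpois(400, 3), rpois(400, 3)))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(hbond_count_significance(1:5, 1:5), "blocks")
})

test_that("superposition RMSD is invariant to rigid motion", {
  set.seed(12)
  x <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(rmsd(x, x), 0, tolerance = 1e-12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- x %*% R + matrix(c(3, -2, 8), 10, 3, byrow = TRUE)
  expect_lt(rmsd(moved, x), 1e-8)
  # symmetric in its arguments
  y <- x + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(rmsd(x, y), rmsd(y, x), tolerance = 1e-10)
})

test_that("RMSD agrees with an independent superposition implementation", {
  set.seed(14)
  x <- matrix(rnorm(24, sd = 3), 8, 3)
  y <- x + matrix(rnorm(24, sd = 0.8), 8, 3)
  fitted <- bio3d::fit.xyz(as.vector(t(y)), as.vector(t(x)),
                           fixed.inds = 1:24, mobile.inds = 1:24)
  oracle <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - y)^2)))
  expect_equal(rmsd(x, y), oracle, tolerance = 1e-6)
})

test_that("per-residue fluctuations follow the isotropic-jitter closed form", {
  nb <- 40
  set.seed(16)
  base <- matrix(rnorm(3 * nb, sd = 8), nb, 3)
  sys <- bead_system(base)
  sigma <- 0.25
  nf <- 8000
  coords <- array(NA_real_, c(nf, nb, 3))
  for (f in seq_len(nf)) coords[f, , ] <- base + matrix(rnorm(3 * nb, sd = sigma), nb, 3)
  traj <- trajectory_ensemble(coords, provenance = "synthetic")
  rf <- rmsf(traj, sys)
  # expected sigma * sqrt(3), slightly reduced by the 6 fitted rigid dof
  expect_close(mean(rf) / (sigma * sqrt(3)), sqrt(1 - 6 / (3 * nb)), 0.05)
  # a static trajectory has zero fluctuation
  still <- trajectory_ensemble(array(rep(base, each = 3), c(3, nb, 3)),
                               provenance = "synthetic")
  expect_close(rmsf(still, sys), 0, 1e-10)
  # rigid-body motion of whole frames does not register
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coords2 <- array(NA_real_, c(3, nb, 3))
  coords2[1, , ] <- base
  coords2[2, , ] <- base %*% R
  coords2[3, , ] <- base + matrix(c(5, 5, 5), nb, 3, byrow = TRUE)
  expect_close(rmsf(trajectory_ensemble(coords2, provenance = "synthetic"), sys),
               0, 1e-8)
})

test_that("native-contact fractions hit their reference limits", {
  sys <- build_toy_dimer(5, 4, "WT", seed = 1)
  nc <- native_contacts(sys)
  expect_gt(nrow(nc), 0)
  expect_equal(native_contact_fraction(sys$pos, sys, nc), 1)
  ref <- reference_configurations(sys, separation = 40)
  expect_equal(native_contact_fraction(ref$dissociated, sys, nc), 0)
  # break exactly half the reference pairs by construction
  half <- nc[seq_len(floor(nrow(nc) / 2)), , drop = FALSE]
  x <- sys$pos
  for (k in seq_len(nrow(half))) {
    b <- residue_beads(sys, half$res_j[k])
    x[b, 2] <- x[b, 2] + 40
  }
  moved <- nrow(half)
  expect_equal(native_contact_fraction(x, sys, nc),
               (nrow(nc) - moved) / nrow(nc))
  expect_error(native_contact_fraction(sys$pos, sys, nc[0, ]), "empty")
})

test_that("boosted and unbiased 2-D interface landscapes agree on shared bins", {
  # reaction coordinates: fraction of native contacts and the per-frame
  # hydrogen-bond count; a soft tether keeps the equilibrium comparison in
  # the reversibly-sampled region
  base <- build_toy_dimer(5, 4, "WT", seed = 31)
  sys <- pmf_restraints(base, k_receptor = 2, k_lateral = 1, k_axial = 0.05)
  nc <- native_contacts(sys)
  rc_of <- function(traj) {
    nf <- n_frames(traj)
    q <- numeric(nf); hb <- numeric(nf)
    for (f in seq_len(nf)) {
      x <- frame_coords(traj, f)
      q[f] <- native_contact_fraction(x, sys, nc)
      hb[f] <- nrow(detect_hbonds(sys, x))
    }
    cbind(q, hb)
  }
  g <- discard_equilibration(
    run_gamd(sys, integrator_config(300000, save_stride = 25L, seed = 32),
             sigma0 = 6))
  c0 <- discard_equilibration(
    run_cmd(sys, integrator_config(600000, save_stride = 25L, seed = 33)))
  edges <- list(seq(-0.1, 1.1, by = 0.2), seq(-0.5, 3.5, by = 1))
  lg <- reweight_cumulant2(rc_of(g), g$boost, edges, 310)
  lc <- reweight_exponential(rc_of(c0), c0$boost, edges, 310)
  ok <- !is.na(lg$F) & !is.na(lc$F) & lg$counts >= 200 & lc$counts >= 200
  expect_gte(sum(ok), 3)
  resid <- lg$F[ok] - lc$F[ok]
  expect_close(resid - mean(resid), 0, 0.5)
})
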