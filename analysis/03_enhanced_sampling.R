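#!/usr/bin/env Rscript

# Enhanced-sampling validation and landscapes.
# (a) Gaussian-accelerated sampling of an analytic 1-D double well,
#     reweighted by both estimators, against the exact profile.
# (b) 2-D free-energy landscapes of the wild-type and mutant dimers over
#     (native-contact fraction, hydrogen-bond count), from boosted runs
#     reweighted by the second-order cumulant expansion.
#
# Writes: results/gamd_double_well.tsv, results/landscape_{wt,mut}.tsv

library(deltabind)
dir.create("results", showWarnings = FALSE)

# --- (a) analytic double-well benchmark ---------------------------------
dw <- bead_system(matrix(c(1.5, 0, 0), 1, 3), mass = 12,
  external = list(list(type = "double_well", bead = 1, axis = 1, h = 3, a = 1.5),
                  list(type = "harmonic", bead = 1, k = c(0, 10, 10),
                       center = c(0, 0, 0))))
pre <- run_cmd(dw, integrator_config(50000, save_stride = 10L, seed = 11))
bp <- estimate_boost_params(pre$potential, sigma0 = 6)
print(bp)
traj <- run_gamd(dw, integrator_config(1500000, save_stride = 10L, seed = 12),
                 params = bp)
x <- traj$coords[, 1, 1]
edges <- seq(-2.6, 2.6, length.out = 40)
l2 <- reweight_cumulant2(x, traj$boost, edges, 310)
le <- reweight_exponential(x, traj$boost, edges, 310)
mids <- landscape_mids(l2)
u <- 3 * ((mids / 1.5)^2 - 1)^2
tab <- data.frame(x = mids, counts = l2$counts,
                  F_cumulant2 = l2$F, F_exponential = le$F,
                  F_analytic = u - min(u[!is.na(l2$F)]))
write.table(tab, "results/gamd_double_well.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ok <- !is.na(l2$F) & l2$counts >= 200
cat(sprintf("Double well: cumulant-2 max error %.3f kcal/mol over %d bins (>= 200 samples).\n",
            max(abs((l2$F - tab$F_analytic)[ok])), sum(ok)))

# --- (b) toy-dimer interface landscapes ---------------------------------
for (variant in c("WT", "MUT")) {
  sys <- pmf_restraints(build_toy_dimer(5, 4, variant, seed = 31),
                        k_receptor = 2, k_lateral = 1, k_axial = 0.05)
  nc <- native_contacts(sys)
  g <- discard_equilibration(
    run_gamd(sys, integrator_config(300000, save_stride = 25L, seed = 32),
             sigma0 = 6))
  nf <- n_frames(g)
  q <- numeric(nf); hb <- numeric(nf)
  for (f in seq_len(nf)) {
    xk <- frame_coords(g, f)
    q[f] <- native_contact_fraction(xk, sys, nc)
    hb[f] <- nrow(detect_hbonds(sys, xk))
  }
  ls <- reweight_cumulant2(cbind(q, hb),
                           g$boost, list(seq(-0.1, 1.1, by = 0.2),
                                         seq(-0.5, 4.5, by = 1)), 310)
  grid <- expand.grid(q_mid = landscape_mids(ls, 1), hb_mid = landscape_mids(ls, 2))
  grid$F <- as.vector(t(ls$F))
  grid$counts <- as.vector(t(ls$counts))
  fn <- sprintf("results/landscape_%s.tsv", tolower(variant))
  write.table(grid, fn, sep = "\t", quote = FALSE, row.names = FALSE)
  basin <- grid[which.min(grid$F), ]
  cat(sprintf("%s landscape minimum at Q = %.1f, %d H-bonds (%s).\n",
              variant, basin$q_mid, round(basin$hb_mid), fn))
  mq <- sum(grid$q_mid * exp(-grid$F / (kB_KCAL * 310)), na.rm = TRUE) /
    sum(exp(-grid$F / (kB_KCAL * 310)), na.rm = TRUE)
  mh <- sum(grid$hb_mid * exp(-grid$F / (kB_KCAL * 310)), na.rm = TRUE) /
    sum(exp(-grid$F / (kB_KCAL * 310)), na.rm = TRUE)
  cat(sprintf("  Boltzmann-average over the landscape: Q = %.2f, %.2f H-bonds.\n",
              mq, mh))
}
cat("Under the tether both variants stay in geometric contact; the\n")
cat("hydrogen-bond coordinate separates them (see the Boltzmann averages\n")
cat("above and the two landscape TSVs).\n")
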