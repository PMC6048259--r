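test_that("collective variables reproduce hand geometry", {
  m <- rep(1, 4)
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0), c(5, 0, 0))
  cv1 <- collective_variable("distance", T = 1, U = 2, W = 3, X = 4)
  expect_equal(eval_cv(p, cv1, m), 4.0)            # |(0.5,0,0) - (4.5,0,0)|
  cv2 <- collective_variable("angle", T = 1, U = 2, W = 3, X = 4)
  expect_equal(eval_cv(p, cv2, m), 180)            # collinear
  p2 <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(eval_cv(p2, collective_variable("angle", T = 1, U = 2,
                                               W = 3, X = 4), m), 90)
  pc <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  cv3 <- collective_variable("torsion", T = 1, U = 2, W = 3, X = 4)
  expect_equal(eval_cv(pc, cv3, m), 0)             # planar cis
  pt <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  expect_equal(abs(eval_cv(pt, cv3, m)), 180)      # planar trans
})

test_that("group centres are mass-weighted and degenerate geometry errors", {
  p <- rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0), c(12, 0, 0))
  cv <- collective_variable("distance", T = 1, U = 2, W = 3, X = 4)
  # masses (1, 2): CoM at 2; masses (3, 1): CoM at 10.5 -> distance 8.5
  expect_equal(eval_cv(p, cv, c(1, 2, 3, 1)), 8.5)
  expect_error(eval_cv(rbind(p[1:2, ], p[1:2, ]), cv, rep(1, 4)),
               "undefined CV")
})

test_that("R and engine CV evaluators agree on randomized coordinates", {
  set.seed(42)
  kinds <- c(distance = 0L, angle = 1L, torsion = 2L)
  for (kind in names(kinds)) for (rep in 1:5) {
    pos <- matrix(rnorm(36, sd = 3), 12, 3)
    mass <- runif(12, 1, 40)
    cv <- collective_variable(kind, T = 1:3, U = 4:6, W = 7:9, X = 10:12)
    vr <- eval_cv(pos, cv, mass)
    vc <- deltabind:::cpp_eval_cv(pos, mass, kinds[[kind]], 0:2, 3:5, 6:8, 9:11)
    expect_equal(vr, vc, tolerance = 1e-10)
  }
})

test_that("engine CV gradients match finite differences of the R evaluator", {
  set.seed(43)
  kinds <- c(distance = 0L, angle = 1L, torsion = 2L)
  for (kind in names(kinds)) {
    pos <- matrix(rnorm(36, sd = 3), 12, 3)
    mass <- runif(12, 1, 40)
    cv <- collective_variable(kind, T = 1:3, U = 4:6, W = 7:9, X = 10:12)
    g <- deltabind:::cpp_eval_cv_grad(pos, mass, kinds[[kind]],
                                      0:2, 3:5, 6:8, 9:11)
    fd <- matrix(0, 12, 3)
    h <- 1e-6
    for (i in 1:12) for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      d <- eval_cv(pp, cv, mass) - eval_cv(pm, cv, mass)
      if (kind == "torsion" && abs(d) > 180) d <- d - sign(d) * 360
      fd[i, k] <- d / (2 * h)
    }
    expect_close(g$grad, fd, 1e-5)
  }
})

test_that("anchor-group validation rejects empty or overlapping groups", {
  expect_error(collective_variable("distance", T = integer(), U = 2,
                                   W = 3, X = 4), "non-empty")
  expect_error(collective_variable("angle", T = 1, U = 1, W = 3, X = 4),
               "disjoint")
})

test_that("bias deposition is kernel-shaped and additive", {
  st <- bias_state(lo = 0, hi = 10, ncells = 50, tau = 5, halfwidth_cells = 4)
  st1 <- deposit_bias(st, 5, dt = 1)
  nodes <- bias_nodes(st1)
  expect_equal(nodes[which.max(st1$bias)], 5, tolerance = 0.11)
  hw <- st1$halfwidth
  expect_true(all(st1$bias[abs(nodes - 5) >= hw] == 0))
  u <- (nodes - 5) / hw
  expect_equal(st1$bias, (1 / 5) * ifelse(abs(u) < 1, (1 - u^2)^2, 0),
               tolerance = 1e-12)
  # two deposits at one point double the bump exactly
  st2 <- deposit_bias(st1, 5, dt = 1)
  expect_equal(st2$bias, 2 * st1$bias, tolerance = 1e-12)
  expect_error(deposit_bias(st, 11, dt = 1), "outside")
})

test_that("the converged bias is flat on a flat potential", {
  # free particle confined in y, z; reflective walls at the grid edges
  sys2 <- bead_system(rbind(c(-20, 0.4, 0), c(-20, -0.4, 0),
                            c(5, 0.4, 0), c(5, -0.4, 0)),
                      mass = c(40, 40, 12, 12),
    external = list(list(type = "harmonic", bead = 3, k = c(0, 10, 10),
                         center = c(0, 0.4, 0)),
                    list(type = "harmonic", bead = 4, k = c(0, 10, 10),
                         center = c(0, -0.4, 0))),
    frozen = c(TRUE, TRUE, FALSE, FALSE))
  sys2$bonds <- data.frame(i = 3L, j = 4L, k = 50, r0 = 0.8)
  ab <- run_abmd(sys2, harmonic_cv(), integrator_config(800000,
                 save_stride = 200L, seed = 8), lo = 20, hi = 30,
                 ncells = 50, tau = 10)
  b <- ab$bias$snapshots[[length(ab$bias$snapshots)]]
  expect_gt(min(b), 0)
  expect_lt((max(b) - min(b)) / mean(b), 0.10)
})

test_that("zero deposition reduces adaptive-bias dynamics to unbiased dynamics", {
  sys <- harmonic_cv_system()
  cfg <- integrator_config(2000, save_stride = 20L, seed = 15)
  ab <- run_abmd(sys, harmonic_cv(), cfg, lo = 10, hi = 30, ncells = 50,
                 tau = Inf)
  cmd <- run_cmd(sys, cfg)
  expect_identical(ab$traj$coords, cmd$coords)
  expect_true(all(ab$bias$bias == 0))
  # determinism under a fixed seed
  ab2 <- run_abmd(sys, harmonic_cv(), cfg, lo = 10, hi = 30, ncells = 50,
                  tau = Inf)
  expect_identical(ab$traj$coords, ab2$traj$coords)
})

test_that("flooding a harmonic CV recovers the analytic PMF", {
  sys <- harmonic_cv_system(kx = 0.25)
  ab <- run_abmd(sys, harmonic_cv(), integrator_config(2500000,
                 save_stride = 500L, seed = 2), lo = 17, hi = 23,
                 ncells = 75, tau = 10)
  pmf <- pmf_from_bias(ab$bias, 310)
  mids <- landscape_mids(pmf)
  fa <- 0.25 * (mids - 20)^2
  expect_close(pmf$F, fa - min(fa), 0.3)
})

test_that("flat and square-well PMFs give closed-form binding energies", {
  mk_pmf <- function(f, lo = 0, hi = 10) {
    structure(list(edges = list(seq(lo, hi, length.out = length(f) + 1)),
                   p = NULL, F = f, M = length(f), temperature = 310,
                   estimator = "manual"),
              class = "free_energy_landscape")
  }
  # flat landscape, equal windows: dG = 0 by symmetry
  expect_equal(binding_dg(mk_pmf(rep(0, 100)), c(0, 5), c(5, 10)), 0,
               tolerance = 1e-12)
  # square well of depth 5 in the bound window: dG = -5
  f <- c(rep(0, 50), rep(5, 50))
  expect_equal(binding_dg(mk_pmf(f), c(0, 5), c(5, 10)), -5,
               tolerance = 1e-9)
  expect_error(binding_dg(mk_pmf(rep(0, 10)), c(0, 5), c(4, 10)), "disjoint")
  expect_error(binding_dg(mk_pmf(rep(0, 10)), c(-5, -1), c(5, 10)),
               "empty window")
})

test_that("ddG arithmetic and the Kd transform reproduce published values", {
  # differences of the printed per-variant means
  expect_equal(delta_delta_g(-9.45, -14.12)$ddg, 4.67, tolerance = 1e-12)
  expect_equal(delta_delta_g(-30.87, -36.10)$ddg, 5.23, tolerance = 1e-12)
  expect_equal(delta_delta_g(-7.3, -7.3)$ddg, 0)
  expect_equal(delta_delta_g(-9.45, -14.12, 0.57, 1.82)$se,
               sqrt(0.57^2 + 1.82^2))
  # the implied fold changes in dissociation constant at 310 K
  expect_close(kd_ratio(4.67, 310) / 1961.64, 1, 0.005)
  expect_close(kd_ratio(5.23, 310) / 4869.14, 1, 0.005)
  expect_equal(kd_ratio(0, 250), 1)
  # invariance to a common shift of both free energies
  d1 <- delta_delta_g(-9.45, -14.12)$ddg
  d2 <- delta_delta_g(-9.45 + 3.3, -14.12 + 3.3)$ddg
  expect_equal(kd_ratio(d1), kd_ratio(d2))
})

test_that("the one-sided ddG significance test behaves at its limits", {
  expect_equal(significance_ddg(c(0, 0, 0)), 1)
  # replicates {4, 5, 6}: closed-form one-sided t-test
  x <- c(4, 5, 6)
  p_hand <- pt(mean(x) / (sd(x) / sqrt(3)), df = 2, lower.tail = FALSE)
  expect_equal(significance_ddg(x), p_hand, tolerance = 1e-12)
  expect_lt(significance_ddg(x), 0.05)
  set.seed(99)
  expect_lt(significance_ddg(c(4, 5, 6), method = "permutation"), 0.2)
  # null calibration: p is roughly uniform for centred noise
  set.seed(100)
  ps <- replicate(200, significance_ddg(rnorm(6)))
  expect_gt(mean(ps < 0.1), 0.02)
  expect_lt(mean(ps < 0.1), 0.25)
})

test_that("window-averaged binding estimates expose replicate spread", {
  sys <- pmf_restraints(build_toy_dimer(5, 4, "WT", seed = 101))
  cv1 <- dimer_cv1(sys)
  r0 <- eval_cv(sys$pos, cv1, sys$mass)
  lo <- max(2, r0 - 3); hi <- r0 + 15
  ab <- run_abmd(sys, cv1, integrator_config(200000, save_stride = 200L,
                 seed = 101), lo = lo, hi = hi, ncells = 80, tau = 5)
  est <- binding_dg_windows(ab$bias, c(lo, r0 + 3), c(r0 + 8, hi))
  expect_lt(est$dg, 0)           # wild type binds
  expect_gte(est$se, 0)
  expect_gte(length(est$windows), 5)
})
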