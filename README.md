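# deltabind

A desk-scale pipeline for quantifying how a single interface mutation
weakens a receptor–activator complex, built for structural-bioinformatics
work on the TorsinA–LULL1 system: the dystonia-linked deletion of one
glutamate weakens TorsinA's binding to its activator LULL1, and showing
that computationally takes a specific battery of simulation methodology.
`deltabind` implements that battery as tested R (plus compiled) code and
exercises it end to end on coarse-grained wild-type/mutant toy dimers with
known ground truth, so every estimator is validated before anyone points
it at real trajectories. It is aimed at computational structural
biologists who want the analysis layer — not an all-atom MD engine.

## What is implemented

* **Toy systems and ensembles** — bead-model receptor–ligand dimers whose
  `MUT` variant differs from `WT` by one declared interface parameter set;
  synthetic ensembles with prescribed contact and hydrogen-bond
  probabilities; fixed-width PDB and a lossless binary trajectory
  container.
* **Langevin dynamics** — BAOAB integrator (2 fs step, 2 ps⁻¹ friction,
  310 K), compiled in C++, bitwise-reproducible under `set.seed()`.
* **Gaussian-accelerated sampling** — boost
  `ΔV = ½k(E − V)²` below threshold `E`, with
  `k = k₀/(V_max − V_min)`,
  `k₀ = min(1, (σ₀/σ_V)·(V_max − V_min)/(V_max − V̄))`, and reweighting to
  the canonical ensemble by per-bin exponential averages or the
  second-order cumulant expansion; free-energy landscapes
  `F = −k_B T ln p`.
* **Adaptive-bias (flooding) free energies** — distance/angle/torsion
  collective variables over bead groups, biweight-kernel deposition with
  reflective edges, PMF = negated window-averaged bias, binding
  `ΔG = −k_B T ln(∫_bound e^{−F/k_BT} / ∫_unbound e^{−F/k_BT})`, the
  mutant penalty `ΔΔG = ΔG_MUT − ΔG_WT`, and the dissociation-constant
  fold change `K_d^MUT/K_d^WT = e^{ΔΔG/k_BT}`.
* **End-state energetics** — single-trajectory MM-PBSA-style
  `ΔG ≈ ΔE_MM + ΔG_sol − TΔS` with a generalized-Born-style polar
  surrogate, Shrake–Rupley surface areas (γ = 0.0072 kcal/mol/Å²), an
  explicit not-computed entropy term, and exact per-residue decomposition.
* **Fingerprints** — residue centre-of-mass contact maps (6 Å inclusive),
  geometric hydrogen-bond detection (donor–acceptor ≤ 3.0 Å and
  acceptor–H–donor angle ≥ 135°), mutant/wild-type hydrogen-bond ratio
  tables (HbR1 clamped / HbR2 free, with the published 30-pair count table
  shipped as plain text), RMSD/RMSF, native-contact fractions,
  block-based Mann–Whitney significance.
* **Workflow** — the four-system, three-replicate comparative design
  (wild type and mutant, each free or restrained by a nanobody-like
  "clamp"), with difference-map attenuation summaries and deterministic
  reports.

## Worked example

```r
library(deltabind)

## 1. the ratio statistic on the published hydrogen-bond counts
tab <- published_hbond_counts()
rt <- hbr_table(tab$pair, tab$tlv, tab$tdelv, tab$tl, tab$tdel)
head(rt[, c("pair", "hbr1", "hbr2", "flag")], 3)
#>        pair     hbr1     hbr2 flag
#> 1 D277-S279 2.846154 0.000000  Yes
#> 2 D262-W489 2.035714 0.375000  Yes
#> 3 E427-K266 2.000000 1.089286  Yes

## 2. the dissociation-constant transform of a binding penalty
ddg <- delta_delta_g(dg_mut = -9.45, dg_wt = -14.12)
ddg$ddg
#> [1] 4.67
kd_ratio(ddg$ddg, temperature = 310)
#> [1] 1960.148

## 3. a toy comparative run: wild type vs mutant, one replicate
wt <- build_toy_dimer(5, 4, "WT", seed = 101)
mut <- build_toy_dimer(5, 4, "MUT", seed = 101)
cfg <- integrator_config(20000, save_stride = 20, seed = 101)
traj_wt <- discard_equilibration(run_cmd(wt, cfg))
traj_mut <- discard_equilibration(run_cmd(mut, cfg))
c(WT = mean(hbond_counts_frames(traj_wt, wt)),
  MUT = mean(hbond_counts_frames(traj_mut, mut)))
#>        WT       MUT
#> 0.4728080 0.4284129
binding_dg_frames(traj_mut, mut)$dG_binding -
  binding_dg_frames(traj_wt, wt)$dG_binding
#> [1] 6.889676
```

Reading the output: a flag of `Yes` marks residue pairs whose mutant
hydrogen bonding is inflated by the crystallization clamp (HbR1 > HbR2);
a ΔΔG of 4.67 kcal/mol corresponds to a roughly 1960-fold rise in the
dissociation constant at 310 K; and on the toy dimer one replicate already
shows the mutant forming fewer interface hydrogen bonds and binding about
7 kcal/mol more weakly by the end-state route (toy-scale numbers — the
magnitudes are properties of the bead model, the signs are the science).

## The analysis workflow

`analysis/` holds numbered drivers that run the study end to end and write
their tables under `results/`:

1. `01_build_systems.R` — build the four variants, record the mutation's
   declared parameter diff and reference energies.
2. `02_sample_dynamics.R` — unbiased production runs, trajectory files and
   per-run summaries.
3. `03_enhanced_sampling.R` — the analytic double-well reweighting
   benchmark and 2-D (native contacts × hydrogen bonds) landscapes.
4. `04_binding_energy.R` — ΔG by flooding PMF and by end-state averaging,
   ΔΔG, K_d ratios and replicate significance.
5. `05_fingerprints.R` — contact/difference maps, RMSF, attenuation norms
   and hydrogen-bond ratio tables.

Run them in order with `Rscript analysis/01_build_systems.R` etc.; each
prints what it found.

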