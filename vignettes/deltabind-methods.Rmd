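---
title: "Methods: toy-scale enhanced sampling and binding energetics for an interface mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toy-scale enhanced sampling and binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

A single-residue deletion in an AAA+ ATPase of the nuclear envelope weakens
the enzyme's binding to its membrane activator, and that loss of binding is
the molecular lesion behind a hereditary movement disorder. Establishing
*how much* binding is lost, and *which* interface interactions carry the
loss, calls for a specific battery of simulation methodology: unbiased
canonical sampling, Gaussian-accelerated boosting with statistical
reweighting, adaptive-bias free-energy calculations along collective
variables, end-state (MM-PBSA-style) energetics with per-residue
decomposition, and interaction fingerprints — residue contact maps,
geometric hydrogen-bond detection, and mutant/wild-type hydrogen-bond count
ratios.

`deltabind` implements that battery as tested, reusable code and exercises
it end to end on coarse-grained *toy* receptor–ligand dimers whose
"wild-type" and "mutant" variants differ by one declared set of interface
parameters. The toy complexes are deliberately not models of the real
proteins: they are the smallest systems on which every downstream statistic
(centre-of-mass contacts, donor–hydrogen–acceptor angles, boost
reweighting, flooding PMFs, per-residue energy splits) is exercised with
known ground truth. The published per-residue-pair hydrogen-bond counts of
the four real systems are carried as plain-text reference *inputs* for the
ratio statistic; nothing at atomistic scale is recomputed here.

## The toy model

A `toy_system` has two chains: receptor (chain A) and ligand (chain B),
built residue-on-residue across a 6.8 Å backbone gap. Each residue carries
a backbone bead and an interface-facing side-chain bead; alternating
receptor residues are hydrogen-bond donors with an explicit hydrogen bead,
and alternating ligand residues are acceptors. The force field is:

* harmonic bonds, $E = \tfrac12 k (r - r_0)^2$;
* a Lennard-Jones-style pair term $4\varepsilon[(\sigma/r)^{12} -
  (\sigma/r)^6]$ with $\sigma$ from bead-radius sums (1–2 and 1–3 bonded
  neighbours excluded), deepened to $\varepsilon = 4$ kcal/mol with the
  minimum at the 2.8 Å side-chain gap for the designated interface pairs;
* screened Coulomb electrostatics $332.0637\, q_i q_j e^{-r/\lambda} /
  (\epsilon_r r)$ with an effective dielectric of 10 and an 8 Å screening
  length. Donor side chains carry a $-0.65/+0.65$ dipole (side chain /
  hydrogen) and acceptors carry $-0.65$ balanced on their backbone, so
  hydrogens orient electrostatically toward approaching acceptors the way
  polar hydrogens do. Hydrogen beads additionally carry a small repulsive
  core so they cannot collapse onto acceptors.

These defaults were chosen once, to make the wild-type bound state a clear
energy minimum (roughly 20 kcal/mol below dissociation at the reference
configurations) that still shows reversible thermal excursions at 310 K,
and to give hydrogen-bond geometries that pass and fail the detection
criteria for physical reasons rather than by construction.

The **mutation** is parameter deletion, not topology surgery: `MUT` zeroes
the central interface residue's side-chain and hydrogen charges, resets its
interface well to background depth, and halves its two sequence
neighbours' interface wells. `variant_parameter_diff()` enumerates every
bead and pair parameter and returns exactly this declared set, which the
test suite asserts. Both variants share identical coordinates at equal
seed, mirroring a comparison of two fixed sequences.

The **synthetic-ensemble generator** (`make_interface_ensemble`) emulates
only the statistical structure of trajectory ensembles: per-residue-pair
contact probabilities and per-site hydrogen-bond probabilities realised by
explicit geometric placement (contacts at 3–5.5 Å vs 6.8–12 Å on the
centre-of-mass criterion; bonds collinear at 2.6–2.95 Å vs distance- or
angle-violating placements), plus isotropic jitter. It does *not* emulate
dynamics: frames are independent, energies are zero, and bonded geometry
may be distorted. Fingerprint tests built on it therefore validate the
*measurement* operators, never the sampling; conclusions about real
proteins would need real trajectories.

## Dynamics

Canonical sampling uses the BAOAB splitting of Langevin dynamics with a
collision frequency of 2 ps$^{-1}$ and a 310 K default temperature (the
only dynamics constants the original all-atom protocol pins down), a 2 fs
step, and no barostat or periodicity — constant-volume vacuum at toy scale.
Velocities are Maxwell–Boltzmann at the target temperature; all randomness
flows through R's RNG, so equal seeds give bitwise-identical trajectories.
The compiled engine and a pure-R reference step (`langevin_step`) consume
Gaussian variates in the same order and are cross-checked to 10⁻¹⁰. The
first 10% of frames are discarded before analysis by default
(`discard_equilibration`); the discard rule is a package choice surfaced as
an argument.

## Gaussian-accelerated sampling and reweighting

When the instantaneous potential $V$ lies below a threshold $E$, the boost
$\Delta V = \tfrac12 k (E - V)^2$ is added and forces are scaled by
$1 - k(E - V)$. The parameters come from the statistics of an unbiased
stage: $k = k_0/(V_{\max} - V_{\min})$ with
$k_0 = \min\!\big(1, \tfrac{\sigma_0}{\sigma_V}\,
\tfrac{V_{\max}-V_{\min}}{V_{\max}-\bar V}\big)$, which enforces the three
standard criteria — order preservation between any two potentials,
contraction of their difference, and a boost standard deviation capped at
$\sigma_0$ so second-order reweighting stays valid. $E$ defaults to the
conservative lower bound $V_{\max}$; the upper-bound variant
$V_{\min} + 1/k$ is an option. $\sigma_0$ defaults to 6 kcal/mol (a
package choice, surfaced as an argument). Parameters are estimated once
from a pre-stage of 20% of the production length; re-estimation is
disabled during production.

Reweighting divides frames into reaction-coordinate bins $j$ and corrects
the biased probabilities $p'_j$ by per-bin Boltzmann factors of the boost:
the full exponential estimator uses $\langle e^{\Delta V / k_B T}\rangle_j$
and the default second-order cumulant estimator replaces it by
$\exp(\beta\,\overline{\Delta V}_j + \beta^2\,\mathrm{var}_j(\Delta V)/2)$,
exact in the Gaussian limit and far less noise-sensitive. Both are
provided because the methodology is described ambiguously in the
literature this follows; they agree within 1% per bin when per-bin boosts
are Gaussian, which the suite checks. Empty bins are excluded from the
normalisation sum and carry `NA` free energy — probabilities are never
extrapolated; single-sample bins are flagged low-confidence. Free energies
are $F_j = -k_B T \ln p_j$ with $k_B = 1.9872\times10^{-3}$ kcal/(mol K),
shifted to a zero minimum.

On a 1-D double well ($h = 3$ kcal/mol barrier, minima at ±1.5 Å) boosted
sampling plus either estimator recovers the analytic profile within 0.5
kcal/mol on every bin holding at least 200 samples; the acceptance suite
runs this at 1.5 × 10⁶ steps, a few seconds of compute.

## Adaptive-bias free energies

Collective variables are defined over four bead anchor groups T, U, W, X:
the distance between CoM(T∪U) and CoM(W∪X); the angle at the centre of U
formed with the centres of T and CoM(W∪X); and the torsion over the four
group centres (degrees, cis = 0, range (−180°, 180°]). Gradients are
propagated to beads by mass weighting and are verified against finite
differences of an independent R evaluator.

Flooding deposits a biweight (quartic) kernel of half-width 4 grid cells
and weight $\Delta t/\tau$ at the current CV value each step; kernel mass
clipped by a grid edge is mirrored back inside, consistent with the
harmonic walls that confine the CV to the grid, so edge nodes fill at the
interior rate. The PMF estimate is the *negated bias averaged over the
final tenth of the run* — once the bias is full it fluctuates around the
negated free energy at the single-deposit scale, and window averaging
removes most of that noise. Convergence is declared when the aligned
estimates of the last two 10%-run windows differ by under 0.2 kcal/mol on
nodes both touched; results are flagged, never silently accepted. On a
harmonic CV the negated converged bias matches the analytic PMF within 0.3
kcal/mol.

Binding free energies integrate the 1-D PMF:
$\Delta G = -k_B T \ln \big(\int_{\text{bound}} e^{-F/k_BT} /
\int_{\text{unbound}} e^{-F/k_BT}\big)$, with bound = [grid start,
reference + 3 Å] and unbound = [reference + 8 Å, grid end] from the toy
geometry, and no standard-state volume correction (none is applied in the
protocol this mirrors; the windows are arguments). Unbinding runs use a
funnel-style setup (`pmf_restraints`): the receptor backbone is held as
the laboratory frame and the ligand backbone is confined in the two axes
orthogonal to the binding axis, which keeps the pathway one-dimensional
and avoids rebinding hysteresis in misaligned poses. Replicate ΔG
estimates are block-averaged over flooding windows
(`binding_dg_windows`); the cross-replicate spread is the reported
uncertainty, mirroring a three-replicate design. ΔΔG is a simple
difference with quadrature-propagated uncertainty, the implied
dissociation-constant fold change is $e^{\Delta\Delta G/k_BT}$, and the
one-sided significance of ΔΔG > 0 across replicates is a one-sample t-test
by default with a sign-flip permutation alternative (the original analysis
names a significance level but not a test).

## End-state energetics

The single-trajectory approximation evaluates complex, receptor and ligand
on the same frames. Per frame,
$\Delta G_{\text{bind}} = \Delta E_{MM} + \Delta G_{\text{sol}} - T\Delta S$
with $\Delta E_{MM} = \Delta E_{\text{int}} + \Delta E_{\text{elec}} +
\Delta E_{\text{vdw}}$ and $\Delta G_{\text{sol}} = \Delta G_{\text{pol}} +
\Delta G_{SA}$. Bonded terms cancel identically under a shared trajectory,
so $\Delta E_{\text{int}} \equiv 0$ is asserted rather than assumed. Gas
phase means unscreened vacuum Coulomb (332.0637 $q_iq_j/r$) plus the pair
term. $-T\Delta S$ is carried as an explicit *not computed* zero — no
normal-mode analysis is attempted, matching common end-state practice when
only enthalpy-like differences are compared.

The polar term is a generalized-Born-style pairwise surrogate, not a grid
Poisson–Boltzmann solver: effective radii are the bead radii,
$f_{GB} = \sqrt{r^2 + a_ia_j e^{-r^2/4a_ia_j}}$, and the solvent factor
$(1/\epsilon_{\text{in}} - e^{-\kappa f_{GB}}/\epsilon_{\text{out}})$ is
Debye-screened at the configured ionic strength (default 0.150 M; the
protocol this follows prints "0.150 nM", which would be physically
meaningless screening and is read as a molar typo — both spellings of the
number are accepted as molar). The surrogate reduces exactly to the Born
self-energy for an isolated bead and to the sum of self-energies at
infinite separation, which is the role the polar term plays at toy scale;
a finite-difference solver would add grid machinery without changing any
tested property. The nonpolar term is $\gamma \times$ SASA with
$\gamma = 0.0072$ kcal/mol/Å², on Shrake–Rupley areas computed with a
deterministic spiral point set (960 points per sphere, 1.4 Å probe) so
results are reproducible to the quadrature, not to a sampling seed.

Per-residue decomposition splits every cross-chain pair energy half-and-half
between the partner residues and assigns buried area to the residue owning
each bead; residue sums reproduce the totals to 10⁻⁶ kcal/mol by
construction, and the suite asserts it.

## Interaction fingerprints

* Contacts: two residues interact in a frame when their mass-weighted
  centres of mass are within **6 Å inclusive**; frequencies are fractions
  of frames. Difference maps are mutant minus wild type, so weakened
  interactions are negative.
* Hydrogen bonds: recorded between chains when a donor heavy atom is
  within **3.0 Å inclusive** of an acceptor heavy atom *and* the
  acceptor–hydrogen–donor angle is **≥ 135°**. The distance is
  heavy-atom-to-heavy-atom — the stated 3.0 Å magnitude matches that
  convention, not the H–acceptor one. Several bonds may be recorded per
  residue pair per frame and counts keep multiplicity.
* Subsampling keeps every stride-th frame starting from the first
  (45,000 frames at stride 10 give exactly 4,500).
* The ratio table: for each residue pair, HbR1 is the mutant/wild-type
  count ratio in the clamped (nanobody-present) condition and HbR2 the
  same ratio free of the clamp, with a zero denominator giving a ratio of
  0. The flag is "Yes" when HbR1 > HbR2 on the unrounded values (the
  clamp inflates the mutant's hydrogen bonding), "No" otherwise, and "−"
  when the mutant count is zero in both conditions. Stored ratios are
  unrounded; display rounding is **round-half-toward-zero**
  (`round_half_down`), the convention that reproduces every printed ratio
  cell of the published table, including its single exact-half case.
* Count-difference significance: per-frame totals averaged over
  non-overlapping 10-frame blocks (to blunt autocorrelation), compared by
  a two-sided Mann–Whitney U test.
* RMSD is Kabsch superposition then root-mean-square deviation
  (cross-checked against an independent implementation); RMSF superposes
  frames on the mean structure and reports per-residue centre-of-mass
  fluctuation. The fraction of native contacts Q counts reference-frame
  contact pairs still present.

## The comparative workflow

`run_experiment` mirrors the four-system, three-replicate design: wild
type and mutant, each free or "clamped". The crystallization nanobody is
modelled as weak harmonic positional restraints (default 1 kcal/mol/Å²) on
the interface side chains of both chains — an *analogy* capturing the
mechanistic claim (an external body rigidifies the interface and masks
mutant/wild-type differences), not a third molecule. Per variant it
produces binding estimates by both routes, contact maps, hydrogen-bond
tables and RMSF; across variants, ΔΔG with its dissociation-constant
transform, difference maps with L1-norm attenuation summaries, and the
ratio table. Stage failures land in an explicit manifest rather than
aborting the bundle. Reports render deterministically.

Problem sizes are the package's own defaults: 5 + 4 residues (about 21
beads), 20,000-step production runs saved every 20 steps, 400,000-step
flooding runs, three replicates — enough for every qualitative contrast to
be stable across seeds while the full comparative experiment completes in
about a minute. The test suite runs the whole design and asserts the
triad: ΔΔG > 0 by both routes in every replicate, fewer mutant interface
hydrogen bonds in every replicate, and a smaller clamped difference-map
norm than free.

## Numerical choices and degenerate inputs

Boundary behaviour is fixed and tested: both geometric cutoffs are
inclusive; subsampling starts at the first frame; bias deposits outside
the grid are rejected while in-range deposits near edges are mirrored;
empty landscape bins are excluded from normalisation, never interpolated;
zero-denominator ratios are 0 by table convention; a zero-stiffness clamp
is the identity; coincident CV group centres, overlapping beads,
zero-variance boost statistics, truncated PDB records and malformed
trajectory headers all raise typed errors naming the offence. Trajectory
files are a self-describing little-endian binary container whose header
implies the exact byte count, so shape mismatches are detected before any
array is built.

## Limitations

The toy dimers share no geometry, energetics or time scale with the real
proteins; all quantitative outputs at toy scale (well depths, ΔΔG
magnitudes, bond counts) are properties of the declared model only. What
transfers is the *methodology*: the estimators and statistics are the same
operations one would run on real trajectories, and the suite demonstrates
they recover known answers where ground truth exists — analytic profiles,
prescribed probabilities, printed worked examples, and sign/ordering
contrasts built into the variants. The entropy term of the end-state route
is not computed; the polar solvation term is a declared surrogate; flooding
convergence is diagnosed, not guaranteed; and single-CV PMFs depend on the
funnel restraints that make the unbinding coordinate well-defined.
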