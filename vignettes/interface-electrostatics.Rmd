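---
title: "Methods: electrostatic interface statistics with epistat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrostatic interface statistics with epistat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistat)
```

# Scope

`epistat` analyses electrostatic complementarity at a protein-protein
interface, with an antigen-antibody complex as the motivating system. It
covers four layers of evidence that are normally produced by separate
tools: crystal-contact geometry, MD-trajectory stability metrics,
per-residue interaction-energy decomposition, and SPR-derived kinetics and
thermodynamics. A synthetic-data module generates every input with exact
ground truth, so the whole pipeline is testable on a laptop without
instrument data or cluster-scale simulations.

# Crystal-contact geometry

Charged side chains are reduced to conventional marker atoms: Lys NZ,
Arg CZ, Asp CG, Glu CD, with charged groups \{NZ\}, \{NE, NH1, NH2\},
\{OD1, OD2\} and \{OE1, OE2\} respectively. Two distance conventions are
exposed and always recorded per output row:

* **representative distance** — Euclidean distance between the two marker
  atoms, the convention used for per-frame trajectory series;
* **group minimum** — minimum over all (basic-group, acidic-group) atom
  pairs, the convention behind prose-style contact distances such as
  "the carboxylate is 2.8 Å from the amine".

Both exist because published interface descriptions mix the two: figure
captions typically fix marker atoms, while running text quotes group-atom
distances. Reporting a single convention silently mislabels one of them.

`findSaltBridges()` scans all inter-chain (basic, acidic) residue pairs
and keeps those with group-minimum distance at or below a cutoff
(default 4.0 Å, the common salt-bridge criterion). The contact threshold
stored with each hit is the measured representative-atom distance, because
occupancy analyses conventionally use the crystal distance of the same
contact as the per-contact threshold; the generic 4.0 Å preset
(`occupancyThresholdPreset()`) is used for contacts that do not exist in
the crystal (for example, contacts created by mutation).

PDB reading is delegated to `bio3d::read.pdb`, wrapped so that alternate
locations are resolved by highest occupancy (ties: first record),
insertion codes are preserved, and HETATM/waters are ignored in geometry.
Coordinates are assumed imaged and whole: no minimum-image correction is
applied anywhere, but trajectory construction warns loudly if any atom
jumps more than 20 Å between frames, the signature of an unwrapped
periodic box.

# Trajectory metrics

**Superposition.** `kabschSuperpose()` computes the least-squares rigid
fit via SVD of the cross-covariance matrix, with the reflection excluded
by sign-correcting the smallest singular vector. Weights are optional and
unused by the standard Cα workflows. Configurations of rank below 2
(fewer than 3 points, or collinear) raise an error rather than returning a
non-unique answer. The test suite cross-checks the minimized RMSD against
an independent quaternion-method (Horn) implementation to 1e-9 Å.

**Cα selections.** `caMask()` selects Cα atoms per chain with the first
and last five residues excluded by default, since flexible termini inflate
RMSD without carrying information about the interface.

**L-RMSD.** The ligand-RMSD of a frame is the RMSD of the antibody Cα
atoms after superposing the frame onto the reference using the antigen Cα
atoms only, with no second fit. It isolates changes in the *relative
orientation* of the two partners: whole-complex tumbling cancels exactly,
a uniform displacement of the antibody shows up at its exact magnitude,
and progressive inter-chain drift produces a monotonically growing series
— the signature used to call a complex dissociating in simulation.

**Occupancy.** A contact's occupancy is the fraction of post-burn-in
frames whose measurement-atom distance is at or below the contact
threshold. Burn-in defaults to the first 20% of the trajectory (20 ns of
a 100 ns run), overridable in absolute ns; equilibration transients
otherwise bias occupancies toward the starting structure. Every saved
frame after burn-in enters the denominator — no subsampling.

**Replica statistics.** `replicaSummary()` returns the mean, the sample
standard deviation (n−1) and the standard error over replicas. Occupancy
tables conventionally report mean ± sd; energy tables report mean ± se.
Both are always stored. A single replica yields NA spread with an explicit
flag, never a silent zero.

# Interaction energies

The per-residue interaction energy against the partner chains is the
time-average, over post-burn-in frames, of

$$E = \sum_{i \in \text{residue}} \sum_{j \in \text{partner}}
      \left[ \frac{f\, q_i q_j}{\varepsilon_r r_{ij}}
      + 4\epsilon_{ij}\left(\frac{\sigma_{ij}^{12}}{r_{ij}^{12}}
      - \frac{\sigma_{ij}^{6}}{r_{ij}^{6}}\right)\right]
      \quad (r_{ij} \le r_c)$$

with $f = 1389.35458$ kJ Å mol⁻¹ e⁻², Lorentz–Berthelot combining
rules (pair-specific overrides take precedence when supplied), relative
dielectric 1, and plain truncation at $r_c = 12$ Å. Units are kJ/mol
throughout, with `kJToKcal()` for conversion. Three deliberate
simplifications, all documented as systematic differences from
MD-engine rerun energies:

* no switching function at the cutoff;
* no reciprocal-space (PME) long-range term — it cannot be attributed to
  individual residue pairs, which is the whole point of a per-residue
  decomposition;
* no intramolecular exclusions, because only inter-chain pairs are summed
  (asserted, not configurable).

Force-field parameters are always read from a per-atom file
(`readNonbondedParams()`); the package hard-codes no force field, and an
atom without parameters aborts the calculation with the missing atoms
listed.

# SPR kinetics and thermodynamics

**Model.** Sensorgrams follow the 1:1 Langmuir binding model:
association $R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})$ with
$R_{eq} = R_{max} k_{on} C / (k_{on} C + k_{off})$, then dissociation
$R(t) = R_0 e^{-k_{off}(t - t_0)}$. Mass transport, baseline drift and
bulk refractive-index steps are deliberately omitted; residual sums of
squares are reported so model violations remain visible.

**Global fit.** `fitKineticsGlobal()` fits one (kon, koff, Rmax) triple
across all concentrations by Levenberg–Marquardt least squares
(`minpack.lm`), parameterized in log space for positivity and
conditioning, multi-started from 8 log-spaced initializations, with
convergence tolerance 1e-10 on the relative RSS change. KD = koff/kon is
an identity of the result object, never refitted. Parameter standard
deviations come from the log-space covariance via the delta method. A
single-concentration panel attaches an identifiability warning instead of
failing.

**Van't Hoff analysis.** From $\ln K_D = \Delta H / RT - \Delta S / R$
($R = 8.314462618$ J mol⁻¹ K⁻¹), a linear regression of ln KD on 1/T
gives ΔH from the slope and ΔS from the intercept. The regression is
unweighted by default (weights optional). ΔG = ΔH − TΔS is propagated
with the full (ΔH, ΔS) covariance by default —
$\mathrm{var}(\Delta G) = \mathrm{var}(\Delta H) + T^2\mathrm{var}(\Delta S)
- 2T\,\mathrm{cov}$ — because slope and intercept of the same regression
are strongly anticorrelated and ignoring the cross term badly overstates
the ΔG uncertainty; the no-covariance variant is exposed for comparison.
Temperatures are Kelvin internally; file interfaces accept °C.

**DSC.** `tmApp()` returns the temperature of maximum heat capacity after
optional moving-average smoothing, refined by a three-point parabola
around the grid maximum. Thermograms with more than one prominent local
maximum (rising above 25% of the scan range over the baseline) are
flagged multi-peak rather than rejected, since broad or shouldered
transitions are real and informative. Flat or boundary-maximal scans are
errors.

# Synthetic data and what passing tests mean

Generators are pure functions of their seed and return machine-readable
ground truth alongside the data.

* **Toy complexes** place idealized residues (charged-group atoms with
  correct internal geometry plus a minimal N/CA/C backbone) so that each
  planted pair's representative distance is exact and all non-planted
  charged pairs are ≥ 8 Å apart. Chains get a gentle helical wobble so
  Cα traces are never collinear. The geometry is deliberately
  non-physical: it validates bookkeeping and measurement conventions, not
  stereochemistry.
* **The synthetic interface reference** (`makeReferenceInterface()`)
  emulates the crystal geometry of the model antigen-antibody interface:
  the eight key charged residues are placed so the published contact
  distances (3.6, 3.5, 4.3, 8.0 Å marker-atom; 2.9, 2.8, 3.7, 4.3 Å
  group-minimum) hold by construction, verified internally to 1e-9 Å. It
  is a labelled synthetic stand-in, not the deposited structure; analyses
  of the real crystal should parse the deposited PDB file instead.
* **Trajectories** are reference + iid Gaussian jitter. Contact targets
  use an explicit Bernoulli(p) schedule that places the measurement atoms
  inside or outside the threshold each frame, so occupancy ground truth
  is exact by construction instead of emergent from a potential — a
  recovery test can then separate estimator error from generator noise.
  Drift adds $t \cdot v$ to one chain, emulating dissociation. Times
  default to 10 ps spacing.
* **Sensorgram panels** use the standard six two-fold dilutions
  (1000 → 31.25 nM). "1% noise" means Gaussian noise with sd equal to 1%
  of Rmax. **KD(T) series** apply multiplicative log-normal noise, which
  keeps KD positive. Temperature grids default to 288–310 K, a realistic
  instrument range.

What the synthetic data does *not* emulate: correlated thermal motion,
side-chain rotamer dynamics, solvent and ion effects, mass-transport
artifacts in SPR, or DSC baseline curvature. Tests passing on synthetic
data therefore demonstrate correctness of the estimators and conventions,
not fidelity of any physical model of real data.

# Problem sizes and numerical choices

The test and demonstration workloads use 30–1000-frame trajectories of
45–400-atom models, 6-curve sensorgram panels sampled at 2 Hz, and 6-point
KD(T) grids — sizes chosen so the full suite exercises every code path in
well under a minute per module while keeping Monte-Carlo checks (50-seed
refits, 200-seed bias checks) statistically meaningful. Distance
comparisons against construction use 1e-9 Å; round trips through PDB text
use 1e-3 Å (the file format's precision); stochastic recovery checks use
3-sigma binomial bounds.

Tie-breaks and degenerate inputs: alt-loc ties keep the first record;
RMSD fits reject rank-deficient configurations; occupancy with an empty
post-burn-in window is an error, not zero; kinetic fits with a single
concentration warn; thermograms with no interior maximum are errors.

# Known limitations

* Energy decomposition is short-range only; absolute values differ from
  MD-engine rerun energies that include PME. Comparisons should be made
  within the package (between residues or variants), not across tools.
* Kabat-style residue labels are taken from configuration as author
  numbering; no renumbering is computed, and mismatched residue names in
  a watch-list are reported rather than guessed around.
* XTC trajectories are not readable with the available backends; use
  multi-model PDB or DCD.
* The 1:1 Langmuir model excludes mass transport; strongly
  transport-limited sensorgrams will fit with visible residual structure.
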