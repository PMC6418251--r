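# epistat

Electrostatic interface statistics for antigen–antibody complexes.

Charged-residue pairs (salt bridges) often dominate how an antibody finds
and holds its antigen, and they are the natural handles for rational
interface engineering: invert one charge and binding collapses, invert its
partner too and binding can be restored. Assessing such designs needs the
same few analyses over and over, usually scattered across structure
viewers, MD post-processing scripts and instrument software:

* **Crystal-contact geometry** — distances between charged groups in a PDB
  structure, in both field conventions (marker-atom distance and
  group-minimum distance), plus automatic inter-chain salt-bridge
  detection.
* **Trajectory stability metrics** — Kabsch superposition, Cα RMSD, and
  the ligand-RMSD (L-RMSD): the RMSD of the antibody Cα atoms after
  superposing each frame on the antigen Cα atoms only, a direct readout of
  whether the complex holds together in simulation. Salt-bridge occupancy
  (fraction of post-burn-in frames within a distance threshold) with
  replica mean ± sd.
* **Per-residue interaction energies** — Coulomb + Lennard-Jones
  (12-6, Lorentz–Berthelot) sums between a residue and the partner chains,
  truncated at 12 Å, time-averaged and aggregated over replicas
  (mean ± se).
* **SPR kinetics and thermodynamics** — global 1:1 Langmuir fitting of
  sensorgram panels (shared k_on, k_off, R_max across concentrations;
  K_D = k_off/k_on), van't Hoff analysis
  (ln K_D = ΔH/RT − ΔS/R) with covariance-aware error propagation of
  ΔG = ΔH − TΔS, and DSC melting-temperature (T_m,app) peak picking.
* **Synthetic data generators** — seeded, with exact ground truth, for
  every input above: toy complexes with planted contacts, trajectories
  with planted occupancy schedules and dissociation drift, sensorgram
  panels, KD(T) series, thermograms.

Everything is driven either from R or from a YAML config via
`runPipeline()` (CLI wrapper in `inst/cli/epistat.R`).

## Worked example

```r
library(epistat)

# a synthetic interface model with the canonical contact geometry
m <- makeReferenceInterface()
representativeDistance(m, "I:52", "H:54")   # 3.6 (Lys NZ to Asp CG, A)
groupMinDistance(m, "I:52", "H:54")         # 2.8 (NZ to nearest carboxyl O)

findSaltBridges(m, "I", c("H", "L"), cutoff = 4.0)
#    label chain_a chain_b group_min_A rep_distance_A
#  K52-D54       I       H         2.8            3.6
#  K52-D56       I       H         2.8            3.5
#  R84-E27       I       L         3.7            5.0

# simulate a six-concentration SPR panel (1000 -> 31.25 nM) and refit it
p <- makeSensorgramPanel(kon = 2.7e5, koff = 2.3e-2, rmax = 100,
                         noiseSd = 1, seed = 1)
fitKineticsGlobal(p)
# KineticFit (1:1 Langmuir, global):
#   kon  = 2.7e+05 +/- 9.8e+02 1/(M s)
#   koff = 0.023 +/- 4.5e-05 1/s
#   Rmax = 100 +/- 0.13 RU
#   KD   = 8.519e-08 +/- 3.4e-10 M (85.2 nM)
#   RSS  = 4631 over 4326 points

# van't Hoff thermodynamics from a KD(T) series
kd <- makeKdSeries(dH = -50, dS = -0.03, noiseFrac = 0.02, seed = 2)
vantHoffFit(kd$T_K, kd$KD_M)
# VantHoffFit (ln KD = dH/RT - dS/R, 6 temperatures):
#   dH = -50.169 +/- 0.866 kJ/mol
#   dS = -0.03056 +/- 0.00290 kJ/(mol K)
#   dG(298.0 K) = -41.062 +/- 0.022 kJ/mol
```

The fitted K_D of 85.2 nM is k_off/k_on of the generating rates recovered
through the noise; the van't Hoff fit recovers the planted ΔH and ΔS
within their reported uncertainties, and ΔG's small error bar reflects the
strong (ΔH, ΔS) anticorrelation handled by the covariance term.

See `vignettes/interface-electrostatics.Rmd` for the models, conventions,
defaults and limitations, and `inst/cli/epistat.R synth <dir>` to generate
a complete runnable example dataset with config.

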