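---
title: "Mixed-resolution Monte Carlo docking: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-resolution Monte Carlo docking: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcdock)
```

# The model

`mrmcdock` docks a flexible ligand into a flexible receptor by Metropolis
Monte Carlo under a mixed-resolution potential.  The receptor is split into
an *atomistic region* (the binding site, plus any residues the user forces
in, e.g. a mobile helix) and a *coarse region*.  The total potential is

$$U(\mathbf r) = U_\mathrm{CG}(\mathbf r) + U_\mathrm{AA}(\mathbf r)
  + U_\mathrm{CG/AA}(\mathbf r), \qquad
  U_\mathrm{CG} = U_\mathrm{bb} + U_\mathrm{Gō}.$$

All atom coordinates are tracked everywhere, including in the coarse
region; coarseness is a statement about which *interactions* are computed
at residue resolution, not about which coordinates exist.  Consequences:

* **Gō term.** Non-bonded interactions among coarse residues act between
  α-carbons only.  A residue pair is a *native contact* if its Cα–Cα
  distance in the reference structure is below 8 Å and its sequence
  separation is at least 3 (closer pairs are already constrained by the
  backbone bonded terms; applying a Gō well there would double-count).
  Native pairs use the 12-10 well
  $\varepsilon\,[5 (r^0/r)^{12} - 6 (r^0/r)^{10}]$, whose minimum is
  exactly $-\varepsilon$ at $r = r^0$; all other coarse pairs are purely
  repulsive, $5\varepsilon (r_\mathrm{HC}/r)^{12}$, truncated at the
  nonbonded cutoff (the term is $\sim 10^{-8}$ kcal/mol there, so the
  truncation is inconsequential).
* **Backbone term.** Bond, angle and dihedral terms whose atoms are all
  backbone atoms (N, H, Cα, HA, C, O and terminal variants) of coarse
  residues.  No 1-4 non-bonded terms accompany them.  Coarse-residue side
  chains are rigid bodies riding with their residue: their internal terms
  and any term spanning regions are booked to the cross term
  $U_\mathrm{CG/AA}$, and they interact atomistically with the atomistic
  region.
* **Atomistic and cross terms.** Lennard-Jones 12-6 with AMBER combining
  rules (arithmetic Rmin/2, geometric ε), 1-2/1-3 exclusions, 1-4 scaling
  (vdW ÷ 2.0, electrostatics ÷ 1.2), plain truncation at the 10 Å cutoff.
  Pair energies are capped at $10^6$ kcal/mol so clashes stay finite and
  $e^{-\beta\Delta U}$ well-defined; capped configurations are flagged and
  in practice immediately rejected.

## SEDDD electrostatics

Electrostatics use the solvent-exposure-dependent distance-dependent
dielectric

$$E_{ij} = \frac{K_\mathrm{coul}\, q_i q_j}{\varepsilon_{ij} r_{ij}},
\qquad
\varepsilon_{ij} = r_{ij}\,[\varepsilon_0 + (1 - s_{kl})
(\varepsilon_1 - \varepsilon_0)], \qquad s_{kl} = c\,(v_k + v_l),$$

with $\varepsilon_0 = 2$, $\varepsilon_1 = 8$, $c = 0.625$.  The slope of
8 per Å means a fully exposed pair at 10 Å feels an effective dielectric
of 80 — bulk-water screening at long range — while buried pairs
($s_{kl} \to 1$) approach the protein-interior value of 2.  $s_{kl}$ is
clamped to $[0, 1 - 10^{-9}]$ to keep the stated invariant
$0 \le s_{kl} < 1$ under all inputs.

The occlusions $v_k$ are computed per *hydration group* (by default one
heavy atom with its bonded hydrogens) with an EEF1-style Gaussian
exclusion sum over neighbouring atoms $m$:

$$v_k = \min\Big(1,\; \sum_{m \notin k}
\frac{V_m}{2\pi^{3/2}\sigma_k r_{mk}^2}
\exp\!\big[-\big(\tfrac{r_{mk} - R_k}{\sigma_k}\big)^2\big]\Big),$$

where $R_k$ is the group's shell radius (its heavy atom's Rmin/2),
$\sigma_k$ its exclusion width and $V_m$ the neighbour's solvation volume,
all read from the parameter file.  The calculator sits behind a small
contract (coordinates in, one scalar per group out) and can be swapped
without touching the rest of the energy model; the test surface pins the
contract's fixture-level behaviour (zero when isolated, saturation for
coincident occluders, monotone decay), not specific interior values.

**Moiety-resolved occlusion.** A design choice that the two-body formula
leaves open: which atoms occlude which groups.  We compute intra-protein
and intra-ligand electrostatic pairs with *same-moiety* occluders only,
and protein–ligand interaction pairs with the full occlusion.  This makes
the decoupled state exact: at $\lambda = (0, 0)$ the total energy is the
sum of the isolated-moiety energies and is rigorously independent of the
ligand pose, which the NCMC work accounting and the λ-linearity identity
$U(\lambda{=}1) - U(\lambda{=}0) = U_\mathrm{VDW} + U_\mathrm{elec}$ rely
on.  The alternative (full occlusion everywhere) leaks ligand-position
dependence into the "protein" energy through the dielectric and breaks
both identities at the $10^{-4}$ kcal/mol level.  SEDDD is applied
uniformly to every electrostatic pair, including intra-ligand ones.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| ε (Gō well depth) | 3.0 | kcal/mol | native-state stability of the coarse region |
| r_HC | 1.7 | Å | hard core of nonnative coarse pairs |
| native cutoff | 8 | Å | contact definition (reference structure) |
| ε₀, ε₁ | 2, 8 | — | buried / exposed dielectric slope |
| c | 0.625 | — | occlusion-to-overlap conversion |
| nonbonded cutoff | 10 | Å | truncation of all atomistic pairs |
| T | 300 | K | with k_B = 0.0019872041 kcal/mol/K |
| contact rule | 3 | Å | heavy-atom distance defining the atomistic region |
| placement radius | 4 | Å | initial random-pose ball |
| K_coul | 332.0636 | kcal·Å/(mol·e²) | AMBER electrostatic constant |

Units throughout: Å, kcal/mol, degrees at user interfaces (move sizes,
parameter files), radians internally.  Atom indices are 1-based, the
natural R convention.

# Sampling

## Move set and flexibility modes

Six move kinds with production maximum sizes: backbone rotation (2°, about
a randomly chosen φ or ψ axis, rotating everything downstream), sidechain
rotation (180°, atomistic residues only), backrub (2°, rotating the
segment strictly between two residues — plus the flanking carbonyl and
amide groups — about their Cα–Cα axis), ligand bond rotation (180°),
ligand translation (1 Å, uniform in the ball), ligand rotation (180°,
uniform random axis through the ligand centroid).  The three modes draw
these with fractions 0.1/0.2/0.1/0.2/0.2/0.2 (fully flexible), thirds over
the ligand moves (fixed protein), and quarters with sidechain rotation
added (sidechain only).  Choices the move definitions leave open, decided
here once: backbone pivots are φ/ψ only; backrub pairs are drawn uniformly
from sequence separations 2–10, keeping the move local and
well-conditioned; rotations use a uniform random axis with angle uniform
in (−max, +max], which for 180° maxima is *not* the Haar measure on SO(3)
— the same convention is used by the engine and the pose generator, so
the two stages are mutually consistent.  Ligand rotations pivot on the
unweighted ligand centroid (atomic masses are not part of the data model).

## Energy bookkeeping

Each trial move re-evaluates the potential with fully vectorised pair
arithmetic over precomputed pair lists; at the system sizes this package
targets (toy complexes of 100–200 atoms; a binding-site-sized atomistic
region) a full re-evaluation costs about a millisecond and removes an
entire class of stale-cache bugs that partial updates invite.  Hydration
occlusions are likewise recomputed at every evaluation.  The running
energy is still tracked by accumulated per-move deltas and compared
against a fresh evaluation every 1000 moves; drift beyond
$10^{-4}$ kcal/mol is a hard error by contract, and the test suite pins
the accumulated-vs-recomputed agreement to $10^{-6}$ over 1000 moves.

## NCMC layer

An NCMC move is a short driven simulation: four phases of 100 interior MC
moves during which $\lambda_\mathrm{elec}$ and $\lambda_\mathrm{VDW}$ walk
a shared 0.05-spaced grid (elec↓, vdw↓, vdw↑, elec↑; one grid step every 5
interior moves).  Interior moves use the scaled potential in the ordinary
Metropolis rule, which samples the canonical distribution of whatever λ is
current.  At each λ update the work accumulates
$w \mathrel{+}= \Delta\lambda \cdot U_\mathrm{comp}(\mathbf r)$ with the
component evaluated at the configuration current when the change is
applied; the driven segment is finally accepted with
$\min\{1, e^{-\beta w}\}$ and the pre-move configuration is restored
exactly on rejection.

Numerical detail: work is accounted per component as
$\lambda_\mathrm{step} \times (\sum_\mathrm{up} U - \sum_\mathrm{down} U)$,
algebraically identical to the update-by-update sum (every update is
exactly one grid step) but exact in floating point for the frozen-
configuration null case — a configuration that never moves accumulates
*bitwise* zero work and unit acceptance, which the tests assert without
tolerance.  A per-move log of (component, Δλ, U) supports replaying the
work sum.

One source text states both "800 individual Monte Carlo moves" and "four
100-move phases" for the interior segment; the schedule arithmetic (full
traversal at 0.05 per 5 moves) forces 100 moves per phase, so the default
is 4 × 100 = 400 with `moves_per_phase` exposed for the other reading.
The mixed protocol alternates one NCMC move with 400 regular MC moves;
every elementary trial move (interior or regular) counts toward the
trial-move budget, so the default 80 000-move budget is 100 cycles.
λ-scaling is linear on both components; no soft core.

# Docking protocol

A run generates `n_initial_poses = 1000` random poses with ligand centroid
uniform in the 4 Å ball around the site centre (defaulting to the
reference ligand's heavy-atom centre of mass), uniform random orientation
and every rotatable bond at an independent uniform angle.  Poses with
capped clash energies are admissible — energy-based seeding avoids them
naturally and no resampling filter is applied.  The lowest *total* energy
pose (configurable to interaction energy) seeds refinement: 40 000 MC
moves, or 80 000 elementary moves of mixed NCMC/MC.  Campaigns fan out
independent runs over prepared protonation variants (variants are inputs;
no pKa machinery in scope) with per-run seeds derived from the master seed
by a deterministic counter scheme, so campaigns are reproducible run by
run and failed runs are recorded and skipped rather than fatal.

Rotatable bonds are detected from the ligand bond graph: acyclic single
bonds between non-terminal heavy atoms, excluding amide C–N — the standard
docking convention, deterministic from the graph.

# Analysis

* **Symmetry-aware RMSD.** The pose is superposed on the reference by a
  Kabsch fit of the shared protein backbone atoms (never ligand atoms);
  the reported value is the minimum ligand heavy-atom RMSD over all
  element-preserving automorphisms of the ligand bond graph, enumerated by
  VF2 with element colours.  Enumeration refuses (with an error) above
  10⁴ mappings rather than silently truncating.
* **Clustering.** Complete-linkage agglomeration of the pose–pose RMSD
  matrix, cut at the 10th percentile (linear-interpolation definition) of
  the *off-diagonal* distances — including the zero self-distances would
  bias the cutoff down.  Complete linkage guarantees every intra-cluster
  distance is at most the cutoff, which the suite asserts against a
  brute-force oracle on all matrices of a seeded random suite of sizes ≤ 8.
* **Ranking.** Method 1: global lowest interaction energy.  Method 2:
  lowest-energy member of the largest cluster, size ties broken by lower
  mean interaction energy (a choice the rule leaves open).  Method 3:
  lowest-energy member of the cluster with the lowest mean interaction
  energy.
* **Move-size diagnostics.** The effective translation/rotation of an NCMC
  move is measured after backbone alignment of the end configuration onto
  the start; the optimal ligand rigid transform is decomposed into a
  centroid shift and a rotation angle from the trace of the rotation
  matrix, reported in [0°, 180°].  The *attempted* displacement is logged
  whether or not the move is accepted, which is what acceptance-vs-size
  histograms need.

# The synthetic fixtures: what they do and do not show

Real receptor–ligand systems require parameterisation pipelines that are
out of scope here, so the test surface is built on synthetic systems that
are complete by construction:

* `make_toy_receptor()` — a helical Cα trace (2.3 Å radius, 1.5 Å rise,
  100°/residue) with full backbone atoms and a two-bead side chain; every
  bonded term's equilibrium is its built geometry, so the reference is an
  exact minimum of the bonded energy and native Gō contacts sit at the
  bottoms of their wells.  The atomistic region is the patch of residues
  closest to a site point off the helix face.  LJ radii and charges are
  deliberately small (heavy Rmin/2 = 1.0 Å, ε ≈ 0.1 kcal/mol, partial
  charges ≤ 0.3 e) so that production-sized moves at 300 K have acceptance
  rates in the 0.1–0.9 range and both accept and reject paths are
  exercised.
* `make_two_state_toy()` — two fixed LJ pockets of unequal depth
  (ε = 2.0 / 0.5 kcal/mol, 7 Å apart) and a single-atom apolar ligand
  confined by a 9 Å spherical wall.  Its pose populations are computable
  to arbitrary accuracy by dense quadrature over the ligand's three
  translational coordinates, giving an exact target for sampling-
  correctness tests of both plain MC and the mixed NCMC/MC protocol.
  These dimensions were chosen once so that the inter-pocket barrier is
  ≈ 1.5 k_BT: runs hop between basins many times within a 10⁵-move test.
* `make_harmonic_toy()` — a single restrained particle
  ($U = \tfrac{k}{2}|x - x_0|^2$, so each coordinate's variance is exactly
  $k_BT/k$; note the bonded terms keep the AMBER $k(r - r_0)^2$
  convention — two conventions, two documented objects).

Passing on these fixtures demonstrates that the energy model, the
samplers, the coupling schedule, the work accounting and the analyses are
*internally correct*.  It does not demonstrate chemical accuracy on real
complexes: the toys have no hydrogen-bond geometry, no torsional strain
competition, no desolvation asymmetry, and their energy scales are mild by
construction.  Claims about real docking performance require real force
fields and reference structures, which are inputs to this package, not
products of it.

Test problem sizes (10–20-residue receptors, 10⁵-move sampling runs,
60-cycle mixed protocols) were chosen as the smallest systems that leave
the assertions statistically meaningful — sampling tests compare against
exact targets within three standard errors estimated by batch means.

# Numerical choices and degenerate inputs

* Steric clashes: pair energies capped at 10⁶ kcal/mol; interatomic
  distances floored at 10⁻⁶ Å; a wall violation adds a large finite
  constant rather than infinity, keeping every Boltzmann factor defined.
* Degenerate torsions: dihedral terms whose defining triples are
  near-collinear are excluded at fixture-build time (the torsion plane is
  ill-defined and its energy would not be rotation-invariant).
* Ties: seed-pose selection and ranking argmins break ties by lowest
  index; clustering inherits `hclust`'s deterministic merge order.
* Quantile convention: percentile cutoffs use R's type-7 linear
  interpolation.
* PDB round-trips preserve coordinates to the format's 10⁻³ Å precision;
  region labels and force-field parameters are not PDB concepts and travel
  in the native parameter file instead.

# Known limitations

* The linear-in-r dielectric is not physical at large separations (it
  should saturate at bulk water); there is no hydrophobic-effect term.
* The Gō term biases the coarse region toward its reference conformation;
  large-scale conformational changes outside the atomistic region are
  suppressed by construction.  Multi-basin coarse potentials are out of
  scope.
* Full energy re-evaluation per move is the right trade-off at fixture
  scale but would need neighbour-listed incremental updates for
  production-size atomistic regions.
* NCMC uses linear λ-scaling without soft-core van der Waals, so
  recoupling into a clash produces large work values and rejection —
  the known cost of that simplification.
* MOL2 support covers the ATOM/BOND sections of the TRIPOS format;
  multi-molecule files use the first molecule only.
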