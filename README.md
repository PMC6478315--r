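# mrmcdock

Flexible protein–ligand docking by **mixed-resolution Monte Carlo (MRMC)**.

Grid-based docking programs freeze the receptor to gain speed; fully
atomistic simulations allow complete flexibility at a cost that rules out
routine docking campaigns.  `mrmcdock` implements the middle way: the
binding site and the ligand are treated with an AMBER-form atomistic force
field, while the rest of the receptor is coarse-grained to a Gō-type
native-contact model on its α-carbons that keeps the protein flexible —
including its backbone — at a fraction of the cost.  All atom positions are
tracked throughout, so cross-region interactions remain fully atomistic.

## The model

The potential is assembled as

```
U(r) = U_CG(r) + U_AA(r) + U_CG/AA(r),          U_CG(r) = U_bb(r) + U_Gō(r)
```

* **U_Gō** — a 12-10 native-contact potential between α-carbons of
  coarse-grained residues.  Native pairs (reference Cα–Cα distance below
  8 Å, sequence separation ≥ 3) interact as
  `ε [5 (r⁰/r)¹² − 6 (r⁰/r)¹⁰]`, a well of depth ε = 3.0 kcal/mol with its
  minimum exactly at the native distance r⁰; all other coarse pairs feel
  the repulsion `5 ε (r_HC/r)¹²` with hard-core radius r_HC = 1.7 Å.
* **U_bb** — AMBER-form bond, angle and dihedral terms over the backbone
  atoms of the coarse region (no 1-4 nonbonded terms), so backbone geometry
  stays physical even where the residues are coarse.
* **U_AA and U_CG/AA** — Lennard-Jones 12-6 with AMBER combining rules and
  1-4 scalings, plus electrostatics under a **solvent-exposure-dependent
  distance-dependent dielectric (SEDDD)**:

  ```
  E_ij = K_coul q_i q_j / (ε_ij r_ij),   ε_ij = r_ij [ε₀ + (1 − s_kl)(ε₁ − ε₀)]
  s_kl = c (v_k + v_l)
  ```

  with ε₀ = 2, ε₁ = 8, c = 0.625.  The hydration-shell occlusions v_k come
  from an EEF1-style Gaussian exclusion sum, so buried pairs see a lower
  dielectric.  A fully exposed pair at 10 Å feels an effective dielectric
  of 80.

Sampling is Metropolis Monte Carlo at 300 K with six move kinds (backbone
rotation, sidechain rotation, backrub, ligand bond rotation, ligand
translation, ligand rotation) and three protein-flexibility modes (fully
flexible / sidechain only / fixed protein).  On top of the plain sampler, a
**nonequilibrium candidate Monte Carlo (NCMC)** layer drives the
protein–ligand coupling `U = U_protein + U_ligand + λ_VDW U_VDW + λ_elec U_elec`
through a four-phase schedule (λ_elec↓, λ_VDW↓, λ_VDW↑, λ_elec↑; steps of
0.05 every 5 interior moves, 100 moves per phase), accumulates the
nonequilibrium work `w = Σ Δλ · U_component`, and accepts the whole driven
segment with probability `min{1, e^(−βw)}`.

The docking protocol generates 1000 random ligand poses within 4 Å of the
site centre (random orientation, every rotatable bond randomised), refines
the lowest-energy pose by 40 000 MC moves (80 000 for mixed NCMC/MC), and
scores poses by the protein–ligand interaction energy.  Analysis tools
include symmetry-aware ligand RMSD (minimised over graph automorphisms of
the ligand), complete-linkage pose clustering at the 10th-percentile
distance cutoff, three pose-ranking rules, and best-of-N performance
curves.

## Worked example

Every component runs on bundled synthetic fixtures — no downloads needed:

```r
library(mrmcdock)
sys <- make_toy_complex(make_toy_receptor(n_residues = 16, n_atomistic_residues = 6),
                        make_toy_ligand(n_rotatable_bonds = 1))
model <- energy_model(sys)
total_energy(model, sys$xyz)
#> Energy breakdown (kcal/mol), lambda = ( 1 , 1 )
#>   u_cg             -24.000000
#>   u_bb               0.000000
#>   u_go             -24.000000
#>   u_aa              -0.572789
#>   u_cg_aa          -11.174881
#>   u_protein        -35.749273
#>   u_ligand          -0.029592
#>   u_vdw_int         -0.020990
#>   u_elec_int         0.052185
#>   u_restraint        0.000000
#>   total            -35.747670
```

`u_go = −24` is the 8 native contacts of the coarse region each sitting at
the bottom of their 3 kcal/mol well; `u_bb = 0` because the fixture's
bonded equilibria are its built geometry; `u_vdw_int`/`u_elec_int` are the
protein–ligand interaction terms that the docking protocol scores and the
NCMC layer scales.

A docking campaign on the two-pocket toy — a system whose exact pose
populations are known by quadrature — finds both binding poses:

```r
toy <- make_two_state_toy()              # two LJ pockets, depths differ
two_state_weights(toy)                   # exact Boltzmann weights
#>         A         B
#> 0.5254885 0.4745115
model <- energy_model(toy$system, wall = toy$wall)
spec <- docking_run_spec("mc", n_trial_moves = 1500, n_initial_poses = 40,
                         site_center = c(0, 0, 0), mode = "fixed_protein",
                         rng_seed = 2024, stride = 500)
camp <- run_campaign(list(toy = model), spec, n_runs_per_variant = 20)
finals <- vapply(camp$poses, function(p) p[3, 1], numeric(1))
table(ifelse(finals < 0, "pocket A", "pocket B"))
#> pocket A pocket B
#>       12        8
```

A command-line front end (`inst/cli/mrmcdock`) exposes `dock`, `report`
and `fixtures` subcommands over the same functions.

## Scope

Ligand parameterisation (GAFF/antechamber), protonation-state prediction
(protonation variants are *inputs* to a campaign), generalized-Born or
explicit solvation, soft-core van der Waals and rotamer-library moves are
out of scope.  The methods vignette
(`vignettes/mixed-resolution-docking.Rmd`) documents the model, parameter
choices, numerical conventions and known limitations.
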