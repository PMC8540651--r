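---
title: "Binding-mode evaluation for covalent TRPA1 agonists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode evaluation for covalent TRPA1 agonists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premode)
```

## The problem

Electrophilic agonists of the TRPA1 ion channel act in two stages. A
reversible, non-covalent *prerequisite* binding mode forms first, outside or
above the final pocket, while the cytoplasmic A-loop (residues ~666–680)
still covers the site; interactions with the loop then let it flip open, and
the agonist's electrophilic warhead reaches the nucleophilic sulfur of C621
to form the final covalent bond. Analysing this process requires a consistent
set of pose-level metrics, rescoring functions, a clustering/ranking
protocol, trajectory descriptors, and a decision rule for forecasting potent
agonists. `premode` packages exactly that analysis layer. Docking searches,
molecular-dynamics engines, force-field parameter derivation and
covalent-bond quantum chemistry are deliberately out of scope: structures,
pose ensembles, energies and trajectories are consumed, not produced.

## Pose metrics

**RMSD.** Docked poses and the crystallographic reference share the target
coordinate frame, so the root mean squared deviation over paired heavy atoms
is computed *without* superposition. Atom pairing is by atom name within the
ligand residue; symmetry-aware matching (graph isomorphism over equivalent
atoms) is intentionally not attempted — names must be consistent between
reference and poses, and a mismatch is an error rather than a guess.

**Warhead distance d.** The Euclidean distance between the ligand's
electrophilic atom and the C621 sulfur. Over an ensemble, `d_best` is its
minimum; in a covalent complex the same measurement is the covalent bond
length (about 1.8 Å for the C–S bond).

**Binding pocket and AA_match.** A target residue belongs to the pocket when
at least one of its heavy atoms lies within 3.5 Å (inclusive) of any ligand
heavy atom; hydrogens are ignored because deposited structures and docking
output treat them inconsistently. AA_match is the percentage of
reference-pocket residues found in the observed pocket, with residues
identified by number and name so apo and holo forms compare correctly. The
denominator is the *reference* pocket size; a union-size denominator is
available (`denominator = "union"`) because the convention is genuinely
ambiguous, but the reference-size reading is the default since the published
values include 100% matches against an experimental reference pocket, which
the union convention would only produce for identical pockets.

**Efficiency index.** EI_NHA = −ΔG/NHA, in kcal/mol per heavy atom. The sign
is chosen so that favorable (negative) free energies give positive indices,
matching how such values are reported. Displayed values are rounded to two
decimals *half away from zero* (base R's `round()` rounds half to even, which
is not how tables are typically typeset); forecasting always uses unrounded
values. One published reference cell is internally inconsistent at this
precision: a ΔG of −77.4 kcal/mol over 23 heavy atoms gives 3.3652…, which
rounds to 3.37, while the table prints 3.36 — almost certainly a truncation.
That cell is documented here and excluded from exact checks; the other five
cells reproduce exactly.

## Scoring

Both rescoring functions share one Lennard-Jones 12-6 kernel with combining
rules: ε_ij = √(ε_i ε_j), R_ij = R_i + R_j, A = ε_ij R_ij¹²,
B = 2 ε_ij R_ij⁶, E = A/r¹² − B/r⁶. The kernel's analytic properties — unique
minimum of exactly −ε_ij at r = R_ij, symmetry, rapid decay — are asserted in
the tests rather than assumed.

**AutoDock-style score.** A weighted sum over ligand–target atom pairs within
the nonbonded cutoff of four terms: the 12-6 term; a directional 12-10
hydrogen-bond well for donor–acceptor typed pairs (C = 5 ε_hb r₀¹²,
D = 6 ε_hb r₀¹⁰, so the well has depth ε_hb at r₀); screened Coulomb
electrostatics q_i q_j/(ε(r) r) with the conversion constant
332.0637 kcal·Å/(mol·e²); and Gaussian desolvation
(S_i V_j + S_j V_i)·exp(−r²/2σ²). Defaults and rationale:

- *Term weights* default to the published AutoDock 4.2 calibration
  (0.1662, 0.1209, 0.1406, 0.1322). The weights of the original study are
  not published, so they are fully configurable and nothing in the
  acceptance checks depends on them.
- *Dielectric* ε(r) defaults to the sigmoidal distance-dependent model of
  Mehler and Solmajer (ε(r) = A + B/(1 + k e^{−λBr}), A = −8.5525,
  k = 7.7839, λ = 0.003627, B = 78.4 − A), with a constant-ε option; the
  functional form used by the original programs is not published.
- *Directional weight* E(t) = cos²(π t / 2·cone) inside a 90° cone, 0
  beyond: smooth, 1 at ideal geometry, monotone non-increasing — the minimal
  shape satisfying the published description. The deviation angle is
  measured through the donor's explicit hydrogen when one is present within
  1.3 Å; without explicit hydrogens the geometry is taken as ideal, because
  heavy atoms alone cannot define it.
- *Desolvation width* σ defaults to 3.5 Å, configurable.
- *Typed-pair bookkeeping*: donor–acceptor pairs are handled by the 12-10
  term and excluded from the 12-6 sum by default (configurable), since
  counting both would double the contact repulsion. Donor/acceptor flags
  come from an optional `hb` column of the parameter table — atom typing is
  data, not chemistry perception.
- *Nonbonded cutoff* defaults to 11 Å, the van der Waals/Coulomb cutoff of
  the simulations this analysis is designed for.

**FITTED-style score.** ΔG = ΔG₀ + 0.14·N_rot + scale·(0.26·U_vdW +
0.035·U_elec + 0.80·Σ f_hb). Only the four printed coefficients are fixed
by the published description; ΔG₀ and the per-interaction scale factor are
not printed and default to 0 and 1, so tests assert only the coefficients.
f_hb is evaluated per donor–acceptor pair as
−ε_hb · exp(−(r − r₀)²/2w²) · E(t) with w = 0.5 Å — a documented,
configurable stand-in for the unpublished original form. No acceptance
quantity depends on it.

## Clustering and ranking

The protocol is greedy and seed-relative: among unassigned poses, the one
with the lowest calculated free energy of binding opens a new rank and
absorbs every unassigned pose within 2 Å RMSD *of the seed* (single-linkage
to the seed, not complete linkage, and an absorbed pose is never
reconsidered). This follows the published wording — a lowest-energy
structure "and its neighboring docked ligand structures within 2 Å". Energy
ties are broken by input order, making the output deterministic. Rank_best
is the label N/M, where N is the 1-based rank of the cluster containing the
pose minimizing the structural metric (RMSD in covalent mode, d in
prerequisite mode) and M is the number of ranks; published labels such as
1/3 for ten-pose runs confirm M counts ranks, not poses. A brute-force
re-implementation of the protocol serves as an oracle in the tests; the two
agree on every ensemble tried (50 seeded ensembles of up to 10 poses).

## Trajectory analysis

**Per-residue profiles** sum the 12-6 kernel over ligand-atom/residue-atom
pairs within the nonbonded cutoff, per residue and frame. Profiling is
LJ-only by design; electrostatics are excluded. The per-residue columns sum
exactly (to rounding) to the total ligand–protein LJ energy within the
cutoff, which the tests verify against a naive double loop.

**Loop gating.** d_LOOPS is the per-frame distance between the N615 backbone
nitrogen and the Q676 side-chain oxygen, the indicator of A-loop opening.
Classification is inclusive toward the extreme states (open when
d ≥ open threshold, closed when d ≤ closed threshold). No default thresholds
are shipped for real data — published figures carry no threshold values — so
they must be supplied; for synthetic fixtures the midpoints of the scripted
plateaus are the natural choice.

**Events.** The ligand is bound when its residue contact count (heavy-atom
pairs within 3.5 Å, the same cutoff as pocket detection) reaches
`min_contacts`. Runs of a state shorter than the dwell (default 5 frames)
are merged into their neighbor before transitions are read off, suppressing
single-frame flicker; reported events are therefore alternating
dissociations and associations. The dwell default reflects that reported
events are at nanosecond resolution while frames are picosecond-spaced.

## Synthetic data: what it does and does not emulate

The generators are pure functions of seed and parameters, and they encode
*ground truth*, not physics:

- Toy pockets place residue templates on a spherical lattice around the
  site, with contact residues' anchor atoms at 2.9 Å from the center and
  non-contact residues at 7.5 Å, so pocket detection has an exact scripted
  answer. Landmark numbering (C621, N615, Q676) is reused so analysis
  defaults work on fixtures unchanged.
- Pose ensembles displace the reference by a rigid translation plus
  per-atom Gaussian jitter; because the RMSD of `reference + s·D` is linear
  in `s`, the perturbation scale is solved in closed form and the achieved
  heavy-atom RMSD equals its target to machine precision (contractually,
  within 0.01 Å over targets up to 10 Å).
- Scripted trajectories translate residue 676 rigidly along the gate axis
  to follow a closed→open ramp (plateaus 6 Å and 14 Å by default), jump the
  ligand between its bound position and a remote position 25 Å away at the
  scripted event frames, and add isotropic Gaussian noise (default 0.1 Å,
  up to 0.3 Å in robustness sweeps). The four scenario kinds — static,
  unbind–rebind under a stable open loop, loop opening with dissociation
  then re-association, and dissociation only — mirror the canonical
  qualitative outcomes of the simulations this analysis targets.

What the fixtures do *not* emulate: force-field-relaxed geometry, sterics,
solvent, gradual (diffusive) binding pathways, or realistic energetics — a
ligand cluster 2.9 Å from pocket anchors sits on the repulsive shoulder of
the 12-6 well, which is irrelevant for the bookkeeping the fixtures test but
means profile magnitudes on fixtures should not be read physically. Passing
tests therefore demonstrate the correctness of metrics, protocols and event
logic, not the realism of any docking or simulation result. Published
RMSD_best values, rank labels and interaction-energy figures are outputs of
the original search engines and simulations and are not reproducible without
them; the package instead verifies everything that is derivable — metric
arithmetic from published ΔG/NHA inputs, threshold logic, protocol
equivalence to brute force, and analytic properties of the kernels.

## Numerical conventions and degenerate inputs

- Distances in Å, energies in kcal/mol, times in ps, charges in elementary
  units, throughout.
- All distance thresholds are inclusive (≤); forecast comparisons are
  inclusive on all three criteria.
- Interatomic distances below 0.01 Å are a singularity error in scoring;
  exact zero distance is an error in the LJ kernel.
- Empty pockets are valid results; an empty *reference* pocket makes
  AA_match undefined (error). Empty correspondences, missing energies,
  unresolvable atoms and inverted loop thresholds are errors, not warnings.
- PDB I/O is fixed-column (wwPDB v3.3) behind `bio3d`; ATOM and HETATM are
  treated identically, altloc records other than blank/'A' are dropped with
  a warning, insertion codes are rejected, and multi-model files become
  trajectories with a default 1 ps frame spacing. Coordinates round-trip at
  the format's 3-decimal precision.
- Parameter lookup is (residue name, atom name) first, element fallback
  second, error third — so tiny tables can parameterize toy fixtures while
  full tables can still override specific atoms.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
problems — pockets of 4–8 residues, ligands of 10–23 heavy atoms, ensembles
of up to 12 poses, trajectories of 30–100 frames, 50-seed clustering sweeps
and 100-seed event-recovery sweeps — sizes at which every brute-force oracle
is exact and the whole suite completes in well under a minute. The
implementation itself is vectorized over atom pairs and has no intrinsic
size limit beyond memory for the pairwise distance matrices.

## Known limitations

- No symmetry-aware RMSD: chemically equivalent atom permutations (e.g. a
  flipped phenyl ring) inflate RMSD unless names are canonicalized upstream.
- H-bond directionality degrades to the ideal-geometry weight when explicit
  hydrogens are absent.
- The unpublished pieces of the original scoring functions — term weights,
  ε(r), E(t), f_hb, ΔG₀, the scale factor — are configurable models chosen
  for smoothness and documented defaults, not refits; absolute rescoring
  values are therefore not comparable to the original programs' outputs,
  though all published term coefficients are honored.
- Trajectories must arrive imaged and fitted; no periodic-boundary
  treatment is performed.
- The forecast rule is a threshold heuristic anchored on one reference
  agonist; it is not an affinity or EC50 model.
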