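---
title: "NOE-guided ensemble docking: models, parameters and design choices"
author: "NOEDock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NOE-guided ensemble docking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NOEDock)
```

## The problem

Weakly binding small molecules (mid-micromolar fragments) often cannot be
crystallized in complex with their receptor, and when the binding site is a
small, transiently open internal cavity — as in the PAS-B domains of
bHLH-PAS transcription factors such as ARNT — even the receptor conformation
that accommodates the ligand is not directly observable. What *is*
measurable in solution is a sparse set of intermolecular NOEs: qualitative
NOESY cross-peak intensities linking ligand protons to assigned protein
methyl groups, each implying an interproton distance below roughly 5 Å.

NOEDock implements the computational half of that experimental strategy as a
desk-scale, fully testable pipeline:

1. **Restraint calibration.** Cross-peaks classified as strong / medium /
   weak become interproton distance bounds with upper limits 2.8 / 3.5 /
   5.0 Å and a universal lower limit of 1.8 Å (van der Waals contact).
2. **Heavy-atom extension.** Each interproton bound is shifted by +1 Å to an
   inter-heavy-atom bound (implicitly absorbing the two C–H bonds), with
   chemically equivalent protons expanded into one unambiguous distance per
   distinct heavy-atom pair; methyl protons collapse onto their single
   methyl carbon.
3. **Cavity-openness sampling.** A weighted-ensemble (WE) resampler with a
   minimal adaptive binning (MAB) scheme runs over a progress coordinate
   defined as the solvent-accessible surface area (Shrake–Rupley) of the
   cavity-lining residues, producing open-cavity conformations without
   biasing the dynamics.
4. **Ensemble reduction.** Quality-threshold (QT) clustering of a sampled
   trajectory at a 2 Å heavy-atom RMSD radius, keeping the medoid of each
   cluster as a docking receptor.
5. **Restraint-guided rigid-body docking.** Random orientations plus local
   rigid-body minimization of an ambiguous-interaction-restraint (AIR) +
   soft-steric score, 1000 poses per receptor conformation by default.
6. **Pose selection.** Symmetry-aware leader clustering of the ligand RMSD
   at 1.5 Å, cluster ranking by the mean score of each cluster's top four
   poses, best-pose-per-cluster selection, and a 0.3 Å NOE-violation
   filter, reported with "as an ensemble, satisfied *k* of *N* restraints;
   *r* of *M* residues" accounting.

## Models and conventions

### Effective distances and ambiguous restraints

All group-to-group distances use the r⁻⁶-summed effective distance

$$ d_\mathrm{eff} = \Big( \sum_{i \in A} \sum_{j \in B} d_{ij}^{-6} \Big)^{-1/6}, $$

the standard aggregate behind ambiguous interaction restraints: it never
exceeds the smallest pairwise distance, reduces to the plain distance for
singleton groups, and lets any one contact largely satisfy a multi-atom
restraint. A restraint's violation is
$\max(0,\ d_\mathrm{eff}-\mathrm{upper},\ \mathrm{lower}-d_\mathrm{eff})$;
lower-bound violations count like upper-bound ones.

### Heavy-atom expansion bookkeeping

The expansion multiplies each restraint by (#distinct ligand heavy atoms) ×
(#distinct receptor heavy atoms) in its proton groups. Both bounds are
shifted by +1 Å, not just the upper one; "extending each interproton
distance" is read as moving the whole interval, which keeps the interval
width — and thus the informativeness of the bound — unchanged. With this
convention a ligand with one degenerate aromatic proton pair (two distinct
carbons) engaged in 7 of 12 restraints yields 19 heavy-atom distances, and
a 28-restraint table with three two-carbon ambiguous methyl groups yields
31 — the counting identities the test suite pins down. The bundled
`inst/extdata/*_synthetic_*.tsv` tables are *synthetic stand-ins* built to
have exactly this degeneracy structure; they are not the experimental
restraint lists.

### Active residues

Docking "active residues" are receptor residues that (a) carry at least one
NOE peak and (b) are labelled `cavity` in the site-label table. Residues
labelled `surface` (a surface-binding contact) or `outlier` (a long-range
artifact, e.g. spin diffusion) are excluded even when they show NOEs. One
ambiguous restraint per active residue is built from every ligand heavy atom
to the residue's side-chain heavy atoms with a 5.0 Å upper bound — the
weak-NOE contact limit — because the underlying docking protocol specifies
active residues but not per-AIR bounds.

### The rigid-body score

The score is deliberately minimal:
$E = w_\mathrm{AIR} \sum_r \max(0, d_\mathrm{eff}^{(r)} - u_r)^2
   + w_\mathrm{steric} \sum_{ij} \max(0,\ s\,(R_i+R_j) - d_{ij})^2$
with softness $s = 0.8$ and Bondi radii. A full docking energy
(electrostatics, desolvation, vdW wells) is intentionally *not*
reimplemented: the selection logic downstream only needs a ranking signal
plus restraint energies, and anything richer would be invention. One
consequence is documented as a deliberate divergence: the original protocol
manually demoted one top pose for unfavourable electrostatics; with no
electrostatics in the score, no such override exists here.

Because only the rigid-body stage of the three-stage docking protocol is in
scope (the torsion-space annealing and explicit-solvent refinement stages
are not), the calibrated NOE restraints are passed into the same ambiguous
penalty sum at the rigid-body stage. In the original protocol the NOE
information enters at the later stages; with those out of scope, feeding it
to the rigid-body objective is what makes restraint-guided pose recovery
possible at all. `scorePose()` itself is agnostic: it evaluates whatever
ambiguous restraint set it is given.

### Minimization

Rigid-body minimization is derivative-free Nelder–Mead over the 6 degrees
of freedom (a rotation vector about the current ligand centroid plus a
translation), with a fixed evaluation budget and a hard monotonicity
guarantee: the returned pose never scores worse than the input, and the
ligand's internal geometry is untouched. A derivative-free method was
chosen because the soft-steric surface is only piecewise smooth; a budget
cap (default 150 evaluations) keeps ensemble runs predictable, with
`@converged = FALSE` flagging budget exhaustion.

### SASA and the cavity coordinate

Shrake–Rupley SASA uses a deterministic golden-spiral lattice (default 960
points/atom, probe 1.4 Å) — no RNG, so the progress coordinate is exactly
reproducible. Hydrogens are excluded by default since crystal-structure
receptors typically lack them; the toy systems retain pseudo-protons for
restraint checking but those do not enter SASA either. Cavity openness is
the summed per-atom SASA of the listed cavity residues computed in the
context of the whole structure.

### Weighted ensemble and MAB

The WE resampler follows the statistically exact split/merge scheme: in an
under-populated bin, walkers are split into equal-weight copies allocated
proportionally to weight (one walker of weight *w* at target 8 becomes 8
copies of *w*/8); in an over-populated bin, the two lowest-weight walkers
are merged repeatedly, the survivor drawn with probability proportional to
weight. Total weight is conserved to 1e-12 per iteration by construction.
The MAB layout reserves one bin for the current lagging walker and one for
the leading walker, with the remaining bins spaced linearly between the
current extremes; the full published recursion of the MAB scheme is richer,
but this documented core reproduces the adaptivity (boundary bins track
the advancing front) without inventing unpublished details. Equal-weight
ties break to the lowest walker index; each iteration consumes one derived
RNG stream, so runs are bit-identical under a fixed seed.

The bundled test system is an overdamped Langevin particle on
$U(x) = h\,((x/w)^2 - 1)^2$. The production-scale 8 µs protein WE run is
*not* reproduced — the sampler's statistical exactness is instead verified
against Boltzmann quadrature and long brute-force Brownian runs on this
double well at ≤ 10⁶ total steps.

### QT clustering and representatives

QT clustering repeatedly commits the largest candidate cluster (all
unassigned frames within the radius of some unassigned seed), breaking
ties to the lowest seed index, so the partition is deterministic. The
radius is a *seed-to-member* distance, matching the "cluster radius"
wording, not a cluster diameter. "Closest to the centroid" is implemented
as the RMSD-space medoid, since a coordinate-space centroid is not a
physical conformation that can be docked into. Because QT needs pairwise
distances, the similarity defaults to pairwise superposed heavy-atom RMSD;
a 1-D reference-RMSD mode (`referenceRMSD()`) is provided for
trajectory-from-equilibrated-structure descriptions.

### Symmetry-aware pose RMSD and leader clustering

Pose RMSD aligns the receptors on Cα atoms, applies that transform to the
second pose's ligand, and takes the no-fit RMSD over a declared atom
subset. For a C2-symmetric ligand the subset is the heavy atoms on the
symmetry axis, so a 180° flip is invisible (< 1e-6 Å) and symmetric poses
are not double-counted, while the full-atom RMSD of the same flip exceeds
1 Å. Pose clustering is *leader* clustering anchored at the best-ranked
unassigned pose (cutoff 1.5 Å) rather than QT, because the selection
procedure is defined relative to the best-ranked pose. Whether the
published 1.5 Å cutoff meant leader distance or complete-linkage diameter
is not stated; leader semantics follow the phrasing.

## The synthetic study system

`makeToyComplex()` builds the ground-truth fixture every stage is tested
against:

- **Receptor:** 8 methyl-probe pseudo-residues (CA backing atom, CM methyl
  carbon, HM pseudo-proton pointing at the pocket centre) on a spherical
  cap of radius 6.5 Å, backed by a wall of blocker carbons at +2.5 Å; one
  `surface` probe near the rim and one distant `outlier` probe emulate the
  surface-contact and spin-diffusion-artifact roles in the residue-label
  logic.
- **Ligand:** a phenol-like C2-symmetric template (ring + hydroxyl on the
  two-fold axis; symmetry atoms C1/C4/O1) or an asymmetric chloro variant.
- **True pose:** a seeded random proper rotation at the pocket centre.
- **NOE table:** fabricated by classifying true effective interproton
  distances with the same 2.8/3.5/5.0 thresholds used for calibration, so
  the true pose satisfies its own restraints exactly at zero noise — the
  self-consistency invariant the tests assert. Optional class noise
  (misclassification by one level, boundary classes flipping inward)
  emulates spin-diffusion artifacts.

The pocket radius (6.5 Å) was chosen so that every fabricated restraint is
geometrically satisfiable at the truth with margin: probe pseudo-protons
sit ≥ 1.9 Å (> 1.8 Å contact) from the nearest ligand proton, probe
carbons clear the soft-steric limit, and the per-residue 5.0 Å AIRs are
satisfied at the true pose for any rotation.

What the toy system does *not* emulate: real side-chain flexibility,
anisotropic cavity shapes, solvent, spin diffusion beyond simple
misclassification, or receptor conformational change on binding. Passing
tests therefore demonstrate the correctness of the pipeline's logic and
statistics, not the accuracy of any particular protein prediction.

## Problem sizes and defaults

Production-scale defaults are kept where they are pure bookkeeping
(15 bins, 8 walkers/bin, 1000 poses/conformation, 2 Å QT radius, 1.5 Å
pose cutoff, top-4 ranking, 0.3 Å tolerance). The validation runs use
desk-scale sizes chosen once as the package's own study conditions: the
double-well WE runs use 220–300 iterations of 25–30 steps at dt = 0.005
with 8 seed replicates; ensemble-docking validation uses 2 receptor
conformations (original + 0.05 Å jitter) × 150 poses at a 200-evaluation
minimizer budget over 20 seeded complexes; the 10 × 1000 = 10,000-model
bookkeeping run uses a 12-evaluation budget. The acceptance script
(`scripts/acceptance.R`) recomputes all headline quantities from scratch at
these sizes.

## Numerical choices and degenerate inputs

- Kabsch superposition corrects the rotation determinant, so mirror images
  retain a positive residual; < 3 points or mismatched counts are errors.
- `effectiveDistance()` rejects coincident atoms (d = 0) rather than
  returning an infinite penalty.
- MAB with all-equal progress coordinates produces a symmetric ε-width
  layout instead of dividing by zero; the single lagging/leading walkers
  are identified by first index on ties.
- An empty final pose set after the violation filter is a reported outcome
  ("no poses passed the 0.3 Å filter"), not an error.
- PDB coordinates are written at 3 decimals; round trips are exact at that
  precision, and pipeline manifests hash every output so reruns can be
  verified byte-identical.

## Known limitations

- The docking score has no electrostatics, desolvation or ligand
  flexibility; it is a selection signal, not an energy function.
- The WE sampler is serial and in-memory; no recycling boundary conditions
  or flux/rate estimates (none are needed for cavity-openness sampling).
- Heavy-atom +1 Å bounds are geometrically loose for arbitrary pseudo-proton
  placements; the pipeline's violation filter therefore runs on the
  interproton restraints, with the heavy-atom set exported for
  interoperability (CNS-style `assign` blocks).
- mmCIF, insertion codes, altLoc ensembles and multi-model NMR PDB files
  are out of scope for the reader.
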