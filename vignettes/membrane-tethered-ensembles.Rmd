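---
title: "Modelling membrane-tethered kinase positioning with memtether"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane-tethered kinase positioning with memtether}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`memtether` treats a multidomain protein assembly as rigid bodies joined
by intrinsically disordered regions (IDRs), sitting on a flat membrane.
The membrane is the plane z = z0 (normal along +z by convention, z0 = 0 by
default); the allowed half-space is z > z0.  Three computational
primitives carry the whole protocol.

**Chain growth.**  IDR segments are modelled as kinematic chains of ideal
backbone geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, standard
angles; trans peptide bonds, omega = 180°; cis-proline is not sampled).
Per-residue (phi, psi) pairs are drawn from a four-class coil library
(generic, glycine, proline, pre-proline).  Fragments of 5 residues are
assembled hierarchically: pairs of partial products are merged by exact
superposition of the backbone triad of their one shared residue, and a
merge that creates a steric clash, dips below the membrane, or hits the
static context is resolved by redrawing the mobile child (30 retries per
merge).  This local-resampling hierarchy is what makes self-avoiding
chains of 500+ residues affordable, and — importantly — its coarse
granularity preserves the entropic repulsion of a wall-confined chain:
conformations that approach the membrane are regenerated in large pieces,
as full rejection sampling would do, rather than locally patched.

**Rigid-body grafting.**  A folded unit is attached by mapping the
backbone triad of a single boundary residue exactly onto its counterpart
in the chain; the body's copy of the shared residue is dropped and the
body then moves with all downstream hinges.  With this convention the
graft is exact by construction (overlap RMSD 0): the overlap region
adopts the rigid body's conformation, which is how fragment-assembly
pipelines attach predicted domains.  A least-squares mode
(`attach_rigid_body(method = "lsq")`) is available for imported models
whose overlap conformation should be fitted rather than imposed.

**Stochastic CCD.**  Anchoring is performed by cyclic coordinate descent
in its stochastic small-rotation form: draw a residue uniformly among the
rotatable hinges, a dihedral kind uniformly in {phi, psi}, and a rotation
from Normal(0, sigma²) with sigma = 1°; accept the move only if the
effector objective strictly decreases (ties rejected) and no new
protein–protein clash appears.  The membrane is not part of the CCD clash
test; half-space violations are handled by the surrounding acceptance
steps.  Objectives are root-mean-square residuals over the effector
atoms: distance to paired points, |z − z0| to a plane, or RMSD to paired
reference coordinates compared in the common frame (no re-superposition).
Convergence requires every effector within 5 Å of the plane (plane mode)
or RMSD < 0.6 Å (alignment mode).  Because accepted moves are pure hinge
rotations, bond lengths and angles are preserved to floating-point
accuracy, and the objective trace is monotone non-increasing by
construction.

## The staged ULK1C protocol

The packaged preset (`ulk1c_preset()`) expresses the assembly logic of
the ULK1 complex on a membrane:

1. **Scaffold.**  The ATG13 IDR (residues 230–363, author numbering
   preserved throughout) grows from the HORMA-dimer stub; the ULK1C core
   is grafted at residue 362.  Candidates whose two EAT cysteine sulfurs
   (tags `C927:SG`, `C1003:SG`) lie within 20 Å of the headgroups enter
   plane-mode CCD over three anchors — both sulfurs plus the FIP200 arm
   tip, which must lie flat on the bilayer — until all three are within
   5 Å of the plane.  Because CCD is membrane-blind, a converged scaffold
   can end up swung below the plane; scaffolds whose ULK1 tether point
   ends below the membrane, or whose frozen chain occludes the
   bound-pose junction, are rejected (they could not host any later
   stage).  Accepted scaffolds additionally pass a bound-state
   feasibility probe — a bounded number of candidate growths and
   junction closures must produce at least one closed bound candidate —
   so that every reported replica supports both conditions at workable
   sampling rates.
2. **Unbound ensemble.**  The ULK1 IDR (residues 277–831) is tethered at
   its C-terminal end to the EAT attachment point on the core, with the
   KD grafted at boundary residue 283 (the KD body supplies residues
   1–282, its overlap stub covering 277–283).  Acceptance: clash-free
   against the scaffold, entirely above the membrane.
3. **Bound ensemble.**  The ULK1 428–450 pose is placed by superposing
   the HORMA body onto the scaffold's HORMA frame.  Fresh candidate
   chains over residues 428–831 are grown toward the placed pose (see
   sampling notes), must satisfy the binding-site proximity rule
   (minimum CA distance of the bound segment to the `HORMA_site`
   centroid at most `d_bind`), are truncated after residue 449, and the
   junction residue 450 is closed onto the pose by alignment CCD
   (< 0.6 Å backbone RMSD).  Finally residues 277–428 are resampled from
   the pose's residue-428 triad with the KD attached, under clash and
   half-space acceptance.

The KD–membrane distance of a member is the height of the mass-unweighted
centre of the KD backbone heavy atoms above the plane, reported in nm
(Å internally; the conversion is centralized in the analysis module).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| CCD sigma | 1 | degrees | stated move size of the stochastic CCD variant |
| plane anchor tolerance | 5 | Å | termination: anchors near the headgroup height |
| alignment threshold | 0.6 | Å RMSD | junction closure on backbone heavy atoms |
| fragment length / overlap | 5 / 1 | residues | fragment-assembly practice; library-agnostic |
| clash cutoff | 2.5 | Å | permissive backbone-level excluded volume |
| d_mem | 20 | Å | pre-CCD filter: SG anchors near the membrane |
| d_bind | 45 | Å | candidate proximity filter (see below) |
| n, replicas | 100, 3 | — | ensemble size per condition per scaffold |

`d_bind` deserves a note: the proximity filter exists only to bound the
CCD workload — the final junction geometry is fixed by the 0.6 Å
alignment threshold regardless.  With the desk-scale fixtures the
probability that a free 400-residue chain spontaneously places the bound
segment within 15 Å of the site is of order 10⁻³–10⁻⁴ per candidate, so
the default admits candidates whose junction approaches within a few
HORMA diameters (45 Å) and lets CCD do the closing.

## The coil library

The packaged default (`extdata/coil_library.yaml`) spans the beta,
polyproline-II, alpha-R and alpha-L basins with class-specific maps for
glycine, proline and pre-proline residues.  Basin weights were fixed by
requiring that free chains sampled with excluded volume reproduce the
experimental dimensions of denatured and disordered proteins (the Kohn
scaling law, Rg ≈ 1.93 N^0.598 Å): at N = 555 the sampler gives a
root-mean-square end-to-end distance of ~203 Å against a scaling-law
expectation of ~207 Å.  The library is a documented stand-in for
MD-derived fragment libraries and is user-replaceable through
`read_dihedral_library()`; the protocol's logic is library-agnostic.

## Synthetic fixtures: what they emulate, and what they do not

All rigid bodies are idealized stand-ins built from helix bundles,
strands and CA shells, with deterministic geometry:

* the **core** carries the two SG anchors and the arm tip near-coplanar
  on its membrane face, the ATG13 overlap stub outboard of the bundle,
  and the EAT helix oriented so the ULK1-IDR tether point (residue 831)
  sits ~22 Å above the contact face — the EAT/MIT tandem is about 25 Å
  tall with its palmitoylatable cysteines facing the membrane and the
  IDR leaving from the distal face;
* the **HORMA dimer** rests on a ~10 Å pedestal above the headgroups,
  representing the membrane-inserted WIPI ring that carries it (the
  WIPIs themselves are not modelled);
* the **KD** is an 80-atom CA shell of radius 16 Å (the dimensions of a
  ~280-residue kinase fold) with an extended overlap stub;
* the **bound pose** is a 23-residue backbone lying flat beside the
  binding-site tag in the HORMA frame.

The packaged IDR sequences are composition-matched synthetic stand-ins of
the exact segment lengths (134 and 555 residues; Pro/Ser-rich,
aromatics-poor).  Ensemble statistics in this package depend on segment
length and Gly/Pro class content, which the stand-ins match — not on
sequence identity or fold detail.  Consequently, passing tests show that
the *protocol* behaves correctly (anchoring, filtering, closure,
tether-statistics scaling); they do not validate atomic detail of any
real structure, nor interaction specificity, which would require the
predicted models this package accepts as PDB input.

## Numerical and design choices

* Angles are stored in degrees in (−180, 180]; torsion measurement wraps
  at ±180 (circular comparisons via `angle_diff()`).
* Clash exclusions are intra-rigid-body pairs and same-chain residues at
  most two apart; the two-residue margin also covers the covalent 1–3
  pairs running through a grafted junction residue, without which the
  junction-aligned bound state would be misclassified as clashing.
* Residue and dihedral-kind draws in CCD are uniform (the stochastic
  variant leaves this open; uniform is the natural choice).  Hinge moves
  that move nothing (e.g. phi at a pinned terminus) are drawn and
  rejected like any non-improving move.
* Rejected CCD moves have zero side effects; minimizations also stop
  after 10,000 consecutive rejections (a stalled descent reports
  `converged = FALSE` — non-convergence is a result, not an error).
* Bound-state candidates are generated toward the placed pose: growth
  enforces the proximity rule during assembly with local redraws, plus a
  reachability heuristic (2.5 Å per remaining residue) that redraws
  partial products whose free end could not plausibly bring the junction
  into range.  This steers only the candidate tail (residues 450–831,
  retained as excluded volume); the distance observable of a bound
  member is set by the resampled 277–428 tether and the KD, which are
  grown by the unbiased sampler.
* Whether candidates are drawn fresh or reused from the unbound pool is
  left open by the protocol; this implementation samples fresh candidates
  over residues 428–831 (residues below the truncation point are removed
  unused, so they are not generated).
* The exhaustive 5°-grid oracle for toy CCD problems is restricted to
  1–3 hinge dihedrals; a grid over every dihedral of even a 4-residue
  chain (72⁵ points) is combinatorially infeasible.
* Degenerate inputs raise typed conditions (`memtether_sampling_error`,
  `memtether_clash_error`) carrying stage diagnostics, so pipeline
  callers can resample rather than abort.
* A single root seed fans out to per-stage, per-replica seeds
  (`derive_seed()`), making any stage independently reproducible; all
  randomness, including in compiled code, flows through R's RNG.

## Problem sizes

The packaged preset uses 3 scaffold replicas and 100 members per
condition per replica — enough for stable ensemble means (standard error
of the pooled mean ≈ 0.4 nm, far inside the spread of the distributions
themselves) at desk scale.  The polymer reference checks
use 2,000 virtual-bond chains of 100 bonds; the library calibration uses
free 555-residue chains.

## Known limitations

* Backbone-plus-CB resolution; no side chains beyond CB, no hydrogens, no
  energetics, no solvent — excluded volume and geometry only.
* The membrane is a hard plane: no curvature, no insertion depth, no
  lipid detail.
* Hierarchical local resampling approximates, not exactly reproduces,
  rejection sampling of the constrained ensemble; its granularity
  (fragment pairs) is part of the method definition.
* The scaffold is frozen during the ULK1-IDR stages; mutual relaxation of
  ATG13 and ULK1 chains is out of scope.
* Reported distances inherit the idealized fixture geometry; absolute
  numbers shift at the ~10–20% level with the (documented) anchor
  heights, and should be read as ensemble statistics of the tether
  model, not structure predictions.
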