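---
title: "Predicting small-molecule binding patches at protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting small-molecule binding patches at protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindpatch)
```

## The problem and the model

A protein–protein (PP) binding interface is usually much larger than the
footprint of a small-molecule ligand. When a ligand binds on top of such
an interface — competing with the partner protein — it engages only a
sub-region of it. `bindpatch` models the residue-level distinction
between that sub-region (**overlap**, O) and the remainder of the
interface (**non-overlap**, N) as a supervised binary classification
problem, and aggregates residue calls into surface patches to report
candidate small-molecule binding sites.

The model rests on three assumptions:

1. **Competitive-binding labels are transferable.** If a homologous
   protein (≥ 40 % sequence identity) is crystallised with a ligand at
   the corresponding surface region, and that ligand — superposed into
   the PP frame — clashes sterically with the partner protein, then the
   aligned interface residues it touches are genuine O labels.
2. **O and N residues differ in local structure and evolution.** O
   residues tend to sit in concave, densely packed, solvent-occluded and
   evolutionarily conserved parts of the interface; the 13 features are
   different operationalisations of exactly those tendencies.
3. **O regions are spatially coherent.** A single ligand contacts a
   connected set of residues, so neighbouring predictions carry
   information; this is why patch-level voting improves over
   single-residue calls and why the classifier includes neighbour
   features at all.

## The pipeline

For a query PP complex the pipeline is: solvent accessibility →
surface/interface definition → five per-residue quantities → 13-feature
vectors → balanced random-forest vote → patch aggregation.

### Interface and surface definitions

A residue of the query chain is an *interface* residue when its minimum
heavy-atom distance to the partner is at most the interface cutoff, and
it is a *surface* residue of the isolated chain. Distances use heavy
atoms only; hydrogens are discarded at parse time, and alternate
locations resolve to the highest-occupancy conformer (ties: first in
file). The surface filter is applied to the query side only; the partner
contributes all of its heavy atoms.

Surface status is defined as relative SASA ≥ 5 % in the isolated chain.
The 5 % value is the conventional low bar for "has any meaningful
exposure"; it is a configurable parameter
(`rel_sasa_threshold`), and results are insensitive to it on the package's
fixtures because pseudo-protein slabs have no deeply buried surface-layer
residues.

### The five per-residue quantities

* **Protrusion index** (`protrusion()`): for each atom,
  `cx = V_empty / V_atoms` inside a 10 Å sphere centred on the atom,
  where `V_atoms` is the *union* volume of all heavy-atom spheres
  intersecting the neighbourhood and `V_empty` the rest of the sphere.
  The residue value is the mean over its atoms. Two interpretation
  choices were genuinely open and are fixed as follows: the union (not
  the sum) of atom volumes is used, so overlapping atoms are not double
  counted; and the central atom itself counts toward `V_atoms`, so an
  isolated atom has a large finite cx rather than a division by zero.
* **Contact density** (`contact_density()`):
  `Σ_j contacts(atom_ij) / totalAtoms_i`, summing over the residue's
  surface-accessible heavy atoms j (atom SASA > 0 in the supplied
  context) and counting same-chain heavy atoms of other residues within
  5 Å. The denominator is the residue's *total* heavy-atom count — the
  formula's literal reading — rather than the count of accessible atoms.
* **Surface fraction** (`surface_fraction()`): residue SASA in the
  complex divided by the residue type's reference area, clipped to
  [0, 1]. The reference is the central residue of an extended Ala-X-Ala
  tripeptide, computed by the same SASA engine on an internal synthetic
  template (ideal extended backbone plus a side-chain pseudo-atom chain
  sized by the residue type's heavy-atom count). The template is not a
  rotamer-accurate side chain; what matters is that reference and query
  areas come from the same engine so the ratio is well defined and equals
  1 for the free tripeptide.
* **Conservation** (`load_conservation()`): normalised evolutionary
  rates are *ingested*, not computed — either a plain TSV or the
  ConSurf-DB grade-file dialect. Negative scores mean conserved. More
  than 20 % unmatched residues is treated as a numbering mismatch and is
  a hard error; individual missing scores are imputed as 0 (the
  normalised mean) with a warning.
* **Hot spots** (`predict_hotspots()`): the published knowledge-based
  predictors this feature family comes from are accessibility-plus-
  packing rules, so the package ships a configurable surrogate in that
  family: a residue is flagged when its in-complex relative SASA is
  ≤ 20 % *and* its contact density is at least the chain median plus
  0.5 × IQR. Both thresholds are parameters, and a user label file
  overrides the surrogate entirely. The surrogate is a stand-in by
  design; treat externally computed hot spots as the preferred input
  when available.

### Feature vectors

Per interface residue: `surfaceFraction` and `density` of the residue
itself; `protru1..5` and `cons1..5` for the residue and its four nearest
surface residues (Euclidean Cα distance, ties broken by chain/residue
order, index 1 = the residue itself); and `hsfPatch8`, the hot-spot
fraction of its size-8 surface patch. Patch members outside the
interface count as non-hot-spots, since hot-spot status is defined on the
interface.

### Surface patches

`build_patch()` implements the centre-of-mass/solvent-vector
construction: the pre-patch (central residue + n−1 nearest surface
residues, Cα distances) defines a centre of mass; every surface residue
gets a solvent vector Cα − COM; the final patch keeps the central
residue plus the closest n−1 surface residues whose solvent-vector angle
to the central one is within 110°, a bound closed at both ends. Two
details were open and are fixed as: candidates for the final patch are
drawn from the whole surface set (not just the pre-patch), and the angle
filter is applied before the distance ranking. A central residue whose
Cα coincides with the pre-patch COM has no defined solvent vector; the
patch is marked degenerate and skipped with a warning.

### The balanced ensemble

`brf_train()` fits K random forests (default K = 1000; 500 trees,
`mtry = floor(sqrt(13)) = 3`, Gini splits, unpruned — the standard
defaults of the underlying implementation). Each member trains on every
minority-class row plus an equal-sized majority-class draw *without*
replacement; the ensemble prediction is a majority vote over members,
with the vote fraction reported per residue. Two aggregation choices
were open: the K draws are combined into one voting ensemble (rather
than averaged as K separate evaluations), and an exact 0.5 vote tie goes
to N, the conservative class. Member-level tree-vote ties also resolve
to N — this keeps `predict()` fully deterministic, where the underlying
library would break ties randomly.

Permutation feature importance (`brf_importance()`) is computed on a
user-supplied held-out set rather than out-of-bag: with K balanced
ensembles there is no single OOB sample, and an explicit evaluation set
makes the quantity reproducible and implementation-independent.

Training pools residues across complexes. Pooling leaks homology between
training and evaluation residues of related complexes; for honest
evaluation keep complete complexes (e.g. by `pair_id`) out of training,
as the end-to-end tests do.

### Patch voting and reported sites

`predict_binding_patches()` reports size-7 patches whose central residue
is predicted O and that contain at least 5 predicted-O members, sorted by
O ratio. `patch_precision_by_ratio()` measures, on labelled data, the
fraction of true-O centres among O-centred patches per vote bin — the
curve that justifies the 5-of-7 default: precision rises steeply with the
O ratio.

## Building training data

`make_pair()` runs the full pair validation: alignment (Needleman–Wunsch,
BLOSUM62, gap open 10/extend 0.5 — standard protein-alignment settings),
the ≥ 40 % identity gate (computed over alignment columns), interface
detection on both sides, overlap labelling (≥ 2 shared residues), Kabsch
superposition on aligned Cα pairs (with the SVD determinant correction,
so reflections are never returned), and the steric collision gate
(strict inequality: a pair at exactly the radius sum is not a clash).
Rejections carry one of three mutually exclusive reasons:
`low_identity`, `insufficient_overlap`, `collision_free`.
`reduce_redundancy()` replaces an external clustering tool with a greedy
scheme (longest reference sequence seeds a cluster, members join at
≥ 40 % identity), drops clusters whose every partner is a peptide
shorter than 5 residues, and keeps the member with the highest
interface-residue identity per cluster.

## What the synthetic fixtures emulate — and what they do not

`make_pocket_complex()` builds a two-layer pseudo-protein slab (chain A,
one Cα + one Cβ-like atom per residue) facing a partner slab across a
~4.3 Å gap, with a 2×2 concavity (default depth 2 Å) at the interface
centre. A partner "plug" residue protrudes into the pocket — the loop
the ligand competes with — so the pocket lining belongs to the PP
interface, and the planted ligand occupies the same pocket, touching the
pocket lining and ring (the ground-truth O set, 12 residues by
construction) and clashing with the plug after superposition. Variants
place the ligand at the interface rim (touches ≥ 2 interface residues
but cannot clash → rejected `collision_free`) or on the back face (no
interface overlap → rejected `insufficient_overlap`); a zero-depth
pocket degrades to the rim case. The PL copy carries a seeded rigid
transform so the superposition step is genuinely exercised, plus 0.08 Å
coordinate jitter so fixtures differ across seeds.

`make_feature_table()` draws the 13 features from class-conditional
Gaussians with the O-class mean shifts configured in `effect_sizes()`:
conservation, protrusion and surface fraction shifted down, contact
density up by 0.97 contacts/atom, and hot-spot frequencies of 48 %
(O) vs 37 % (N) — the directions and magnitudes characteristic of real
overlap regions — at a default 377:1623 class imbalance (~1:4.3) per
2000-residue table. `make_sphere_cloud()` places residues on a Fibonacci
sphere with contiguous O caps, giving label-coherent geometry for patch
benchmarks; `make_ring()` gives exact closed-form patch geometry.

What passing tests on these fixtures shows: the geometry engines match
their closed forms, the labelling/filter logic implements its
definitions exactly, and the learning-and-voting machinery recovers
planted class structure of realistic effect size under realistic
imbalance. What it does not show: performance on real PDB complexes —
pseudo-proteins have no side-chain chemistry, no real packing
heterogeneity, and feature tables drawn from Gaussians have none of the
correlated, heavy-tailed structure of real descriptors. Accuracy numbers
on fixtures are therefore upper bounds of convenience, not performance
claims.

## Numerical choices

* **SASA**: Shrake–Rupley sphere sampling with a deterministic Fibonacci
  point lattice, probe 1.4 Å, 960 points/atom. Deterministic points make
  areas reproducible to the bit; 960 points put the single-sphere error
  well under 1 %.
* **Protrusion volumes**: uniform voxel grid centred on the query atom,
  default spacing 0.25 Å, with a linear antialiasing ramp one voxel wide
  at every sphere boundary. Hard in/out voxel counting carries a
  lattice-alignment bias of several percent on atom-sized spheres
  regardless of spacing parity; the ramp removes it (closed-form error
  ≈ 0.3 % at 0.25 Å) and halving the spacing roughly halves the residual
  error. Coarser grids remain available via `grid_spacing`.
* **Distance ties** (nearest residues, patch membership): broken by
  (chain, residue number, insertion code) order, so results are
  independent of input row order.
* **Collision**: strict `d < r_i + r_j`; the boundary case is not a
  clash.
* **Vote ties**: to N at both the member and the ensemble level (see
  above).
* **Degenerate inputs**: empty interfaces predict nothing with a
  warning; < 3 or collinear Cα pairs are superposition errors; zero-atom
  residues are SASA errors.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use: K = 20 members on
2000-residue feature tables for classifier recovery (held-out accuracy,
class-error gap, null baseline), 2500-residue sphere clouds (≥ 500
O-centred patches) for the patch-precision curve, five pocket fixtures
(~25 interface residues each) for end-to-end training, and one held-out
fixture for patch recovery. These sizes were chosen to make every
statistical check well-powered at desk scale; K and all table sizes are
parameters, and the method default K = 1000 is unchanged.

Monotonicity of the patch-precision curve is asserted between adjacent
vote bins within 1.96 pooled binomial standard errors: bin precisions
are proportions of finite samples, and the check must not flag ordinary
sampling noise in near-empty bins as a trend violation.

## Known limitations

* The hot-spot surrogate is a two-threshold rule, not a reimplementation
  of any published predictor; supply real hot-spot labels when you have
  them.
* The tripeptide reference areas use synthetic extended templates, so
  absolute surface fractions for large aromatic side chains are
  approximate (ratios remain well behaved and bounded).
* Sequence-redundancy reduction is greedy single-pass clustering —
  adequate at desk scale, not a replacement for dedicated tools on
  thousands of sequences.
* First NMR model only; no assembly generation from symmetry operators;
  mmCIF only insofar as the underlying parser handles it.
* Training pools residues across complexes by default (see above);
  group-aware splitting is the user's responsibility via `pair_id`.
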