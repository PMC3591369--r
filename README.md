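# bindpatch

Predicting where small molecules bind at protein–protein interfaces.

Small molecules that bind *on top of* a protein–protein binding interface
can block (or stabilise) the interaction, which makes parts of some
interfaces attractive drug-design targets. Only a sub-region of a typical
protein–protein (PP) interface is competent to bind a small ligand,
though. `bindpatch` addresses the question: **given the structure of a PP
complex, which interface residues would a small-molecule ligand most
likely engage?**

The package is aimed at structural bioinformaticians working on
protein–protein interaction inhibitors: it provides both the trained-model
workflow (features → classifier → patch vote) and the data machinery to
build labelled training sets from structure pairs.

## Method

Training data come from **PP:PL pairs**: a PP complex (reference protein
P1 bound to partner P2) matched with a protein–ligand (PL) complex whose
protein P3 shares ≥ 40 % sequence identity with P1. Interface residues are
defined by a 5 Å minimum heavy-atom distance. Mapping the PL interface
onto the PP interface through a global sequence alignment labels each PP
interface residue

- **O (overlap)** — contacts the partner protein *and*, via the aligned
  position, the ligand, or
- **N (non-overlap)** — contacts the partner protein only.

Pairs are kept only when ligand and partner actually compete: P3 is
superposed onto P1 (Kabsch, Cα atoms of aligned columns) and the mapped
ligand must clash sterically with P2 (some heavy-atom pair closer than the
sum of the van der Waals radii). Pairs with fewer than two overlap
residues are discarded, and redundancy is removed by greedy sequence
clustering at 40 % identity.

Each interface residue *i* is described by 13 features built from five
per-residue quantities:

| quantity | definition |
|---|---|
| protrusion index | cx = V_empty / V_atoms in a 10 Å sphere around each atom; residue value = atom mean. 0 = buried, large = protruding |
| contact density | Σ_j contacts(atom_ij) / totalAtoms_i over surface-accessible atoms j, contacts = same-chain heavy atoms within 5 Å |
| surface fraction | SASA(residue, in complex) / SASA(residue centred in an extended Ala-X-Ala tripeptide) |
| conservation | normalised evolutionary rate (negative = conserved), ingested from ConSurf-style files |
| hot-spot flag | knowledge-based binary flag (occlusion + packing surrogate, or user-supplied) |

The feature vector combines the surface fraction and contact density of
the central residue, the protrusion and conservation of its five nearest
surface residues (the residue itself first), and the hot-spot frequency in
its size-8 surface patch (`hsfPatch8`).

Because N residues outnumber O residues roughly 4:1, the classifier is an
ensemble of **K class-balanced random forests**: each member trains on all
minority-class residues plus an equal-size majority-class draw, and the
final call is a majority vote (vote fraction > 0.5 → O). Predictions are
aggregated spatially with **surface patches** (central residue + nearest
neighbours whose solvent vectors lie within 110° of the central one):
size-7 patches with an O-predicted centre and ≥ 5 predicted-O members are
reported as likely small-molecule binding patches.

## Worked example

Everything below runs offline on the package's deterministic synthetic
fixtures (a pseudo-protein complex with a concave interface pocket and a
planted ligand).

```r
library(bindpatch)

## build a labelled PP:PL pair from the pocket fixture
pc   <- make_pocket_complex(seed = 1)
pair <- make_pair(pc$pp, "A", "B", pc$pl, "A", pair_id = "pocket_demo")
pair
#> PP:PL pair pocket_demo
#>   identity 1.00 | overlap 12 | non-overlap 13 | rmsd 0.20 A
```

The pair is accepted: the reference chains align at 100 % identity, 12 of
the 25 PP-interface residues also contact the ligand, and the superposed
ligand clashes with the partner chain (competitive binding).

```r
## train and evaluate the balanced ensemble on synthetic feature tables
train <- make_feature_table(seed = 1)   # 377 O + 1623 N (~1:4.3)
test  <- make_feature_table(seed = 2)
fit   <- brf_train(train, K = 20, seed = 1)
fit
#> Balanced random-forest ensemble
#>   members: 20  trees/member: 500  mtry: 3
#>   balanced training rows per member: 754 (of 2000 total)

evaluate_overlap_prediction(predict(fit, test), test$label)
#>    tp  fp fn   tn accuracy error_o error_n    n
#> 1 312 281 65 1342    0.827   0.172   0.173 2000
```

Held-out accuracy is 82.7 % with the two class error rates balanced at
~17 % each — the point of the down-sampling ensemble, which would
otherwise be swamped by the majority class. `glance(fit)` and `tidy(fit)`
summarise the ensemble; `brf_importance()` + `plot_importance()` give
permutation feature importances, and `patch_precision_by_ratio()` +
`plot_patch_precision()` show how patch precision climbs with the
predicted-O fraction.

```r
## end to end: predict binding patches on a new complex
res <- predict_interface_overlap(fit, pc$pp, "A", "B",
                                 conservation = make_fixture_conservation(pc))
res$patches[, c("central", "n_overlap", "ratio")]
```

Each reported row is a size-7 surface patch whose centre is predicted
overlap with at least 5 overlap votes — the predicted small-molecule
binding site.

A command-line interface with the same functionality (subcommands
`features`, `train`, `predict`, `pair`, `fixtures`) is installed under
`inst/cli/bindpatch`.

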