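---
title: "Methods: structure-based pharmacophore screening for dual kinase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based pharmacophore screening for dual kinase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
library(dplyr)
```

# The problem

Type II kinase inhibitors bind the DFG-out inactive conformation of a
kinase, anchoring to the hinge region through backbone hydrogen bonds,
threading the gate area past the conserved alpha-C glutamate and DFG
aspartate, and burying a hydrophobic group in the allosteric back
pocket. Because this geometry is conserved across kinases, a single 3D
arrangement of chemical features — a *pharmacophore* — can describe
active chemotypes for two different kinases at once, which is the basis
of dual-target screening campaigns against pairs such as VEGFR2 and
FAK, whose kinase domains align closely at the hinge
(Cys919/Cys502), the DFG motif (Asp1046/Asp564) and the alpha-C
glutamate (Glu885/Glu471).

`pharmscreen` implements the desk-scale machinery of such a campaign:
pharmacophore models with excluded volumes, feature perception on 3D
conformers, a matching engine, the enrichment metric battery used for
model selection, the lead-likeness filtration cascade applied to raw
virtual-screening hits, BOILED-Egg ADME classification, geometric
validation of the type II interaction pattern in docked poses, and
local sequence alignment of kinase domains. Every stage can be
exercised on synthetic inputs generated in-package, so the whole
pipeline is testable without databases, a docking engine, or downloads.

# The pharmacophore model and the matcher

A model is a set of typed features — hydrogen-bond acceptor (`ACC`),
donor (`DON`), projected donor (`DON_PROJ`, a point 2.8 Å along the
D–H direction marking where the receptor acceptor sits), aromatic ring
centroid (`ARO`) and hydrophobic group centroid (`HYD`) — each with a
center, a radius and an *essential* flag, plus excluded-volume spheres
marking receptor-occupied space. Matching a conformer proceeds in three
stages:

1. **Correspondence prefilter.** Every assignment of essential features
   to distinct perceived points of the same kind is enumerated
   depth-first, pruning any partial assignment whose pairwise point
   distances deviate from the model's inter-feature distances by more
   than `pair_tol` (default 1.0 Å). Optional features are appended
   greedily where a compatible unused point exists; they are reported
   but never gate acceptance and never enter the score, since screening
   compounds may or may not present them.
2. **Least-squares alignment.** Each surviving correspondence is
   superposed onto the model by the Kabsch algorithm; the fitness is
   the RMSD over essential pairs. Poses above `rmsd_cutoff` (default
   1.2 Å) are rejected. The default is permissive relative to the
   sub-0.5 Å fits reported for co-crystallised reference inhibitors,
   but bounded well below the feature radius.
3. **Excluded-volume check.** A pose is rejected if any transformed
   heavy-atom center (for feature-cloud fixtures: any point) lies
   strictly inside an exclusion sphere.

Ties between equal-RMSD candidates are broken by more matched optional
features, then by lexicographically smaller mapping, making results
deterministic. For up to five essential features and eight points the
engine is tested for exact agreement with brute-force enumeration over
all type-respecting injections, and for invariance of everything except
the reported transform under rigid motion of the conformer.

The matcher deliberately accepts pre-perceived feature sets directly.
This is what makes the engine testable without real actives: inverse
design of a molecule matching a given pharmacophore is intractable,
whereas planting a noisy copy of the feature geometry is exact.

# Feature perception

Perception rules live in an editable dictionary
(`inst/extdata/feature_rules.tsv`), not in code: acceptors are N/O
atoms with an available lone pair (amide nitrogens and pyrrole-type
aromatic N–H excluded), donors are N–H/O–H heavy atoms, aromatic
features are ring centroids from the toolkit's ring perception, and
hydrophobic features are centroids of contiguous groups of at least
three apolar carbons, with halogens on those carbons included — so a
chloro-trifluoromethyl-phenyl moiety contributes a single hydrophobic
centroid, the behaviour expected for type II back-pocket groups.
Whether an aryl hydrophobe is better represented by its ring centroid
or substituent centroid is not settled usage; both are expressible by
editing the dictionary. Points are sorted deterministically by kind and
position, which makes perception invariant to input atom order.

# Receptor-based model derivation

`derive_model()` reproduces the receptor-based workflow: across a set
of pre-superposed complexes, ligand-side interaction points (acceptors
near protein donors, donors near protein acceptors with their
projections, hydrophobic group centroids in apolar contact, buried
aromatic centroids) are clustered per kind by single linkage at 2.0 Å;
clusters present in at least `min_share` of the complexes become
features. Features shared by all complexes are essential, others
optional; if fewer than three clusters are fully shared, the three
widest-shared are promoted so the model stays matchable. Binding-site
heavy atoms within 8 Å of any ligand become exclusion spheres (1.2 Å
radius), except those overlapping a feature center — the receptor atom
behind a projected donor would otherwise veto every correctly mapped
pose.

# Model assessment and selection

Screening a labelled test set yields TP/FP/TN/FN, from which the
package computes sensitivity, specificity, yield of actives
(Ya = TP/(TP+FP)), enrichment (E = Ya·N/A), accuracy, discrimination
ratio (DR = Se/Sp) and F1 — all as exact ratios of integers, rendered
to two decimals by round-half-away-from-zero only at output time, so
borderline cells such as 76/160 = 0.475 → 0.48 are well defined. A
strict truncation rendering is also available. Ranking uses exact
rational comparison, so models whose rounded F1 ties are still ordered
correctly, and each model is annotated as balanced, biased toward
actives (specificity below 0.5: it accepts nearly everything) or biased
toward decoys (sensitivity below 0.5).

The package ships transcriptions of two published kinase
model-assessment tables (20 VEGFR2 models against 40 actives/1200
decoys; 14 FAK models against 17 actives/983 decoys) as
`assessment_counts()`. Recomputing them exposed a transcription quirk
worth documenting: the FAK table's `N` column is TP+FP and all its
cells follow the standard formulas, whereas the VEGFR2 table's `N`
column equals TP+FP+FN (hits plus missed actives) and its printed Ya
and E cells use that `N` as denominator. `compute_metrics()` therefore
exposes `ya_denominator = "hits_plus_misses"` to reproduce such tables
verbatim; the default remains the standard definition, which also
matches the narrative enrichment quoted for the selected VEGFR2 model
(9.82 versus the printed 9.66). Two further internal inconsistencies of
the source tables are machine-checked in the test suite rather than
silently resolved: the VEGFR2 test set is described as 39 actives but
every row implies 40 (TP+FN = 40), and the model described as "third
best by F1" is in fact outranked by a fourth model under both exact
rationals and the printed cells.

# The filtration cascade

Raw virtual-screening hits pass through, in order: deduplication by
canonical SMILES; the screening window (350 ≤ MW ≤ 500 Da, rotatable
bonds ≤ 10); at most one Lipinski violation (violations: MW ≥ 500,
logP > 5, HBD > 5, HBA > 10 — the weight rule is "< 500", so exactly
500 Da violates); Veber (rotatable ≤ 10 and TPSA < 140 Å²);
toxicophore-clean; TPSA < 140 Å²; ESOL logS ≥ −5; the lead-likeness
bounds (MW ≤ 450, −3.5 ≤ logP ≤ 4.5, rings ≤ 4, rotatable ≤ 10,
HBD ≤ 5, HBA ≤ 8 — several variants of these bounds circulate, so they
are shipped as an editable ruleset); and PAINS-clean. Every stage is a
pure predicate of the descriptor row, so the surviving set is
independent of stage order and refiltering is idempotent; only the
per-stage removal counts depend on order (with both the Veber and TPSA
stages enabled, the polarity bound removes compounds at the Veber
stage). Boundary semantics are unit-tested at the exact cutoff values.

Descriptors come from the chemistry toolkit (OpenBabel molecular
weight, atomic-contribution logP, Ertl TPSA), from the molecular graph
(donor/acceptor counts as N–H/O–H and N+O, cyclomatic ring count,
aromatic heavy-atom fraction), and from SMARTS counts (rotatable bonds
as non-terminal acyclic single bonds minus acyclic amide C–N). The
toolkit exposes a single atomic-contribution logP, which the descriptor
set reports as both `clogp` and `wlogp`. Aqueous solubility is the ESOL
linear model on logP, MW, rotatable bonds and aromatic proportion, with
coefficients shipped as a data file. The PAINS and toxicophore alert
files are curated, clearly documented subsets of the published families
(the full published PAINS list runs to 480 patterns); both files are
plain TSV and swappable.

# ADME classification

The BOILED-Egg model classifies compounds in the TPSA × WLOGP plane:
inside the "white" ellipse predicts high gastrointestinal absorption,
inside the "yolk" predicts blood-brain-barrier permeation, and points
on a boundary are classified by the strict-interior rule. The ellipse
parameters shipped in `inst/extdata/boiled_egg_ellipses.tsv` are a
reconstruction of the published best-fit boundaries; the classifier is
tested for exact agreement with direct evaluation of those inequalities
on thousands of random points, so swapping in different parameters
preserves correctness.

# Type II pose validation

`validate_type2()` checks a docked pose geometrically rather than
re-docking: every configured key residue (hinge, DFG, alpha-C; shipped
specifications carry the VEGFR2 and FAK residue numbers) must make at
least one hydrogen bond with the ligand — donor–acceptor heavy-atom
distance at most 3.5 Å and D–H⋯A angle at least 120°, both
configurable, the angle waived when no hydrogen position is available,
as in heavy-atom-only crystal structures — and the ligand's apolar
carbons must make at least 3 contacts (C–C ≤ 4.5 Å) with hydrophobic
back-pocket residues. These criteria are conventional geometric
definitions; the original interactive modelling suite does not publish
its own. The validator only requires *some* qualifying donor toward the
alpha-C glutamate rather than specifically a urea N–H, since published
hit lists do not state which donor satisfied it.

# Sequence similarity

Kinase-domain similarity uses exact Smith–Waterman local alignment with
affine gaps (BLOSUM62, gap open 11, extend 1 — the common
protein-search defaults) in place of a heuristic database search tool;
identity and positives (columns scoring > 0, identities included) are
reported over the full alignment length including gap columns, the
conventional report format. Because the original tool's exact parameter
set is unpublished, identity/positives of real kinase-domain pairs
should be compared with published values only within a few percentage
points. The implementation is tested against an independent
dynamic-programming oracle on short sequences and on synthetic diverged
domains; real kinase-domain FASTA files are user-supplied inputs.

# Synthetic data: what it does and does not show

The generators provide every input the pipeline needs, with seeded
determinism and exact ground-truth bookkeeping:

* `gen_feature_fixtures()` plants actives as noisy, rigidly transformed
  copies of a model's feature cloud (defaults mirror the published
  test-set shapes, 40/1200 and 17/983, ≈30:1 decoy:active) plus
  distractor points placed in sterically allowed space; decoys either
  shuffle the geometry of a correct kind multiset or delete one
  essential feature. At 0.2 Å noise the default matcher recovers
  sensitivity and specificity above 0.9, and matched RMSDs concentrate
  near the planted-correspondence optimum.
* `gen_confusion_library()` draws Bernoulli hits at target
  sensitivity/specificity for metric-pipeline checks.
* `gen_toy_complex()` builds a minimal three-key-residue site plus
  ligand realizing a requested hydrogen-bond distance, angle and
  back-pocket contact count, with the expected validator verdict.
* `gen_property_library()` draws descriptor rows inside clean ranges
  and perturbs each to fail exactly its planned cascade stage.

Passing on these fixtures demonstrates the *algorithms* — the
correspondence search, the scoring, the bookkeeping, the boundary
semantics — under controlled geometry and descriptor distributions. It
does not demonstrate performance on real chemistry: real actives are
conformational ensembles whose feature clouds are correlated with
chemotype, real decoys are property-matched rather than geometry-
shuffled, and real descriptor distributions are far from uniform. The
shipped kinase model files are likewise labelled synthetic: their
feature inventories, essential flags and excluded-volume counts follow
the published model descriptions, but the 3D coordinates are
reconstructions at plausible type II site geometry, because the
original coordinates were never published.

# Numerical choices

* Metrics on exact rationals; 2 dp rendering round-half-away-from-zero,
  with a truncation mode for reproducing truncated tables.
* Kabsch superposition via SVD with determinant correction; degenerate
  (collinear) correspondences are rejected with an informative error.
* Hydrogen-bond boundary comparisons carry a 1e-9 guard so poses
  constructed exactly at a cutoff are not lost to floating-point noise.
* Exclusion clashes use the strict interior (distance < radius).
* Conformer embedding is seeded distance geometry (ETKDG) through the
  system Python, bitwise-reproducible for a fixed seed on one platform;
  force-field refinement sits behind a default-off flag, since fixture-
  based testing does not need it and the published workflow's
  minimization protocol is tool-specific.
* Problem sizes in the tests and the acceptance script mirror the
  published test-set shapes (1240- and 1000-compound libraries, 200
  random matcher instances, a 200-compound planned-violation cascade
  library), which keeps the full suite deterministic and fast.

# Known limitations

Docking (pose generation and scoring) is out of scope: poses are
inputs. Database-scale screening numbers are not reproducible at desk
scale and are not attempted. SDF is V2000 only; tautomer enumeration is
not performed; the protonation model is a conservative rule set
(carboxylic/sulfonic acids, aliphatic amines, amidines) that leaves
ambiguous groups untouched. The alert files are curated subsets, not
the full published lists. Aromaticity perception delegates to the
chemistry toolkit and inherits its conventions.
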