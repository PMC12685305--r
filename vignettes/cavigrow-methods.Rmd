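---
title: "cavigrow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cavigrow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavigrow)
```

`cavigrow` is a desk-scale pipeline for structure-guided small-molecule
discovery: it detects and scores surface cavities on a protein structure,
grows cavity-conditioned ligands de novo with a fragment genetic
algorithm, partitions the grown ligands into high- and low-affinity
binder (HAB/LAB) classes by binding energy with statistical
authentication, trains graph classifiers on that partition, and ranks
screened compounds by ROC-threshold selection plus personalized PageRank
over bioactivity descriptor spaces. This vignette explains each model,
its assumptions, the tunable parameters with their units and defaults,
and the design choices made where the design was genuinely open.

## Cavity detection: a hydrogen probe on a 0.5-angstrom grid

`build_grid()` lays a rectangular grid (default spacing 0.5 angstrom)
over the structure with a 4-angstrom margin and classifies every point
as **occupied** (within vdW radius + probe radius of a heavy atom, probe
default 1.0 angstrom — a hydrogen-sized probe), **surface** (vacant but
26-adjacent to an occupied point) or **vacant**. Van der Waals radii are
Bondi values with 1.7 angstrom for unknown elements.

`detect_cavities()` computes a per-point *burial*: the fraction of the
26 lattice directions along which a ray from the point hits an occupied
point within 12 angstrom. Points with burial at or above `burial_min`
(default 0.5) are clustered by 26-connectivity; components above
`min_volume` (default 50 cubic angstrom) become cavities. Cavity volume
is the point count times the grid cell volume, so it converges as the
grid is refined; the test suite checks that halving the spacing moves a
toy pocket's volume by less than 15%.

Druggability is scored as

```
0.25 * min(volume / 500, 1) + 0.30 * burial
  + 0.30 * hydrophobic lining fraction
  + 0.15 * pharmacophore diversity
```

where diversity is the Shannon entropy of the {donor, acceptor,
hydrophobe, charged} residue classes lining the cavity, normalized by
log 4. The functional form and weights are this package's own
construction: published druggability scores in this family of tools
combine the same ingredients (solvent exposure, burial, lining
pharmacophores) but their exact formulas are not public. The score is
clamped to [0, 1] and is monotone non-decreasing in burial by
construction. Cavities are named by membrane location (EC/IC/TM by mean
z against a user-declared membrane slab, NA when no slab is given) plus
a druggability ordinal, e.g. `IC2`.

Two caveats. First, burial is measured on 26 lattice rays, so it is
quantized in steps of 1/26; a "sealed" pocket reports burial close to,
but not always exactly, 1. Second, cavity detection is exactly invariant
only under lattice-compatible rigid motions (the test uses a 90-degree
rotation); arbitrary rotations can move single boundary points across
the discretization.

## Ligand growth: a fragment GA inside the cavity

`grow_ligands()` evolves heavy-atom molecular graphs. The shipped
library (`load_fragment_library()`) holds 177 fragments — ring systems,
linkers and terminal groups assembled from common drug scaffolds — each
with free-valence attachment points. The GA starts from seed fragments
and applies:

* **GROW** (probability 0.8 per mutation): attach a random fragment at a
  random free valence;
* **LINK** (probability 0.2): bridge two sites at topological distance
  of at least 4 through a linker fragment, closing a ring;
* **crossover** (rate 0.6): exchange subtrees across two parents at
  acyclic single bonds;
* **deletion** (inside the mutation path): drop a terminal moiety.

Every candidate is validated through the same valence rules as user
input. Candidates are embedded in 3D by a deterministic
distance-geometry relaxation (bond springs at 1.50/1.40 angstrom, 1-3
spacers at 2.45, a 2.8-angstrom nonbonded floor; the random
initialization is seeded from the canonical form, so identical molecules
always embed identically). The embedded molecule is posed rigidly at the
cavity centroid over 30 sampled orientations and scored:

```
fitness = 1.0 * fill + 1.0 * pharm - 1.0 * clash - 0.25 * strain
```

with *fill* the fraction of cavity points within 2 angstrom of a ligand
atom, *pharm* the fraction of ligand pharmacophores (donor, acceptor,
hydrophobe, aromatic, from element/H-count/aromaticity) with a
complementary lining feature within 5.5 angstrom, *clash* the number of
atoms on occupied grid points, and *strain* the mean absolute
bond-length deviation. The 5.5-angstrom contact distance is geometric:
the probe-inflated occupied shell keeps ligand heavy atoms about
vdW + vdW + probe = 4.4 angstrom from lining atom centers, and one
lattice layer of slack on top of that counts as contact.

Selection is elitist in two places: parents are drawn from the top third
of each generation, and only members at or above the 70th fitness
percentile are eligible for *collection*. Collected ligands must be
clash-free, 10-40 heavy atoms, have at least 80% of atoms within 2.5
angstrom of a cavity point, and be new canonical forms; collection stops
at `target_count` (default 500 unique molecules) or the generation cap
(200), in which case the result carries an explicit shortfall flag. The
elitist collection bar is what lets cavity pharmacophores shape the
output chemistry rather than only the parent pool — without it, two
cavities with identical geometry but different lining chemistry yield
indistinguishable ligand sets.

GA defaults (population 64, crossover 0.6, mutation 0.3, elitism 4,
GROW/LINK 0.8/0.2, 10-40 heavy atoms) are package choices in the usual
range for fragment GAs. With a fixed seed the whole loop is
bit-reproducible. The coarse embedding is adequate for a 0.5-angstrom
grid fitness but is *not* a conformer model: bond angles and torsions
are only loosely realistic, and no synthetic-accessibility filter is
applied.

## Canonical identity, fingerprints, descriptors

Uniqueness counts rest on a canonical line notation: Morgan-style
iterative rank refinement over (element, degree, charge, implicit H,
aromatic flag, ring membership) with neighbor-rank multisets, ties
broken by promoting one member of the lowest tied class (an
automorphism orbit after refinement, for any ordinary molecular graph)
and re-refining. The canonical SMILES writer emits atoms in canonical
DFS order. Hydrogens are implicit throughout; aromaticity is perceived
for 5/6-rings with the standard alternation or lone-pair-donor patterns
(benzene, pyridine, pyrrole, furan, thiophene, imidazole families);
exotic aromaticity is out of scope.

Atom-pair fingerprints hash (atom type, atom type, topological
distance) triples with atom type = (element, heavy degree, aromatic
flag) and distances capped at 30 bonds, into a stable 32-bit mix. The
descriptor panel is a fixed, documented set of 24 physicochemical
descriptors (masses, counts, topology, crude logP and TPSA estimates).
The logP and TPSA contributions are simple additive schemes — adequate
for property *windows* (decoy matching) and for set-level cosine
comparisons, not for quantitative lipophilicity prediction. Failed
descriptors are imputed with the panel median and flagged.

## Authentication: energies, the -7 kcal/mol threshold, and tests

`score_ligands()` takes a pluggable backend. The built-in surrogate is a
transparent additive estimate: -0.35 kcal/mol per matched pharmacophore
pair, -0.06 per heavy atom inside the cavity envelope, +0.8 per clash,
plus seeded Gaussian noise (sigma 0.3 kcal/mol). It has the right
qualitative shape (bigger, better-matched, clash-free ligands score more
negative) but its numeric scale is shallower than physical docking
scores: a 25-atom well-matched ligand lands around -3 to -5 kcal/mol.
The default segregation threshold stays at the field-standard
-7 kcal/mol (inclusive: energy less than or equal to the threshold is a
HAB); runs using the surrogate should set the threshold near the
surrogate's own scale (the examples use -2), which is why the threshold
is a first-class parameter. An external-docking adapter defines the
receptor/box handoff contract (cavity bounding box + 4 angstrom pad)
but is not a docking implementation.

`segregate()` always yields disjoint energy supports, so the two-sample
tests comparing HAB and LAB energies essentially always reject on a
threshold split of adequate size; they become informative when the
negative class comes from elsewhere (user-supplied negatives, decoys).
The package implements all three tests over the ECDFs:
Kolmogorov-Smirnov with the exact pooled-sort D (p-value from the
standard asymptotic distribution), the two-sample Anderson-Darling
midrank statistic with the published normalization (p interpolated on
the significance scale, clipped to [0.001, 0.25]), and Epps-Singleton at
t = (0.4, 0.8) scaled by the pooled semi-interquartile range with the
usual small-sample correction. The significance gate (alpha 0.05)
defaults to warn-and-proceed; `gate = "stop"` makes it blocking.

Class balance outside [1/3, 3] raises an imbalance flag; when HABs
outnumber LABs, `generate_decoys()` builds negatives by fragment
recombination of HAB scaffolds, accepting only candidates
property-matched to some HAB (MW within 25, cLogP within 1, HBD/HBA
within 1) yet topologically dissimilar to every HAB (atom-pair Tanimoto
below 0.4).

## Graph classifiers: four encoders, one convex head

No deep-learning runtime is assumed. The four architectures are
implemented as deterministic message-passing graph encoders with seeded,
fixed random projection weights — in the spirit of extreme-learning /
random-features models — followed by a trainable logistic readout head
fit by ridge-regularized IRLS (`glmnet`), which minimizes binary
cross-entropy. The architecture semantics live in the aggregation:

* **GCM** — unnormalized sum over neighbors plus a self term;
* **GCN** — symmetric degree-normalized convolution;
* **GAT** — per-edge softmax attention coefficients over neighbors
  (leaky-ReLU scores);
* **AFP** — gated (GRU-style) node updates with an attentive graph
  readout.

All encoders end in a mean+max (AFP: attentive+max) readout and the same
2-class head. This makes training convex, fast, and exactly reproducible
on CPU, at the cost of not learning the message-passing weights
themselves; on scaffold-separable data the fixed-feature encoders are
easily sufficient (held-out CV AUC above 0.9 for all four
architectures on the planted two-scaffold dataset), and a label-shuffled
control stays at chance. Node features: one-hot element over
{C,N,O,S,P,F,Cl,Br,I,other}, degree, formal charge, aromatic flag,
implicit H count. Defaults: hidden 64, 2 layers, ridge lambda 0.01,
threefold stratified cross-validation, seed 42.

Class imbalance is handled by upsampling the minority class to parity
inside each training fold only — never the validation fold — and the
fold audit (training id multisets, validation ids, label tables) is kept
on the model object so leakage checks are mechanical. Metrics are
per-fold AUC (trapezoid over the midrank ROC, equal to the Mann-Whitney
pairwise-ordering probability), sensitivity and specificity at 0.5.
`tune_model()` searches a declared config space by mean CV AUC;
candidates whose embeddings collapse (a 1-unit, 8-layer encoder loses
all variance) are ranked last with a warning rather than aborting the
search.

## Ranking: thresholds and HAB-anchored PageRank

`choose_threshold()` evaluates every distinct score as a cut and
maximizes either G-means (sqrt of sensitivity times specificity) or
Youden's J (sensitivity + specificity - 1); ties go to the lower, more
inclusive threshold. `select_positives()` applies a strict
greater-than cutoff, default 0.5.

`project_and_rank()` interprets "similarity-network ranking" as
personalized PageRank: positives and HABs are projected into a
descriptor space, linked by a bipartite graph weighted with cosine
similarity (negatives clamped to 0), and a random walk with damping 0.85
and teleport mass restricted to the HAB nodes is iterated to an L1
tolerance of 1e-10; the positives' stationary mass, renormalized to sum
1, is the score. The HAB-restricted teleport is the design choice that
makes the ranking *HAB-anchored*: compounds similar to many
high-affinity binders accumulate walk mass. The joint
positives-plus-HABs graph (rather than a positives-only graph) was
chosen so that HAB hubs mediate similarity transitively.

Five descriptor-space providers ship by default: **Chemistry** is the
24-descriptor panel; **Targets**, **Networks**, **Cells** and
**Clinics** are deterministic seeded random projections of the folded
atom-pair fingerprint. The latter four are explicit stand-ins: they give
the multi-space machinery deterministic, distinct views of chemistry,
but they do not claim biological meaning. Real bioactivity embeddings
can be supplied as provider functions with the same signature.
`multi_level_screen()` runs spaces in order (default Chemistry through
Clinics), keeps the top `ceiling(q * n)` per level (q default 0.5), and
retains a full audit trail of which level dropped each compound.
`screen_smiles()` is the direct-SMILES path with no probability filter.

## Conservation analytics

`interface_rmsd_matrix()` superposes every structure pair twice on
shared C-alpha atoms (matched by chain and residue number): once on the
whole protein, once on the cavity residue set; the normalized value is
cavity RMSD divided by whole RMSD, which cancels global flexibility.
Superposition is the standard SVD solution with the determinant
correction. Conventions: a pair with whole-protein RMSD below 0.01
angstrom is a rigid copy and its normalized entry is defined as 0; pairs
sharing fewer than 3 atoms in either set are marked missing and excluded
from the mean/median summaries, and both normalized and raw cavity
summaries are emitted. Cross-structure residue correspondence is by
shared residue numbering; structures with incompatible numbering need a
caller-supplied renumbering first. `ligandset_similarity()` reduces each
ligand set to its arithmetic-mean descriptor vector and reports the
pairwise cosine matrix.

## Synthetic fixtures: what they emulate, and what they do not

The `make_*` generators are first-class, tested code and define the
package's study conditions:

* `make_pocket()` — a two-layer spherical shell of pseudo-atoms
  (Fibonacci lattice, about 2-angstrom spacing) with a circular mouth
  and planted lining pharmacophore classes; ground truth (centroid,
  interior radius, volume) is emitted alongside. It emulates a single
  well-formed binding pocket, not a real protein surface: no secondary
  structure, no side-chain geometry, no multiple touching pockets.
* `make_energy_set()` — a two-component Gaussian energy mixture
  (defaults N(-9, 0.5) vs N(-5, 0.5) kcal/mol, n = 500, half binders)
  attached to distinct scaffold families, with truth labels. At these
  defaults the -7 threshold recovers at least 99% of labels (the
  two-sided Gaussian tail mass beyond 2 sd is about 2%, split across
  both components).
* `make_separable_classes()` — aromatic-amine vs aliphatic-ether
  scaffold families; `divergence` in [0, 1] is the probability margin of
  drawing from the own family, so 0 gives identical class distributions
  and 1 fully separable ones. Both classes use the same molecule-code
  range, so no size confound separates them at divergence 0.
* `make_roc_set()` and `make_structure_family()` — shifted-Gaussian
  score sets and perturbed C-alpha traces for the ROC and conservation
  modules.

All fixtures are bit-reproducible from (parameters, seed); every
randomness source goes through one derived-seed stream per fixture.
Passing tests on these fixtures demonstrate the machinery —
planted-signal recovery, oracle equivalence, reproducibility — not
performance on real receptors: real cavities are less spherical, real
docking energies are not two-Gaussian mixtures, and real
active/inactive chemistry is far less separable than the planted
scaffold families.

## Problem sizes, numerical choices, known limitations

The test suite and the acceptance script run everything at reduced n
chosen as the smallest sizes at which the planted effects are
comfortably detectable: pockets of radius 6-8 angstrom, 15-20 grown
ligands per GA run (the default target stays 500), classifier datasets
of 100+100, two full pipeline reruns for the determinism check. The
heterogeneity analysis (PCA separation of ligand sets grown in a
hydrophobic vs a polar pocket) uses fixture seed 11.

Numerical conventions worth knowing: PageRank power iteration converges
to 1e-10 in L1 with a 1e4 iteration cap; Kabsch rejects collinear point
sets (second singular value below 1e-10 relative); threshold ties pick
the more inclusive cut; ROC uses midranks; the canonicalizer's
tie-break assumes refinement classes are automorphism orbits, which
holds for ordinary molecular graphs but is not proven for pathological
regular graphs; pipeline resume trusts the stage artifacts on disk
(`labeled.tsv` is the energy record; deleting it re-scores from
re-derived poses, which regenerates energies from re-embedded ligands).

Known limitations, deliberately accepted: no tautomer or stereochemistry
handling; no conformer search beyond the coarse embedding; the surrogate
scorer is not a docking engine and its scale differs from physical
binding energies; the four non-Chemistry descriptor spaces are
deterministic stand-ins; no synthetic-accessibility scoring of grown
ligands.
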