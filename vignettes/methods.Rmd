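---
title: "resibind: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{resibind: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `resibind`, the tunable
parameters and their defaults, the numerical and design choices made
where the problem left them open, and what the synthetic test bed does
and does not establish.

## The model

Binding-site prediction is framed as binary classification per
residue: given a 3D structure, decide for every polymer residue
whether it belongs to a ligand binding site. Three layers make up the
pipeline.

**Descriptors.** Each residue gets 14 numbers:

| level | descriptors |
|---|---|
| residue | relative solvent accessibility (RSA); cysteine indicator |
| atom | counts of heavy atoms typed aromatic, acceptor, donor, hydrophobic, positive, negative |
| interaction | counts of detected aromatic-stacking, disulfide-bridge, hydrogen-bond, hydrophobic, repulsive, salt-bridge contacts |

Atom classes come from a shipped, editable typing table covering the
20 standard amino acids; an atom may carry several classes (TYR OH is
donor and acceptor) and each class increments its own counter.
Interactions are detected purely from atom classes and Euclidean
distances: for every heavy-atom pair in different residues, each
interaction type fires when its class requirement (donor×acceptor for
hydrogen bonds, positive×negative for salt bridges, like charges for
repulsive, both-hydrophobic, both-aromatic, CYS-SG×CYS-SG for
disulfides) and its distance window are both met. A pair may satisfy
several types at once. Pairs of backbone atoms (N, CA, C, O, OXT) in
sequence-adjacent residues of one chain are excluded as covalent
neighborhood; side-chain contacts of adjacent residues are kept.

**Neighborhood encoding.** Residues are nodes of a contact graph:
adjacent iff some heavy-atom pair lies within 6 Å. A residue's first
shell is its direct neighbors, the second shell the
neighbors-of-neighbors not already seen (BFS levels 1 and 2). The
feature vector is the residue's own 14 descriptors, the arithmetic
mean over its first-shell members, and the mean over its second-shell
members — 42 values, fixed column order, zero blocks for empty
shells. Since adjacency ignores chain identity, shells extend across
protein–protein interfaces, which is what lets the classifier see
interface binding sites.

**Classifier.** For a query, templates (ligand-bound structures with
known binding residues) are selected from a local store by global
alignment identity (BLOSUM62, Needleman–Wunsch) within a window —
the upper bound, default 0.95, excludes the query itself and
near-duplicates during benchmarking. Binding residues in the pooled
template matrix are the minority class, so training uses balanced
bagging: each of `n_bags` bags keeps all minority rows plus an
equal-size majority sample drawn without replacement, and fits an
extremely-randomized-trees probability forest. Confidence is the mean
positive-class probability over all trees of all bags (duplicating
bags provably changes nothing); labels use a 0.5 threshold exposed as
a parameter because the precision/recall trade-off belongs to the
user.

**Pockets and ligand suggestion.** Predicted residues are clustered
with DBSCAN on representative coordinates (CA, else heavy-atom
centroid). Each cluster is summarized by a distance signature: all
pairwise representative distances, binned by the unordered pair of
residue chemical categories (fixed precedence positive > negative >
aromatic > polar > hydrophobic > other over the residue's atom
classes) and sorted. Two signatures are compared by greedily matching
the sorted lists within a tolerance; the score is twice the match
count over the total pair count, so identical sites score 1 and
category-disjoint sites 0. For sorted lists this greedy matching
equals the optimal one-to-one interval matching, which the test suite
verifies exhaustively on small lists. Per pocket, the best-scoring
template site of each ligand code yields the ranked suggestions.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| contact_cutoff | 6.0 | Å | heavy-atom residue contact; merges one coordination shell |
| probe_radius / sasa_points | 1.4 / 960 | Å / – | water probe; sampling density converged to < 0.02 RSA |
| hydrogen_bond window | 2.0–3.9 | Å | conventional donor–acceptor contact range |
| salt_bridge, repulsive | 2.0–6.0 | Å | charged-group interaction range |
| hydrophobic | 2.0–4.5 | Å | apolar carbon contact |
| aromatic_stacking | 1.5–3.5 | Å | atom–atom between ring atoms |
| disulfide_bridge | 1.8–2.8 | Å | S–S covalent bond length window |
| label_margin | 0.5 | Å | vdW-sum contact rule for ground-truth labels |
| n_bags × trees_per_bag | 10 × 100 | – | balanced-ensemble shape |
| threshold | 0.5 | – | decision point on mean probability |
| min/max_identity, max_templates | 0 / 0.95 / 50 | – | template window; 0.95 blocks self-matches |
| eps / min_samples | 6.0 / 3 | Å / – | DBSCAN; one contact shell per pocket |
| sim_tol | 0.5 | Å | signature match tolerance |
| dca_threshold | 4.0 | Å | community convention for a pocket "hit" |

All interaction windows and the typing table are plain text files
under `inst/extdata/` and can be replaced wholesale.

## Numerical and design choices

- **PDB dialect only**; mmCIF is a future extension. Multi-model
  (NMR) files use the first model; alternate locations resolve to the
  highest-occupancy conformer, ties broken by altloc letter. These
  are this package's choices where the field has no single rule.
- **Hydrogens** are retained by the parser but ignored by every
  descriptor computation (heavy-atom convention).
- **Ligand filtering** approximates "biologically relevant" curation
  with a shipped exclusion list (water, cryo-agents, buffers,
  counter-ions). Metal ions are treated as ligands, not as typed
  protein atoms.
- **Shells from the distance graph**, not the interaction graph: the
  simplest neighbor criterion consistent with an atomic-level contact
  model, and it makes inter-chain shells automatic. An
  interaction-graph mode was considered and rejected for v1 because
  it couples the neighborhood definition to threshold choices.
- **Empty shells encode as zeros** rather than sentinels, keeping the
  matrix dense and model-friendly.
- **Interaction counts at a residue include all partners**, inside or
  outside its shells — per-residue tallies are the natural reading of
  interaction-level descriptors.
- **Per-query training**: a model is trained from the matched
  templates of each query rather than one global model. A global mode
  is a possible extension; the per-query form matches the
  template-matching design and keeps training sets small.
- **Resampling scheme**: 1:1 undersampling of the majority class
  without replacement, all minority rows kept in every bag.
  Oversampling was rejected to keep bags small and decorrelated.
- **Row canonicalization**: training rows are sorted by label and
  feature values before bag sampling, so the fit is invariant to the
  order in which template residues arrive.
- **Aromatic stacking uses atom–atom distances**, not ring
  centroids/normals — consistent with the purely distance-and-class
  interaction model; angle-dependent geometry is out of scope.
- **Site similarity is a residue-level distance-multiset variant** of
  atom-triplet site-matching algorithms: clusters are residue sets, so
  the comparison runs at residue granularity with representative
  coordinates. The greedy-on-sorted matcher is exact for this
  interval-matching problem.
- **MCC degenerate case** (any zero marginal) is defined as 0;
  dataset aggregation is the unweighted per-structure mean, with a
  pooled-residue mode behind a flag.
- **Determinism**: one top-level seed; bag seeds are derived as
  `seed + bag`; ranger runs single-threaded with an explicit seed.
  Identical seeds give byte-identical fixtures, bag compositions,
  predictions and reports.

## The synthetic test bed

The generator emulates the inputs the pipeline needs — PDB-format
multi-residue structures with named heavy atoms, placed pseudo-ligands
defining ground-truth binding residues, and on-disk template stores —
with three folds (ideal helix, cubic lattice, random coil), pseudo
side chains whose atom names are fully covered by the typing table,
and a ligand placement routine that guarantees the contact rule labels
exactly the requested target residues (infeasible target sets raise an
error rather than approximate). Planted sites draw from a
charged/polar alphabet against a hydrophobic/small-polar background,
so the binding signal is carried by the same descriptor families that
distinguish real sites: exposed charged and H-bonding groups in a
locally dense neighborhood.

What it does **not** emulate: real backbone geometry and rotamers,
crystallographic noise and missing atoms, realistic sequence homology
structure between templates, chemically diverse ligands, or the label
noise of curated databases. Passing the recovery experiments therefore
shows the machinery is correct and the planted signal recoverable — it
does not certify benchmark-level accuracy on real proteins, which
would require real template databases.

Problem sizes used by the tests and the acceptance script — 20–30
residues per structure, 10–20 template stores, 330-row separable
matrices, 50–80 point clustering sets — were chosen as the smallest
sizes at which every pathway (two shells, multiple pockets, both
chains, both classes in every bag) is exercised.

## Known limitations

- PDB fixed-width input only; no mmCIF, no network fetching.
- Distance-only interaction criteria; no H-bond angles, no ring
  geometry, no explicit hydrogens.
- Sequence-based template selection only; no structural alignment
  fallback for remote homologs.
- RSA from sphere sampling is deterministic but lattice-fixed, so
  rigid rotations perturb it by up to ~1e-2; labels are robust to
  this, confidences move in the third decimal.
- Per-query training cost scales with the number of selected
  templates; featurization (dominated by SASA) is the bottleneck for
  large complexes.
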