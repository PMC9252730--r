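# resibind

Residue-centric prediction of protein–ligand binding sites from 3D
structure.

Most of what a protein does, it does through binding sites — the
residues in direct contact with a ligand. Finding those residues
experimentally is slow and expensive, so structure-based predictors
are a standard first step in function annotation and early drug
discovery. `resibind` implements a residue-centric strategy: instead
of searching for surface cavities, it asks, for every residue *r* of a
query structure *P*, a binary question — is *r* part of a binding site
or not? — and answers it with a supervised classifier trained on
ligand-bound template structures matched to the query by sequence.

## Method

**Encoding.** Each residue is described by 14 physicochemical
descriptors: 2 at residue level (relative solvent accessibility by
Shrake–Rupley sampling, and a cysteine indicator), 6 at atom level
(how many of the residue's heavy atoms are typed aromatic, acceptor,
donor, hydrophobic, positive, negative), and 6 at interaction level
(counts of detected aromatic-stacking, disulfide-bridge,
hydrogen-bond, hydrophobic, repulsive and salt-bridge contacts, from
atom classes and Euclidean distances). The residue's spatial
neighborhood is a graph over heavy-atom contacts (≤ 6 Å): the 14
descriptors are computed for the residue itself and averaged over its
first and second shells of neighbors, giving a 42-value feature
vector. A whole structure becomes a feature matrix *G* with one row
per residue. Because the contact graph crosses chain boundaries, sites
at protein–protein interfaces are encoded like any others.

**Classification.** Binding residues are rare (class imbalance is
intrinsic to the problem), so the classifier is an ensemble of
balanced bags: each bag keeps every minority-class row plus an
equal-size majority subsample and fits an extremely-randomized-trees
probability forest. The per-residue confidence is the mean
positive-class probability over all trees; the label is thresholded at
0.5. Feature importances (impurity-based, averaged over bags,
normalized to sum 1) explain each prediction.

**Post-processing.** Predicted residues are clustered into candidate
pockets with DBSCAN on representative coordinates; each pocket is
compared against the template binding sites with a distance-signature
similarity score (sorted intra-site distance lists per chemical
category pair, greedily matched within 0.5 Å) to rank candidate
ligands, since similar sites tend to bind similar ligands. Evaluation
uses MCC, precision, recall and DCA (distance from pocket center to
the nearest ligand atom).

Training data come from a local template store (one directory per
ligand-bound structure with labels, ligands and sequence). A synthetic
generator builds toy structures, bound ligands and whole stores with
known ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(resibind)

# a synthetic template store and a held-out bound query
store_dir <- file.path(tempdir(), "demo_store")
generate_template_store(10, store_dir, seed = 3)
store <- read_template_store(store_dir)
query <- generate_bound_fixture(n_residues = 30, seed = 42,
                                structure_id = "demo")

result <- predict_binding_sites(query$structure, store,
                                bsite_config(seed = 7))
print(result)
#> <bsite_result> demo
#>   templates used: 10  (identity 0.03-0.26)
#>   predicted binding residues: 4 / 30
#> <bsite_pockets> 1 pocket(s), 0 noise residue(s)
#>   pocket 1: 4 residues, center (-0.8, 0.0, 34.9)
#>   pocket 1 ligands: LG1 (0.67), LG3 (0.22), LG4 (0.22), LG6 (0.22), LG2 (0.00)

evaluate_structure(result$predictions, query$manifest$labels,
                   result$pockets, query$structure)
#> MCC 0.850  precision 0.750  recall 1.000  (tp 3 fp 1 fn 0 tn 26)
#>   DCA per pocket: 2.35  [hit]
```

The query was generated with a 3-residue planted site; the classifier
(trained only on the 10 templates, none of which is the query — the
0.95 identity cap excludes near-duplicates) recovers all 3 true
binding residues plus one neighbor, clusters them into a single
pocket whose center sits 2.35 Å from the ligand (a "hit" at the 4 Å
DCA convention), and ranks the query's true ligand code (`LG1`) first
at similarity 0.67. The importance ranking is dominated by the
atom-class counts that distinguish the charged planted site from the
hydrophobic background:

```r
head(feature_importance(result$model), 3)
#>          feature importance
#> 1 atoms_acceptor  0.1759487
#> 2    atoms_donor  0.1177665
#> 3 atoms_negative  0.1057954
```

A command-line interface with the same behavior is installed as
`exec/resibind` (`featurize`, `predict`, `evaluate`, `fixtures`
subcommands; `--help` for details).

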