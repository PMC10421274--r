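# mathqsar

Binary QSAR classification of bioactive compounds from SMILES strings
with a molecular-graph Transformer whose self-attention is augmented by
intramolecular hydrogen-bond information.

## What problem this solves

Screening compound libraries against a protein target (the motivating
application is estrogen receptor alpha, the endocrine-therapy target in
ER-positive breast cancer) starts from bioactivity tables of SMILES and
IC50 values. `mathqsar` turns such a table into a trained active/inactive
classifier and an evaluation report, for computational chemists and
ML-for-drug-discovery researchers who want a self-contained, reproducible
R implementation.

The core model treats each heavy atom as a token and mixes four terms
into every attention head:

    A(i) = ( λa · softmax(Qi Kiᵀ / √dk) + λd · g(D) + λg · A + λh · Hbond ) Vi

where `A` is the covalent adjacency matrix, `D` the heavy-atom distance
matrix from a seeded 3D conformer, `g` a row-softmax of negated
distances, and `Hbond` a {0,1} matrix of intramolecular hydrogen bonds
(hydrogen on an N/O/S donor within a distance threshold of an N/O/S
acceptor). With `λh = 0` the same code path is the plain
structure-augmented attention baseline, so the contribution of the
hydrogen-bond term is a one-flag ablation.

Around the model, the package provides the full workflow: ChEMBL-style
preprocessing (salt stripping, deduplication, IC50 labeling at the
1000/10000 nM cutoffs, pIC50 conversion, 80/20 splitting), five-fold
stratified cross-validation with precision/recall/F1/specificity/ROC-AUC
reporting, a hydrogen-bond threshold sweep over the 2.2–4.0 Å grid, and a
synthetic fixture generator with a planted hydrogen-bond/activity signal
so everything is testable offline.

## Worked example

```r
library(mathqsar)

# featurize one molecule: the 26-heavy-atom xanthene propanamide
fs <- featurize("CC(C)(C1c2ccccc2Oc2ccc(O)cc21)C(=O)Nc1nccs1",
                featurizer_config(dthreshold = 3.0, seed = 42))
fs
#> <DescriptorSet> CC(C)(C(=O)Nc1nccs1)C1c2ccccc2Oc2ccc(O)cc21
#>   26 heavy atoms; 0 H-bond triple(s) at 3 Angstrom (distance mode)
dim(fs$adjacency)
#> [1] 26 26

# salicylamide folds into an intramolecular N-H...O contact:
featurize("NC(=O)c1ccccc1O",
          featurizer_config(dthreshold = 3.0, seed = 42))$hbond_triples
#>   donor acceptor distance
#> 1     1        3 1.870531

# a full experiment on a synthetic fixture
spec <- fixture_spec(n_molecules = 200, hbond_signal_strength = 0.9,
                     noise = 0.1, seed = 7)
tab  <- generate_bioactivity_table(spec)
recs <- prepare_bioactivity(tab, seed = 42)
cv   <- cross_validate(recs, k = 5,
                       featurizer_config = featurizer_config(3.0, seed = 42),
                       model_config = math_config("test"), seed = 1)
cv
#> <math_cv> 5-fold cross-validation
#>   mean:  roc_auc 0.7869  precision 0.7370  recall 0.7216  f1 0.6886  specificity 0.7976
#>   best fold by F1: 1
```

The fold-averaged ROC AUC around 0.79 reflects the fixture's planted
signal (90% signal strength, 10% label noise) learned by the scaled-down
2-block configuration in 10 epochs; the printed numbers are what the
code above produces, not targets. (Note the 26-atom example carries no
hydrogen-bond triple in its single default-seed conformer — whether a
molecule's force-field minimum adopts the folded rotamer is exactly the
kind of conformer sensitivity the vignette discusses.)

A thin command-line front end over the same functions ships in
`inst/cli/math-qsar` (`make-fixtures`, `prepare`, `featurize`, `train`,
`evaluate`, `sweep`).

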