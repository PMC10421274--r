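---
title: "Hydrogen-bond-augmented molecular attention for QSAR classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond-augmented molecular attention for QSAR classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mathqsar` classifies compounds as active or inactive against a protein
target (the motivating application is inhibition of estrogen receptor
alpha, ChEMBL target 206) from nothing but a SMILES string. The classifier
is a molecular-graph Transformer: each heavy atom is a token, and the
self-attention weights are augmented with three structural matrices. For
head $i$ with hidden state $H$,

$$
\mathrm{A}^{(i)} \;=\; \Bigl(\lambda_a\,\mathrm{softmax}\!\bigl(\tfrac{Q_i K_i^\top}{\sqrt{d_k}}\bigr)
\;+\; \lambda_d\, g(D) \;+\; \lambda_g\, A \;+\; \lambda_h\, H_{\mathrm{bond}}\Bigr) V_i ,
$$

where $Q_i = H W_i^Q$, $K_i = H W_i^K$, $V_i = H W_i^V$, $A$ is the
covalent adjacency matrix, $D$ the pairwise heavy-atom distance matrix
from a 3D conformer, $g$ a distance normalizer, and $H_{\mathrm{bond}}$ a
`{0,1}` matrix marking heavy-atom pairs joined by an intramolecular
hydrogen bond. Setting $\lambda_a = 1$ and the other weights to zero
recovers plain scaled-dot-product attention; setting $\lambda_h = 0$
recovers the adjacency/distance-augmented attention without hydrogen-bond
information, which is the ablation baseline the package exposes through
the same code path (`math_config(lambda_h = 0)`).

The encoder stacks `n_blocks` of multi-head attention plus a
position-wise feed-forward sub-layer, each wrapped in a residual
connection and layer normalization. A masked mean over atom embeddings
feeds a logistic classification layer, so the output is $P(\text{active})
\in [0,1]$. Binary cross-entropy is minimized with Adam; there is no early
stopping, and all training loops are deterministic given a seed on one
CPU. Because molecules are processed one at a time (gradients are
accumulated over each mini-batch and averaged), no padding or atom
masking is needed; the result is mathematically identical to padded
batching with masked softmax and pooling.

## Featurization

`featurize()` produces five descriptors per molecule:

* **Node features** (27 columns): one-hot element over
  {B, N, C, O, F, P, S, Cl, Br, I, other}, one-hot heavy-atom degree 0-5,
  one-hot attached-hydrogen count 0-4, one-hot formal charge
  {-1, 0, +1}, a ring flag and an aromatic flag. This is the featurization
  convention of the molecule-attention Transformer family, which this
  architecture extends.
* **Adjacency matrix** over heavy atoms.
* **Distance matrix** from a single 3D conformer, generated by seeded
  distance-geometry embedding (ETKDGv3) with explicit hydrogens followed
  by MMFF force-field relaxation. One conformer per molecule; conformer
  ensembles are out of scope.
* **Hydrogen-bond triples** $(i, j, d)$ and the corresponding Boolean
  matrix.

Atoms are renumbered into the toolkit's canonical rank order before
anything else, so all descriptors are reproducible regardless of how the
input SMILES is written.

### Hydrogen-bond detection

A triple is recorded when a hydrogen covalently bound to an N/O/S donor
lies within `dthreshold` angstroms of an N/O/S acceptor. Choices worth
making explicit:

* **Donor definition.** Hydrogens on carbon are not donors by default; a
  `strict_literal` flag treats any hydrogen as a potential donor for users
  who want the wider reading.
* **Distance measured.** The hydrogen-to-acceptor distance, matching the
  set definition over hydrogen-atom indices; a `donor_acceptor` mode
  measures from the donor heavy atom instead (donor-acceptor separations
  of about 3.0 angstroms are the textbook figure for moderate hydrogen
  bonds, which motivates the default threshold below).
* **Covalent exclusions.** 1,2-contacts (acceptor bonded to the donor)
  are always excluded and 1,3-contacts (donor and acceptor sharing a
  neighbour) are excluded by default; otherwise covalent geometry would
  be counted as hydrogen bonding.
* **No angle criterion.** Only the distance cut-off is applied. Bond
  angles, partial charges and electronegativity all modulate real
  hydrogen-bond strength; the descriptor deliberately stays a pure
  distance test.
* **Heavy-atom projection.** Triples are reported on the donor heavy
  atom so that $H_{\mathrm{bond}}$ is shape-compatible with $A$ and $D$.

The default threshold is 3.0 angstroms: it sits at the boundary between
"moderate, mostly electrostatic" (2.5-3.2) and "weak" (3.2-4.0) hydrogen
bonds in Jeffrey's classification, and the sweep helper
(`run_sweep()`) covers the 2.2-4.0 grid in 0.2 steps for the same reason.
Boolean mode records presence at the default threshold; distance mode
filters at a user-chosen threshold. Both feed a `{0,1}` matrix to the
attention: the published description of the distance variant is a
threshold-filtered triple set, with no real-valued weighting formula, so
none is invented.

$H_{\mathrm{bond}}$ is **not** softmax-normalized and carries its own
weight $\lambda_h$ with default 1 (the augmented-attention equation adds
the hydrogen-bond term without a mixing scalar; exposing $\lambda_h$ keeps
the faithful default while making the ablation a configuration change).
$\lambda_a, \lambda_d, \lambda_g$ default to $1/3$ each — they are fixed
scalars, not learned parameters, and nothing enforces that they sum to 1.
$g$ defaults to a row-wise softmax of $-D$, so nearer atoms receive larger
weight; a raw softmax of distances would up-weight the *farthest* atoms,
which contradicts both chemical intuition and the practice of
distance-augmented attention models. An elementwise $e^{-D}$ normalizer is
available.

### Why conformer generation is delegated to RDKit

Distance-geometry embedding must be deterministic given a seed, or
nothing downstream (descriptor matrices, detected hydrogen bonds, trained
weights) is reproducible. The featurizer therefore shells out to a small
bundled Python helper built on RDKit, the toolkit whose ETKDG
implementation accepts an explicit random seed; requests are batched and
memoised per session, so a 200-molecule dataset costs one subprocess
call. If embedding fails after five seed-incremented retries, the
molecule falls back to topological shortest-path distances scaled by 1.5
angstroms per bond, with hydrogen-bond detection disabled and a warning —
the pipeline never crashes on a hard-to-embed structure.

## Preprocessing pipeline

`prepare_bioactivity()` reproduces a ChEMBL-style IC50 workflow: load CSV
→ clean (drop non-nM units, missing IC50 and blocklisted annotation rows;
strip salts to the largest fragment by heavy-atom count with molecular
weight, then lexicographic canonical-SMILES tie-breaks) → deduplicate by
canonical SMILES (first record wins; median aggregation optional) → label
(IC50 ≤ 1000 nM active, ≥ 10000 nM inactive, otherwise intermediate) →
exclude intermediates → convert to pIC50 = 9 − log10(IC50/nM) → random
80/20 train/test split. Every stage logs its removal count. ChEMBL does
not expose a single column identifying agonist-only or binder-only
entries, so the annotation filter is a configurable column + pattern
blocklist approximating that manual curation; consequently row counts on
a live ChEMBL export depend on the snapshot date and curation choices and
are logged for comparison rather than asserted.

## The synthetic fixture generator

`generate_bioactivity_table()` builds datasets in which activity is
statistically linked to intramolecular hydrogen-bond capability — the
association the model is supposed to exploit. Two hand-curated template
families are enumerated from scaffold × substituent grids:

* **Family A** — salicylaldehyde-, salicylamide- and salicylate-like
  scaffolds with an ortho donor/acceptor pair. Every member was verified
  to parse, embed at the default seed, and show at least one
  intramolecular hydrogen-bond triple at 3.0 angstroms.
* **Family B** — matched analogues in which the donor is methylated away
  (and amides are N,N-disubstituted), so no N-H/O-H/S-H exists and the
  triple count is structurally zero.

Curation matters: a random SMILES generator produces unembeddable or
exotic structures, and even for real scaffolds a single conformer does
not always adopt the hydrogen-bonded rotamer (2-hydroxyacetophenone, for
instance, relaxes to the non-bonded rotamer under this pipeline and was
excluded). Family A is drawn with probability `active_fraction` (default
0.5); labels follow the family with probability `hbond_signal_strength`
(default 0.9) and are flipped with probability `noise` (default 0.1).
IC50 values are sampled log-uniformly — bioactivity spans orders of
magnitude — inside the label's band, keeping a 5% margin from the
1000/10000 nM boundaries so labels are never ambiguous; planted defect
rows (missing IC50, duplicates, dot-disconnected salts, intermediates)
are drawn from spare templates so each cleaning rule removes exactly its
planted count.

What the fixture does *not* emulate: real estrogen-receptor
pharmacophores, the size and scaffold diversity of a ChEMBL export
(fixture molecules have 9-16 heavy atoms), assay noise structure, or
activity cliffs. Passing tests on the fixture therefore demonstrate that
the implementation learns a planted structure-activity signal, not that
the model attains any particular accuracy on real bioactivity data.

## Scaled-down experiment profile

The full-scale configuration (8 blocks, 16 heads, hidden size 1024, batch
64, 100 epochs, Adam at 1e-4, five-fold cross-validation) matches the
published training setup but is a GPU-scale workload. All package
experiments use `math_config("test")`: 2 blocks, 4 heads, hidden size 64,
10 epochs, batch 16, learning rate 1e-3 (chosen once by inspecting
training-loss stability on the fixture; 1e-4 barely moves in 10 epochs at
this scale), on 200-compound fixtures. Cross-validation folds are
stratified — the motivating dataset is imbalanced, and stratification
keeps every fold evaluable — and the best fold is selected by highest F1.
Reported quantities are fold-averaged metrics; a model refit on all
training data against the held-out test set is available through the same
functions, and the two aggregations are deliberately kept distinct.

## Numerical choices and edge cases

* Truncated-normal initialization (Glorot-scaled, clamped at two standard
  deviations), zero biases, unit layer-norm gains; layer-norm epsilon
  1e-5; probabilities clipped to [1e-12, 1 − 1e-12] inside the loss.
* Softmax rows are max-shifted before exponentiation.
* Metrics with zero denominators (e.g. precision when nothing is
  predicted active) are reported as `NA` with an `undefined` flag, never
  as errors; ROC AUC is computed by the trapezoidal method (it equals the
  normalized Mann-Whitney statistic, which the tests verify
  independently).
* Dropout defaults to 0 so that every documented run is bit-reproducible;
  the classification threshold is 0.5.
* A single-class training set raises a classed error rather than fitting
  a degenerate model.

## Known limitations

* One conformer per molecule; molecules whose bound conformation differs
  from the force-field minimum can miss (or gain) hydrogen bonds.
* The distance-only hydrogen-bond criterion ignores geometry and
  chemistry beyond the N/O/S element filter.
* The scaled-down profile is sized for desk-scale verification;
  reproducing published-scale accuracy would require the full
  configuration, the original data snapshot, and GPU-scale training.
* Pre-training, regression on pIC50, multi-task heads and external
  baseline models (SMILES-Transformer, fingerprint MLPs) are out of
  scope.
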