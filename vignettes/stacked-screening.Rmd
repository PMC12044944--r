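---
title: "Stacked ensemble screening under class imbalance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble screening under class imbalance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stackscreen implements a multi-step stacking strategy for classifying
compounds as active or inactive against a protein target when the two
classes are badly imbalanced — the regime typical of ChEMBL extracts, where
potent actives outnumber confirmed inactives by factors of five or more.
This vignette explains the model, its assumptions, the tunable parameters,
the synthetic data the package tests itself on, and the design choices made
where more than one defensible option existed.

## The pipeline

### Curation

Activity tables are reduced to one record per chemical structure:

* only rows whose standard relation is exactly `=` are kept — censored
  measurements (`<`, `>`, `/`) carry no usable potency value, and every
  dropped row is recorded with a reason code rather than silently
  discarded;
* IC50 values are converted to pIC50 (`-log10` of the molar value), so a
  1 µM compound scores 6 and a 1 nM compound 9;
* structures are standardized (largest organic fragment, canonical SMILES)
  and duplicates are collapsed to the median pIC50 of their measurements —
  the median is robust against a single discordant assay;
* labels use two cutoffs: active at pIC50 ≥ 6, inactive below 5, with the
  band in between flagged `intermediate` and excluded from modelling. The
  cutoffs are arguments, not constants; the defaults are the common potency
  convention (active at ≤ 1 µM, inactive beyond 10 µM) and deliberately
  leave a buffer zone so that assay noise near the boundary cannot flip
  labels.

The stratified train/test split assigns `round(0.75 · n)` compounds of each
class to training. Splitting is seeded and conserves the labelled set
exactly.

### Fingerprints

Five descriptor families with fixed widths form the feature side of the
model:

| family  | width | kind   | realization |
|---------|------:|--------|-------------|
| AP2DC   | 780   | binary | element-class pairs (12 classes) × topological distances 1–10 |
| CDKExt  | 1024  | binary | hashed linear/ring path fingerprint (OpenBabel FP2) |
| FP4C    | 307   | count  | matches of 307 functional-group SMARTS patterns |
| MACCS   | 166   | binary | the 166 MACCS structural keys |
| Pubchem | 881   | binary | circular (ECFP4) bits folded to width 881 |

The contract for each family is its *dimension*, its *value kind* and
*determinism* — not bit-for-bit agreement with any particular fingerprint
program, whose exact bit semantics are only partially documented and whose
reproduction would add nothing testable. Where the native width of the
underlying machinery differs from the declared width, bits are folded
(OR-ed modulo the target width); folding preserves determinism and row
order, which is all downstream code relies on. The atom-pair block is
computed directly from the molecular graph: atoms are mapped to 12 element
classes (C, N, O, S, P, F, Cl, Br, I, B, Si, other), shortest-path
distances come from the bond graph, and each (unordered class pair,
distance ≤ 10) combination sets one of 78 × 10 = 780 bits.

Structure standardization keeps the largest carbon-containing fragment and
canonicalizes with OpenBabel, which also normalizes aromatic/Kekulé forms.
Full tautomer enumeration is not performed; for fingerprint purposes the
canonical aromatic form is stable under re-application, which is the
property the pipeline needs (standardization is idempotent and tested as
such).

### Balanced subsets

With `n_maj` majority and `n_min` minority compounds, the majority class is
shuffled once (seeded) and cut into `K = round(n_maj/n_min)` disjoint
near-equal slices, each paired with the full minority class. Every majority
compound is used exactly once across subsets — nothing is discarded, unlike
plain under-sampling. When `n_maj` is not divisible by `K` the slices
differ by one compound (e.g. 790 majority compounds over five subsets give
slices of 158); we prefer near-equal disjoint slices over sampling with
replacement or dropping to a smaller `K`, because disjointness is what
makes the subsets' base models genuinely diverse.

### Base classifiers and the probabilistic feature vector

Each (algorithm, descriptor family, subset) triple yields one base
classifier. Six algorithms are registered — KNN, a single-hidden-layer
MLP, PLS-DA, random forest, an RBF-kernel SVM and gradient boosting — each
with a small default hyperparameter grid searched by stratified 10-fold
cross-validation maximizing MCC on the subset. The default grids (k ∈
{3,5,7,9}; hidden units ∈ {16,32,64}; components 2–8; 500 trees with mtry ∈
{√p, p/4}; C ∈ {0.1,1,10} × γ ∈ {1/p, 0.01}; depth {3,6} × η {0.1,0.3} at
300 rounds) are deliberately compact: base models need to be decent and
*diverse*, not individually optimal, since the meta-learner weighs their
outputs.

The probabilistic feature vector (PFV) has one column per base model, in
algorithm-major order; with the full roster and five subsets it is 150
columns wide. A training compound's entry in a column is

* the **out-of-fold** score when the compound belongs to that base model's
  own balanced subset (each compound scored by the fold model that excluded
  it), and
* the **fitted-model** score otherwise.

The distinction matters: in-subset fitted scores would leak the training
labels into the meta-features exactly where overfitting is most damaging.
For compounds outside the subset the fitted model has never seen them, so
its direct score is already honest. (Whether refit or out-of-fold scores
should also be used outside the subset is genuinely open; we chose the
cheaper option that still blocks the first-order leak.) PLS-DA class scores
are linear and can fall outside [0, 1]; they are clipped, since PFV entries
are probabilities by contract.

### Feature selection and the meta-classifier

PFV columns are ranked by random-forest mean decrease in Gini impurity
(MDGI), averaged over five forest seeds because single-forest importance
rankings are noticeably seed-sensitive. Candidate subset sizes m = 10, 20,
…, 150 (truncated to the PFV width) are each evaluated by stratified
cross-validation of an RBF-SVM meta-classifier on the top-m columns; the m
with the highest pooled out-of-fold MCC wins, with ties broken toward the
smaller m (the cheaper model). The final meta-classifier is an RBF-SVM
with Platt-style probability outputs trained on the chosen columns; its
decision threshold defaults to 0.5 and is exposed in the API. Selection
folds are seeded independently of the base-model folds so the two
cross-validation layers do not share structure.

### Evaluation

Metrics follow the standard confusion-matrix definitions: SN = TP/(TP+FN),
SP = TN/(TN+FP), ACC, BACC = (SN+SP)/2, MCC, and rank-based AUC (the
Mann–Whitney statistic with midrank ties). Degenerate denominators yield
`NA` plus a flag — except MCC, which returns the conventional 0, flagged.
Cross-validation reports metrics on pooled out-of-fold predictions (the
per-fold confusions are retained and sum exactly to the pooled one); pooled
aggregation was chosen over fold-averaging because a single number per
model is what the evaluation harness compares.

### Chemical-space diagnostics

`chem_space_report()` compares classes property-by-property (MW, AlogP,
HBA, HBD, TPSA, nRotB) with two-sided Mann–Whitney tests — exact by full
enumeration when the smaller group has ≤ 8 members, normal approximation
with tie correction otherwise — and reports Lipinski/Veber pass fractions
using strict inequalities (a compound at MW exactly 500 fails). Between
train and test partitions it reports the fraction of test-set Bemis–Murcko
frameworks absent from training and the full train×test Tanimoto matrix on
2048-bit circular fingerprints. Scaffolds are extracted by iteratively
pruning terminal atoms (the 2-core of the heavy-atom graph), which removes
side chains and exocyclic substituents — including double-bonded ones, a
known difference from framework variants that retain them; ring-free
molecules share a single sentinel key.

## Synthetic data: what it emulates, and what it does not

`generate_smiles_dataset()` builds molecules from a fixed grammar of ~30
ring scaffolds and a pool of substituent chains, then plants activity:
actives carry at least one marker substructure (thiol, nitrile, or primary
aliphatic amine) with probability `marker_effect` (default 0.9), inactives
with probability `1 − marker_effect`; labels are then flipped with
probability `label_noise` (default 0.05) and pIC50 values are drawn
consistently with the final label. The default composition is 1314 actives
to 275 inactives, matching the roughly 5:1 imbalance the pipeline is
designed for; tests and the acceptance script use smaller sizes of the same
shape so the suite runs in minutes. Ring-bearing substituents keep the
Bemis–Murcko framework space large, so random train/test splits contain
genuinely novel frameworks (roughly a third of test frameworks are unseen
at the scales the acceptance script uses).

This generator emulates the *statistical* structure the method assumes —
imbalance, substructure-driven activity, label noise, scaffold novelty —
and nothing else. Real bioactivity data have activity cliffs,
assay-dependent noise, correlated measurement batches and much broader
chemistry; passing tests on the generator shows the machinery is correct
and that the stacking signal-recovery logic works, not that any particular
real-world accuracy will be achieved.

`generate_feature_dataset()` skips chemistry entirely: binary features
with `n_informative` columns whose presence probability is shifted by
`effect_delta` between classes. It drives the tests that need exact control
of where signal lives (feature-selection recovery, ensemble benefit,
null-effect checks).

## Numerical choices and degenerate inputs

* All randomness flows from a single integer seed through a deterministic
  child-seed derivation, and RNG state is restored after every call, so
  package functions never perturb the caller's stream. Two runs with the
  same seed and configuration produce byte-identical metric JSON.
* MCC with a zero denominator is 0 (flagged); SN/SP/BACC with empty
  denominators are `NA` (flagged), never silently 0.
* Tanimoto between two empty fingerprints is 0 with a warning.
* Selection ties break toward smaller m; `which.max` over an
  ascending-size grid implements this directly.
* Constant PFV columns are legal (importance ≈ 0); an all-constant PFV is a
  degenerate-input error.
* Folds exceeding the subset size raise a typed fold error rather than
  producing empty folds.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on generated data:
sampling invariants over 200 random size/seed configurations; metric
identities over 1000 random confusion tables; feature-selection recovery on
600/120 samples × 150 features with 10 informative columns over 10 seeds;
ensemble benefit with 3 algorithms × 2 blocks × 5 subsets on 5:1 imbalanced
data over 10 seeds; and an end-to-end chemistry run with 250/50 compounds.
These sizes are the package's own scaled-down mirror of the study-scale
configuration (which is also exercised structurally: 790/159 → five
158-compound slices, 30 base models per subset, a 150-wide PFV, 15
selection candidates).

## Known limitations

* Probability calibration is whatever the SVM's Platt fit provides; no
  additional calibration layer is applied.
* No applicability-domain estimate accompanies predictions; screening
  ranks are meaningful within the library screened, not absolutely.
* Scaffold extraction prunes exocyclic double-bonded atoms (plain
  framework semantics).
* The PLS-DA probability clip is a projection, not a calibrated mapping.
* Fingerprint blocks are deterministic for a fixed OpenBabel version;
  artifacts produced under different toolkit versions should not be mixed.
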