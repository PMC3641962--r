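---
title: "Classifying BCRP (ABCG2) substrates with support vector machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying BCRP (ABCG2) substrates with support vector machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrpsvm)
```

## The problem

The breast cancer resistance protein (BCRP, gene *ABCG2*) is an ATP-binding
cassette efflux transporter that pumps a chemically diverse range of drugs
out of cells. Whether a compound is a *substrate* of wild-type BCRP matters
for oral absorption, brain penetration, and drug–drug interactions, but
measuring transport experimentally is slow. `bcrpsvm` implements a
ligand-based (QSAR) route: a soft-margin support vector machine over
molecular descriptors, trained on compounds with known substrate status,
that classifies new molecules as `substrate` or `non-substrate`.

The package covers the whole modelling pipeline — descriptor computation and
ingestion, descriptor elimination, F-score feature selection with
correlation pruning, kernelized SVM training with exponential grid search,
a multi-run random-split evaluation protocol, overfitting-aware model
selection, and cross-model classification-overlap analysis — together with
a synthetic data generator so that every stage is testable without any
proprietary descriptor software or compound download.

## The model

Given scaled descriptor vectors $x_i$ with labels $y_i \in \{+1, -1\}$
(substrate / non-substrate), a C-SVM finds the maximum-margin decision
function

$$f(x) = \sum_i \alpha_i y_i K(s_i, x) + b, \qquad 0 \le \alpha_i \le C,$$

where the $s_i$ are support vectors. Three kernels are supported; the
default is the radial basis function

$$K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2),$$

with the linear kernel $\langle x_i, x_j\rangle$ and the polynomial kernel
$(\gamma \langle x_i, x_j\rangle + c_0)^d$ available for comparison. The
quadratic program is solved by libsvm (through `e1071`); decision values
are then recomputed from the stored support vectors by the package's own
kernel code, which makes models serializable to plain-text JSON and pins
the tie rule (a decision value of exactly 0 maps to `substrate`;
configurable in `predict()`).

Performance is summarized by overall accuracy (ACC), sensitivity (SE,
accuracy on substrates), specificity (SP, accuracy on non-substrates) — all
percentages — and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
 {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}} \in [-1, 1].$$

A zero factor under the root makes the MCC undefined; `performance()`
reports `NA` in that case rather than silently substituting 0 (a
`mcc_zero_convention` switch restores the common 0 convention). Display
rounding is one decimal for the percentages and three for MCC; full
precision is always retained in the returned objects.

## Descriptors

Five descriptors — the ones used by the final published substrate model —
are computed natively from 3D structures:

| Name | Meaning |
|------|---------|
| `AAC` | Mean information index on atomic composition: Shannon entropy (bits) of the element-count distribution, hydrogens included |
| `SPH` | Spherosity: $3\lambda_3 / (\lambda_1+\lambda_2+\lambda_3)$ from the eigenvalues of the (unweighted) covariance of atomic coordinates; 0 = planar/linear, 1 = isotropic |
| `Mor17m`, `Mor25m` | 3D-MoRSE signals $\sum_{i<j} w_i w_j \sin(s r_{ij})/(s r_{ij})$ at scattering parameters $s = 16$ and $s = 24\ \text{Å}^{-1}$ (signal $k$ maps to $s = k-1$, the conventional Mor01–Mor32 grid), mass-weighted |
| `R2m` | GETAWAY R autocorrelation of lag 2: $\sum_{d_{topo}(i,j)=2} \sqrt{h_i h_j}/r_{ij} \cdot w_i w_j$ with leverages $h_i$ from the molecular influence matrix $H = M(M^\top M)^{-1}M^\top$, mass-weighted |

Mass weights are carbon-scaled, $w_i = m_i / m_C$. These definitions follow
the standard descriptor-handbook forms; the commercial Dragon software's
exact implementation is unpublished, so values here will not match Dragon
output bit-for-bit. Every other descriptor a practitioner may want enters
through `load_descriptor_table()`, which ingests Dragon-style delimited
exports; the rest of the pipeline is agnostic to where a column came from
(column provenance is recorded as `computed` or `ingested`).

Numerical choices worth knowing: for planar or linear molecules the Gram
matrix $M^\top M$ is rank-deficient and the Moore–Penrose pseudo-inverse is
used for $H$ (the result is flagged); coincident-atom geometries make
spherosity undefined and raise an error; structures materialized from
SMILES get 2D layout coordinates and explicit hydrogens (Open Babel) and
are *refused* by the 3D descriptors rather than silently embedded in 3D,
because the original modelling geometries came from a force-field
optimization this package deliberately does not replicate. Atomic masses
are pinned in the package (IUPAC 2021 standard weights) for
reproducibility.

## Preprocessing

Two elimination rules run before modelling, in a fixed order:

1. **Sparsity** — drop descriptors with strictly more than 80% exact zeros
   (`zero_fraction = 0.8`; the zero test is exact equality by default since
   descriptor exports carry literal zeros, with an `eps` option).
2. **Low variation** — drop descriptors whose sample SD relative to their
   range is below 3% (`rel_sd = 0.03`), constants always. The underlying
   elimination criterion ("SD less than 3%") does not say 3% *of what*; SD
   relative to range was chosen because it is unit-free and matches the
   intent of removing near-constant columns. Both thresholds are arguments.

Survivors are min–max scaled to $[-1, 1]$ — the libsvm convention — with
parameters fitted on **training rows only**. Test and external compounds may
scale outside $[-1, 1]$; they are not clipped. By default the elimination
filters run once on the modelling set before splitting (treating descriptor
elimination as dataset-level preprocessing, the common QSAR convention); a
strict `per_split` mode refits them inside each training split.

## Feature selection

Each descriptor gets an F-score,

$$F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar x)^2}
           {s^2_{+} + s^2_{-}},$$

the ratio of between-class mean separation to the summed within-class
variances (the `fselect.py` definition used with libsvm). Ranking is by
descending F with lexicographic tie-breaks for determinism. Descriptors
correlated at $|r| \ge 0.9$ are then pruned in a single greedy pass in
F-score order, so of any correlated pair the higher-scoring member is kept.
Finally features are added one at a time in rank order, evaluating
cross-validated accuracy after each addition, and the walk stops at the
first strict decrease, returning the set before the decrease (never fewer
than one feature; a first feature below the majority-class baseline is
flagged in the trace).

On strongly separable data, cross-validated accuracy can hit its ceiling
after two or three features and then plateau indefinitely, so a strict
decrease never arrives. Two guards exist for that regime: `run_protocol()`
caps the walk at `max_features = 25` descriptors by default, and
`greedy_forward_selection()` offers an alternative `patience` stop rule
(stop after *p* non-improving steps and return the set at the first
maximum). The default remains the strict-decrease rule.

## Hyperparameter search

`grid_search()` evaluates every pair on exponentially growing sequences,
$C \in 2^{-5}, 2^{-3}, \ldots, 2^{15}$ and
$\gamma \in 2^{-15}, 2^{-13}, \ldots, 2^{3}$, by stratified 5-fold
cross-validated accuracy **on the training set** (using the test set here
would leak information into model choice). Fold assignment is a
deterministic function of the seed. Ties prefer the smaller $C$, then the
smaller $\gamma$ — the least complex model. The grid ranges and fold count
are the conventional coarse defaults for libsvm-style tuning; no canonical
values exist for this problem, so both are arguments and are recorded in
every result object.

## The evaluation protocol

`run_protocol()` reproduces the multi-run design: `n_runs = 100` independent
random splits of the modelling set (default training fraction 0.75, giving
167 train / 56 test from 223 compounds; `|train| = floor(fraction * n)`),
and for each split the full chain — scaling, F-score ranking, correlation
pruning, greedy selection, grid search, final refit on the whole training
split — is redone from scratch (the most conservative reading of the
protocol; feature selection and tuning are never reused across splits).
The external validation set is scored once per run and never participates
in any modelling decision; splits are plain random by default (a
`stratified` switch exists). Per-run seeds are derived deterministically
from the base seed, so the entire experiment is byte-reproducible.

`compare_kernels()` and `sweep_ratios()` stack mean ACC/SE/SP/MCC per
category across kernels and training fractions (0.5–0.85).
`select_best_model()` ranks runs by the absolute training–test accuracy
gap, then by the number of selected descriptors, then by run index —
overfitting-aware selection that deliberately ignores external performance.
`overlap_matrix()` compares the selected models pairwise by the percentage
of compounds classified identically.

## The synthetic generator

Real modelling inputs (proprietary descriptor exports for 263 compounds)
cannot ship with the package, so `make_descriptor_dataset()` generates
datasets with the statistical structure the pipeline assumes, and with
known ground truth. Defaults mirror the study conditions: 164 substrates
vs 99 non-substrates, 5 informative descriptors among 100, and a
class-mean separation of `delta = 3` within-class SDs. The generator
plants:

- **informative** columns: unit-variance normals with class means at
  $\pm\delta/2$;
- **noise** columns: class-independent standard normals;
- **correlated duplicates**: near-copies of informative columns
  ($|r| > 0.99$) with the class signal attenuated to 95%, so the original
  is always the more discriminative member — what the correlation pruner
  must remove;
- **zero-inflated** columns with an exact planted zero fraction — what the
  sparsity filter must remove;
- an optional **borderline fraction** of compounds whose informative
  profile is drawn at the class midpoint while keeping the true label,
  emulating the region where substrates and non-substrates are too similar
  to separate and creating irreducible error by construction.

`make_split_fixture()` carves out an external validation set with
proportional class allocation (defaults reproduce the 223 = 139/84
modelling + 40 = 25/15 external layout). `toy_molecules()` provides seven
fixed-geometry molecules (methane, water, ethane, benzene, CO₂, isobutene,
propan-2-ol) whose descriptor values are checked against independent
brute-force formula evaluations in the test suite.

What passing tests on synthetic data do **not** show: real descriptor
distributions are skewed, heavy-tailed and block-correlated rather than
Gaussian with isolated duplicates, and real substrate/non-substrate
boundaries are not linear shifts. The synthetic results validate the
machinery (selection, tuning, leakage-freedom, calibration under the
null), not the attainable accuracy on chemical data.

## Problem sizes used in validation

The packaged checks run the full protocol (100 runs, default grids) on the
263-compound synthetic analog, a 10-seed null calibration at `delta = 0`
(one run per seed), and a 10-seed selection-recovery study at 5 runs per
seed on a 150/75 analog. These sizes were chosen so the complete validation
executes comfortably on a single CPU while still exercising the protocol at
the scale of a realistic substrate data set.

## Known limitations

- Native descriptor values follow published definitions, not Dragon's
  unpublished implementation; models trained on Dragon exports and on
  native values are not interchangeable.
- No force-field geometry optimization, charge assignment, or
  tautomer/stereochemistry normalization; coordinates are taken as given.
- Disconnected structures (salts) are refused by default;
  `largest_fragment()` is an explicit opt-in.
- Whether the original modelling filtered descriptors on the full
  modelling set or per split, and whether salts were stripped, is not
  documented; both are exposed as options with the defaults stated above.
- MCC is undefined (reported `NA`, not 0) when a confusion-matrix marginal
  is empty, which can happen on tiny evaluation sets.
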