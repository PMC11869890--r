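---
title: "pathsyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathsyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how `pathsyn` computes what it computes, which knobs
matter, and the design decisions taken where the methodology was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The problem and the model

Given (a) a drug table with target-gene sets, SMILES and toxicity terms,
(b) a pathway gene-set collection, (c) multi-omics matrices for cancer cell
lines, and (d) a dose-response screen of drug pairs on those cell lines,
the package predicts which (pair, cell line) instances are synergistic.
The central idea is to use pathways as the bridge between drug space and
cell-line space, so that the same 157-ish pathway axes describe both what a
drug pair perturbs and what a cell line dysregulates.

### Pathway-bridge featurisation

With indicator matrix $D$ ($d_{ij} = 1$ iff drug $i$'s targets intersect
pathway $j$), Jaccard matrix $P$ over pathway gene sets, and
$\tilde{D} = DP$, a pair $(i, j)$ scores
$a_{ijk} = \tfrac12 (d_{ik}\tilde{d}_{jk} + d_{jk}\tilde{d}_{ik})$
on pathway $k$. The construction is symmetric in the drugs, zero on
pathways neither drug touches, and — because $P$ has unit diagonal —
dominates the plain indicator: $\tilde{D} \ge D$ elementwise. These
properties are asserted as invariants in the tests, and the whole chain is
checked against naive set-arithmetic loops at $10^{-12}$ tolerance.

Upstream, drugs and pathways are screened for density: at least 10 targets
per drug, at least 10 genes per pathway, and each pathway must be acted on
by at least half of the retained drugs. All bounds are inclusive. Two
points were underdetermined and decided here:

- **Denominator of the coverage fraction.** The half-of-drugs criterion is
  evaluated against the drugs retained by the target screen (not the
  pre-screen roster). The screen is described as a single pass, so that is
  how it is implemented — one pass in the order target screen, size
  screen, coverage screen; it is not iterated to a fixpoint.
- **Screening order independence.** The retained sets are invariant to
  input row order, which the tests quantify by permutation.

### Drug-level blocks

MACCS keys are computed from SMILES with OpenBabel (via `ChemmineOB`),
using the standard 166-key dictionary; the padding position of 167-bit
toolkit outputs is discarded. Toolkits disagree on a few
aromaticity-sensitive keys for fused heteroaromatics (key 125 for caffeine
is the canonical example); the test oracle therefore freezes
independently computed reference vectors for molecules where toolkits
agree bit-for-bit. Descriptor columns present in fewer than 10 drugs are
dropped *before* pair encoding; toxicity terms need only one attached
drug. Drugs with no toxicity annotation get all-zero vectors rather than
being dropped. A pair is encoded as the elementwise sum of the two drug
vectors, read as 0/1/2 = neither/one/both.

### Cell-line blocks

Expression (TPM) and copy-number ratios are transformed
$x \mapsto \log_2(x+1)$. Methylation and RNAi matrices drop rows with NA
in **strictly more than** 70% of cell lines, then KNN-impute: a missing
entry (gene $g$, cell $c$) is the mean value at $c$ of the $k = 5$ nearest
rows, with distance the root mean squared difference over jointly observed
columns (scaling by the count of shared columns keeps rows with unequal
missingness comparable) and only rows observed at $c$ eligible. $k = 5$ is
a conventional default; the imputation is exercised with $k = 1$ and
$k = 2$ closed-form toys in the tests. Probe-level rows mapping to one
gene are averaged per cell line after imputation.

Continuous omics are scored per (cell line, pathway) with a single-sample
gene-set variation statistic: each gene's values are mapped through a
Gaussian-kernel CDF estimate across cell lines (bandwidth $s_i/4$), genes
are ranked per cell line with symmetric weights $|N/2 - \text{rank}|$, and
a weighted KS random walk down the ranked list yields the maximum
deviation as the enrichment score, bounded in $[-1, 1]$. Numerical
choices: the bandwidth is floored at $10^{-8}$ of the global value range
so constant gene rows score finitely rather than erroring; when the
positive and negative walk extremes tie in magnitude the negative one is
taken; the max-deviation statistic is used throughout (no
magnitude-difference variant). The implementation reproduces an
independent reference implementation on a frozen 12-gene × 4-cell fixture
to $10^{-6}$. Mutations are consumed as per-cell mutated-gene sets and
scored by Jaccard overlap with each pathway; an empty mutated set scores 0
everywhere by convention (empty intersection over a non-empty union).

### Labelling

The combination score of a (pair, cell line) group is the mean over dose
points of (expected growth − observed percent growth) — positive when the
pair suppressed growth more than the additive expectation. Concentration
identity is deliberately ignored. Labels are strict: a score exactly at
the threshold is non-synergistic. Single-agent rows and a configurable
exclusion list (by default the duplicate vinorelbine catalogue id
NSC753082) are removed first.

## 2. Modelling choices

- **Split and scaling.** 80:20 stratified split; per-column
  standardisation is estimated on the training partition only and applied
  to both sides. Train-only statistics are the leak-free reading of an
  ambiguous convention; the alternative (scaling on the pooled data) leaks
  a small amount of test information.
- **Imbalance correction** toward a 2:1 negative:positive ratio:
  inverse-frequency class weights (the positive-class weight is the
  negative:positive count ratio; no resampling, so the 2:1 target does not
  apply to counts), random majority undersampling, or SMOTE oversampling
  (uniform interpolation between a minority point and one of its 5 nearest
  minority neighbours). The direction of undersampling is worth a note:
  reducing the *majority* class is the only reading consistent with
  reaching a 2:1 negative:positive ratio when positives are the minority,
  and that is what is implemented.
- **Cross-validation.** Stratified 5-fold. The default is leak-free:
  resampling happens inside each fold's training split, so no synthetic
  point derives from held-out data (assertable through the provenance
  flags `rebalance` returns). A resample-first mode (rebalance once, then
  fold) is provided behind a flag because it is a protocol one encounters
  in practice; its metrics are optimistic for over/undersampling — the
  tests assert the direction of that optimism rather than hiding it.
- **Hyperparameters.** Grid search scores each point by mean
  cross-validated AUPR (the metric of record under imbalance; ties keep
  the first grid point). The production default grid includes learning
  rate 0.1, depth 7, 700 rounds. Desk-scale tests use smaller
  forests — the vignette's scales are stated below.
- **Metrics.** AUC is the Mann–Whitney rank statistic with mid-ranks;
  AUPR is step integration of the precision–recall curve over distinct
  thresholds (average precision); precision is defined as 0 when nothing
  is predicted positive; thresholded metrics use score > 0.5. The
  implementation is cross-checked against an independent reference at
  $10^{-9}$ on random vectors with ties.
- **Feature-set search.** All $2^8 - 1 = 255$ block subsets (or $2^B - 1$
  generally) under one identical configuration; subsets ranked separately
  on recall, F1 and AUPR (min-rank for ties), ordered by average rank with
  AUPR then bitmask as tie-breaks.
- **Importance.** Per-feature gain summed per block, normalised to
  proportions; top-k refits (k = 1..5, 10) trace how quickly per-block
  importance saturates.

## 3. The synthetic study

The generator exists so every stage is testable end-to-end with no
downloads. Defaults — 500 genes, 20 drugs (190 pairs), 30 pathways of
10–50 genes, 12 cell lines, 9 dose points (a 3×3 grid's worth), ≈ 2,280
instances — run the full pipeline in well under a minute on one CPU; the
end-to-end learning checks (one strong-signal fit plus ten null fits) take
about two minutes. Construction:

- pathway gene sets are sampled without replacement; each drug draws ~70%
  of its ≥ 10 targets from 1–3 "home" pathways, so drugs act coherently;
- each cell line has a sparse activity vector (≈ 5 strongly active
  pathways); omics values are a per-gene baseline plus the summed activity
  of pathways containing the gene, so pathway scoring of the omics
  recovers the activity;
- the planted synergy of (pair, cell) is
  $\alpha \cdot z(\langle a_{pair}, w_{cell}\rangle) + \sigma\varepsilon$
  with $z$ standardised and $w_{cell}$ the rectified activity — the signal
  flows *exactly through the pathway-bridge features* the model sees,
  which is the checkable form of the pathway-as-bridge claim;
- each instance emits dose records with observed = expected − synergy −
  dose noise, so averaging recovers the planted value exactly at zero
  noise, and with the default $\alpha = 10$, $\sigma = 1$,
  $\sigma_d = 3$ the recovery regression has unit slope and $R^2 > 0.95$;
- the labelling threshold is placed at the 90th percentile of the planted
  synergy, giving ≈ 10% prevalence, a realistic rate for synergy screens.

With $\alpha = 0$ the labels are independent of every feature and the
pipeline's held-out AUC is chance-level; the tests check both regimes.

What the generator does **not** emulate: real fingerprint structure (bits
are Bernoulli draws; actual SMILES exercise the MACCS path separately),
marginal distributions of real screens, dose-response curve shapes,
batch effects, or inter-pathway correlation beyond shared genes. Passing
tests therefore demonstrate correctness of the machinery and
recoverability of a pathway-mediated signal — not expected performance on
any real screen.

## 4. The validation statistic

For replicate viability tables, with the best monotherapy the arm of lower
mean viability, $\Delta via$ the mean-viability improvement of the
combination over it and $HR$ their mean ratio, the score is
$\Delta via - \Delta via \times HR = \Delta via^2 / \overline{via}_{best}$,
hence non-negative and zero exactly when combining adds nothing; values
above 0.004 are called synergistic. The estimator from replicates is not
fully pinned down by the statistic's usual presentation (replicate
pairing and an efficacy- versus viability-based ratio are both
conceivable); `pathsyn` uses unpaired arm means, the simplest reading,
and treats the 0.004 decision bound — not any particular point value — as
the check. Viabilities above 1 are retained, not clamped.

## 5. Known limitations

- The GSVA-style scorer is $O(\text{genes} \times \text{cells}^2)$ per
  assay; it is meant for hundreds-to-thousands of genes and tens-to-
  hundreds of cell lines, not single-cell scale.
- SMOTE interpolates in the standardised feature space; with very few
  minority instances (< k+1) it refuses rather than degrades.
- The classifier adapters (logistic, lasso, RF, SVM) exist for protocol
  comparisons; only the gradient-boosted path supports gain-based
  importance decomposition.
- No dose–response curve fitting, no Loewe/Bliss/HSA/ZIP reference models:
  the expected-growth column is taken as given.
- `pathsyn` deliberately has no network clients; real drug/pathway/omics
  dumps must be provided in the documented tabular formats.
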