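---
title: "Predicting self-interacting proteins from PSSM bi-gram features with a relevance vector machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting self-interacting proteins from PSSM bi-gram features with a relevance vector machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipRVM)
```

## The problem

Self-interacting proteins (SIPs) are proteins whose copies bind each other,
forming homodimers and higher homo-oligomers. Homo-oligomerization matters
for signal transduction, enzyme activation, immune response and gene
regulation, but experimental confirmation of self-interaction is slow, so
sequence-only prediction is attractive. Pair-level predictors of
protein–protein interaction lean on co-expression, co-localization or
co-evolution of *two different* partners — none of which exists for a
protein against itself — so SIP prediction needs its own pipeline.

sipRVM implements such a pipeline:

1. **Evolutionary representation.** Each protein is represented by its
   position-specific scoring matrix (PSSM), the L × 20 profile produced by
   an iterative PSI-BLAST search (e-value 0.001, 3 iterations against a
   large non-redundant database — recorded in `psiblast_config()`; the
   search itself is outside this package). Rows are mapped to probability
   profiles by `normalize_pssm()`.
2. **Bi-gram transition features.** `bigram_features()` summarizes the
   profile by the expected adjacent-position transition mass for each
   ordered amino-acid pair:
   \[ B_{mn} = \sum_{i=1}^{L-1} P_{i,m}\, P_{i+1,n},
      \qquad 1 \le m, n \le 20 , \]
   giving 400 features per protein after row-major flattening
   (`flatten_bigram()`). Because each row of \(P\) sums to one, the 400
   features sum to exactly \(L - 1\): one unit of transition mass per
   adjacent pair. This invariant anchors much of the test suite.
3. **Compression.** `fit_pca()` / `apply_pca()` reduce the 400 features to
   350 components by default (mean-centered PCA, no variance scaling),
   discarding low-variance directions that mostly carry sampling noise.
4. **Classification.** `rvm_fit()` trains a relevance vector machine — a
   sparse-Bayesian kernel model — on the projected features, and
   `predict()` scores new proteins; the evaluation harness
   (`repeated_holdout()`, `evaluate_sip()`) reproduces the five-repeat
   1/6-holdout protocol with mean ± sd reporting.

## The relevance vector machine

The classifier is kernel regression on the 0/1 class labels with a
Gaussian likelihood. With a design matrix
\(\Phi = [\,1, k(x_i, x_j)\,]\) (bias column plus a Gaussian-kernel basis
centred on every training point), targets are modeled as
\(t = \Phi w + \varepsilon\), \(\varepsilon \sim N(0, \sigma^2 I)\), and
each weight carries an independent zero-mean Gaussian prior with precision
\(\alpha_i\). At fixed hyperparameters the weight posterior is Gaussian:

\[ \Sigma = (\sigma^{-2}\Phi^\top\Phi + A)^{-1}, \qquad
   \mu = \sigma^{-2}\, \Sigma\, \Phi^\top t, \qquad A = \mathrm{diag}(\alpha). \]

Hyperparameters are driven by type-II maximum likelihood (evidence
maximization), iterating the standard re-estimates

\[ \gamma_i = 1 - \alpha_i \Sigma_{ii}, \qquad
   \alpha_i^{\mathrm{new}} = \gamma_i / \mu_i^2, \qquad
   \sigma^2_{\mathrm{new}} = \frac{\lVert t - \Phi\mu \rVert^2}{N - \sum_i \gamma_i}. \]

Most \(\alpha_i\) diverge during training; their bases are pruned (default
threshold \(10^9\)), and the few training points whose bases survive are
the *relevance vectors*. The fitted decision function is
\(y(x) = w_0 + \sum_j w_j\, k(x, \mathrm{rv}_j)\), thresholded at 0.5 by
default (a score equal to the threshold counts as positive; raising the
threshold trades sensitivity for specificity).

This is deliberately the *regression-form* RVM applied to binary labels,
not the logistic RVM with a Laplace approximation: it is the simpler
formulation whose posterior has the closed form above, and the
`beta = 0` setting recorded in `sip_config()` selects exactly this mode.
The test suite exploits the closed form: at fixed \(\alpha\), the
posterior mean must coincide with ridge regression
\((\Phi^\top\Phi + \sigma^2 A)^{-1}\Phi^\top t\), which an independent
`solve()` call verifies to 1e-8 relative error.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kernel_width` | 2 | Gaussian width; \(k(x,y) = \exp(-\lVert x-y\rVert^2 / \mathrm{width}^2)\) |
| `kernel_convention` | `"width2"` | `"half"` selects \(\exp(-\lVert x-y\rVert^2 / 2\,\mathrm{width}^2)\) |
| initial \(\alpha_i\) | \(1/N\) | uniform, weakly informative start |
| initial \(\sigma^2\) | \(0.1\,\mathrm{var}(t)\) | a fraction of the label variance |
| `prune_threshold` | 1e9 | \(\alpha_i\) above this removes basis \(i\) |
| `tol` | 1e-3 | converged when \(\max_i \lvert\Delta \log \alpha_i\rvert\) falls below |
| `max_iter` | 1000 | sweep cap; best state returned with a warning otherwise |
| `pca_k` | 350 | retained components (the evaluation studies here use 50 at n = 200, since k cannot exceed the training fold size) |
| `threshold` | 0.5 | decision threshold on the regression score |

Both kernel conventions are in real-world use; the default divides by the
squared width directly, matching common RVM toolboxes. The kernel formula,
the \(\sigma^2\) initialization and the pruning/convergence constants are
not forced by the model and are therefore exposed in the config rather
than hard-coded.

## Feature scale and the kernel: a design decision

A Gaussian kernel width is only meaningful relative to the scale of its
inputs, and bi-gram features have no fixed scale: their total mass is
\(L - 1\), so a 150-residue protein lives roughly twice as far from the
origin as a 75-residue one. Feeding raw PCA scores to a width-2 kernel
makes the kernel matrix essentially diagonal — the model memorizes
training points and generalizes poorly.

The pipeline therefore rescales the projected training scores by a single
scalar — the square root of their total variance — and applies the same
factor to any test data (`scale = "total_variance"` in `sip_config()`;
`"none"` restores raw behaviour). After this, typical squared distances
sit near 2, where a width of 2 resolves structure. The factor is a
training-fold statistic, so the rescaling leaks nothing from held-out
data. This is the same reasoning behind the `scale = TRUE` default of
common SVM interfaces, applied once globally rather than per feature so
that the relative variance structure PCA found is preserved.

## Normalizing PSSM scores

PSI-BLAST emits integer log-odds scores, not probabilities. The mapping to
row-wise probability profiles is a genuine choice: this package applies
the elementwise logistic \(1/(1+e^{-x})\) — the common convention for
PSSM-derived features, bounded and monotone — followed by row
renormalization so the bi-gram mass invariant holds exactly. A `softmax`
row transform is available as a config switch for users who prefer a
Boltzmann reading of the scores. Rows at non-standard residues (X/B/Z/U)
are kept, with a warning, since PSI-BLAST still scores them and dropping
rows would silently change \(L\).

## The synthetic data generator

Real inputs require a PSI-BLAST search against a non-redundant database
and curated interaction databases for labels; neither fits in a test
suite. The generators make every stage testable offline:

* `generate_pssm()` draws each profile row from a symmetric Dirichlet —
  small concentration gives peaked (conserved) positions, large gives
  near-uniform ones.
* `generate_sip_dataset()` plants class signal exactly where the bi-gram
  features look: each protein is a latent residue path from a first-order
  Markov chain, with per-position Dirichlet rows peaked on the path
  (peak 8 over base 0.25, putting roughly two thirds of a conserved row's
  mass on its residue). Negatives use a uniform transition matrix;
  positives multiply 20 planted transitions — the symmetric pairs
  \((m, m+10)\) and \((m+10, m)\) for \(m = 1..10\), a
  palindromic-motif-like signature covering 5% of the 400 transitions —
  by `effect_size` before row renormalization. `effect_size = 1` is an
  exact null; larger values move the planted bi-gram coordinates apart in
  a way that is tunable and interpretable. Sequence lengths are uniform
  on 60–150, long enough for stable transition mass and short enough for
  fast tests. Features are computed through the public
  `bigram_features()` path, so the generator cannot drift from the
  production featurization.
* `generate_blobs()` provides the classical two-Gaussian fixture for RVM
  unit tests, and `write_synthetic_pssm_dir()` materializes raw integer
  PSSMs in the PSI-BLAST ASCII dialect (plus a matching FASTA) so the
  parser and the file-based featurizer are exercised on real files.

What the generator does **not** emulate: homology structure (rows are
conditionally independent given the latent path, whereas PSI-BLAST rows
share alignment context), realistic amino-acid composition, database
search noise, or the label noise of curated interaction data. Passing
tests therefore demonstrate that the pipeline recovers adjacent-position
transition signal under controlled conditions — not that it reproduces
published accuracies on curated proteome datasets, which would require
the external databases.

## Evaluation protocol

`split_plan()` holds out a random sixth of the data as an independent
test set and repeats the construction five times (both configurable),
reporting each metric as mean ± sample sd. Splits are stratified by
default so each fold preserves the class ratio — with strong imbalance
(real SIP data runs roughly 1:11 positive:negative) an unstratified
sixth can easily lose most positives; an unstratified mode exists. A
per-fold pipeline is refit from scratch — PCA, scale factor and RVM —
on the training fold only.

Metrics are accuracy, sensitivity \(TP/(TP+FN)\), specificity, precision
and Matthews correlation, plus a threshold-sweep ROC whose trapezoidal
AUC equals the concordance probability (verified against pair counting
and against pROC in the tests). A metric with a zero denominator (e.g.
precision with no positive calls) is reported as 0 with a warning flag
rather than an error, so batch summaries never abort; folds whose test
set lacks positives are flagged in the report.

## Numerical choices and degenerate inputs

* Posterior solves use a Cholesky factorization with jitter escalation
  (0, 1e-10, 1e-8, 1e-6 of the mean diagonal) before declaring a
  conditioning failure — after aggressive pruning,
  \(\sigma^{-2}\Phi^\top\Phi + A\) can be nearly singular.
* In early sweeps of a full model (all \(N + 1\) bases active with small
  \(\alpha\)), \(\sum_i \gamma_i\) can transiently reach \(N\), making the
  \(\sigma^2\) denominator non-positive. The exported `rvm_update()`
  treats this as an error by contract; inside `rvm_fit()` the previous
  \(\sigma^2\) is retained for that sweep instead. A perfect fit floors
  \(\sigma^2\) at 1e-12; an underflowing \(\mu_i^2\) (below 1e-300) sends
  its basis to the prune threshold.
* PCA component signs are fixed so the largest-magnitude loading of each
  component is positive, making models deterministic and serializable;
  training contains no randomness at all, so refits are bit-identical and
  row-permutation changes the decision function by less than 1e-8.
* Exact duplication of the training set is *not* bit-invariant: the
  \(\alpha\) initialization \(1/N\) and the \(\sigma^2\) re-estimate both
  see \(N\), and duplicated kernel bases need not prune back to the
  original support. The learned classification agrees (identical training
  labels, probe-score correlation above 0.99) but scores can shift at the
  second decimal; the tests assert the invariance that actually holds.
* The per-sweep log marginal likelihood is recorded as a diagnostic. The
  update equations do not guarantee monotonicity, and near convergence
  the trace shows sub-1e-6 float oscillation on a plateau; the test
  allows that tolerance and requires 95% of sweeps non-decreasing.
* Model archives are JSON at 17 significant digits, which round-trips
  IEEE doubles exactly; identical training inputs give byte-identical
  archives.
* A one-row PSSM has no adjacent-position transition, so
  `bigram_features()` rejects \(L < 2\) as degenerate rather than
  returning a zero vector. Single-class label vectors are rejected by
  `rvm_fit()` for the same reason: no discriminative model exists.

## Problem sizes in the tests

The suite exercises the pipeline at desk scale, chosen so the default
test run completes in well under a minute of compute per module: planted
signal studies use 200 proteins (balanced), PCA to 50 components and
five holdout repeats; oracle-equivalence checks run 100 random profiles
with lengths 2–200 and 50 random posterior problems; the blob sparsity
fixture uses 200 points. `scripts/acceptance.R` recomputes the same
quantities end to end from a single seed.

## Known limitations

* The regression-form RVM emits uncalibrated scores, not probabilities;
  the 0.5 threshold is a convention, and heavily imbalanced data may
  warrant tuning it (no class reweighting is applied).
* Batch evidence maximization is \(O(N^3)\) per sweep in the active basis
  count; thousands of training points call for the incremental
  (fast marginal likelihood) algorithm, which is out of scope here.
* The PSSM parser reads the standard `psiblast -out_ascii_pssm` dialect
  only (first 20-score block); the percentage block and
  information-content columns are ignored by design.
* Published headline accuracies on curated yeast/human SIP datasets are
  not reproducible without those datasets and an NR-scale PSI-BLAST; this
  package validates the method's machinery, not those numbers.
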