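---
title: "Compressive subsampled ensemble analytics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressive subsampled ensemble analytics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbda2)
```

## The problem and the protocol

High-dimensional tabular biomedical data — population surveys, biobank
extracts, imaging-derived phenotypes — routinely pair thousands of features
with an outcome of interest, with heavy missingness, multicollinearity, and
no credible parametric model. `cbda2` mines such data for the small set of
features that reproducibly predict the outcome, using a compressive
subsampling strategy:

1. **Subsampling.** Draw `M` independent subsamples, each a fixed, small
   block of `n_cases` cases (with replacement) by `n_features` distinct
   features. The block size is fixed, not proportional, so the per-subsample
   work is independent of the full data size. Each training block is paired
   with a disjoint validation block of `validation_factor * n_cases` cases
   on the same features.
2. **Ensemble prediction.** On each block, fit a stacking ensemble: every
   base learner in a registry produces out-of-fold predictions under V-fold
   cross-validation, and non-negative meta-weights on the simplex combine
   them. The ensemble is scored on the paired validation block (accuracy and
   MSE).
3. **Feature mining.** Rank the `M` models by validation performance, keep
   the top `M*`, and count how often each feature appears among them.
   Informative features accumulate counts because the blocks containing them
   rank high. A cutoff `mu + z_(1-alpha) * sigma` on the frequency
   distribution declares positives; scanning `M*` and `alpha` grids and
   integrating the per-alpha precision-recall points selects the `M*` that
   maximizes the PR AUC.
4. **Diagnostics.** The distribution of ensemble weights across all `M`
   models versus across the top `M*` shows whether the protocol converged to
   a subset of better-performing learners; Bray-Curtis dissimilarity against
   a matched run on pure-noise data, and the variance of the weights over
   `M*`, quantify the contrast.
5. **Overfitting test.** Nested ensembles on the top-k ranked features
   (k = 1..K) on one fixed disjoint split locate the smallest model size
   whose performance is within tolerance of the best.

The central assumption is weak and structural rather than parametric: if a
feature carries signal, blocks that happen to include it tend to validate
better than blocks that do not, for at least one learner class in the
registry. No linearity, distributional form, or effect homogeneity is
assumed.

## Why the frequency cutoff is normal-shaped

At `M* = M` every feature's count is Binomial(`M`, `k/p`) where `k` is the
per-block feature draw: with `p` in the hundreds-to-thousands, the
distribution of the `p` counts is well approximated by a normal, so
`mu + z * sigma` with `z = qnorm(1 - alpha)` is a calibrated one-sided
false-discovery control (at `alpha = 1e-6`, `z = 4.75`). At smaller `M*`
the null counts remain exchangeable across uninformative features and the
same functional form applies, now with the signal features pushed into the
upper tail. Two variants of the cutoff are provided, differing in which
histogram supplies `mu` and `sigma`:

* `stats_source = "at_m_star"` (default): the frequency distribution of the
  top-`M*` table itself;
* `stats_source = "at_m_total"`: the all-`M` distribution.

Both are legitimate readings of the procedure; the default uses the
distribution actually being thresholded, which is self-consistent across
`M*` values. The declaration rule is a strict inequality (`count > cutoff`);
boundary equality is negative, the conservative choice.

A deliberate interpretation: significance levels such as `1e-6` are read on
the decimal scale (`qnorm(1 - 1e-6) = 4.75`). A natural-log mode exists in
[fdr_cutoff()] for completeness, but the decimal grid
(0.9, 1e-2, 1e-5, 1e-10, 1e-16, 1e-20) is the default.

## Precision-recall over ROC, and the AUC convention

With thousands of features and ~10 real ones, true negatives dominate any
ROC summary; precision-recall curves ignore true negatives and discriminate
much better between `M*` settings. Conventions used, chosen to keep the
integral in [0, 1] and degenerate cases meaningful:

* precision = TP/(TP+FP), recall = TP/(TP+FN) — the standard definitions;
* an undefined ratio (empty denominator) is 1: no mistake of that kind was
  possible;
* the curve is anchored at recall 0 with the precision of the
  lowest-recall point and integrated by the trapezoidal rule up to the
  largest observed recall, with no extrapolation to recall 1;
* ties in the AUC trajectory resolve to the smaller `M*` (cheaper
  downstream).

## The ensemble meta-step

The meta-learner solves non-negative least squares of the outcome on the
out-of-fold prediction matrix (Lawson-Hanson NNLS), then renormalizes onto
the simplex — the canonical stacking default, well-posed for both binary
and continuous outcomes. A log-loss mode (simplex-parameterized likelihood
optimization initialized at the NNLS solution) is available for binary
outcomes. Learner failures are tolerated: a failing learner's column is
dropped with weight 0 and a warning; a training block with a single outcome
class is a degenerate subsample, skipped and logged by the training stage.
Binarization uses `prediction >= 0.5 -> class 1`, ties to class 1.

The registry mirrors the major learner classes rather than enumerating many
hyperparameter variants per class: regularized GLMs (glmnet), random
forests (ranger), gradient boosting (xgboost), SVM (e1071), k-nearest
neighbours, a small neural network (nnet), bagged regression trees (rpart),
and the constant-mean reference. `default_registry()` spans all classes
(~12 learners); `lean_registry()` is the three-learner fast set (lasso,
random forest, boosting) used throughout the scaled benchmark runs. Tree
ensembles in the lean set are deliberately small (30 trees, 12 boosting
rounds) and the lasso picks its penalty by AIC along a short path: on
300 x 30 blocks these settings lose little accuracy but keep a full
`M = 500` training stage within minutes on one CPU. Larger grids are a
`learner()` call away.

## Synthetic benchmarks and the accuracy oracle

Two generators define the test bed:

* **Null**: features i.i.d. N(0,1), outcome i.i.d. Bernoulli(0.5),
  independent of everything — any flagged feature is a false discovery;
* **Binomial**: `k_true` features (default 10) drive a linear score
  `Z = sum(b_j X_j) + e`, `e ~ N(0, noise_sd^2)`, and
  `Y ~ Bernoulli(plogis(Z))`.

The generative coefficients default to `b_j = 2` with `noise_sd = 1`. With
ten such features the score's signal standard deviation is `sqrt(40)`, and
the achievable classification accuracy sits near 90% — a regime where the
protocol must genuinely rank features rather than trivially separate
classes, and which matches the plateau this benchmark family is known for.
Generation order is fixed (features, then score noise, then outcome), so a
seed identifies a dataset exactly.

`bayes_accuracy_oracle()` computes the accuracy ceiling by Monte-Carlo
simulation of the generator. A subtlety worth stating: the score noise `e`
is not observable, so the ceiling is the accuracy of the best
feature-measurable rule — by symmetry, the sign of the observable signal
`S = sum(b_j X_j)` — with `e` integrated out:
`E[plogis(S+e) 1(S>0) + (1-plogis(S+e)) 1(S<=0)]`. Conditioning on the full
score `S + e` instead would overstate the ceiling (and would not reduce to
0.5 when all coefficients vanish, as a ceiling must). For the default
configuration the ceiling is 0.902 (2e6 draws).

## Data wrangling conventions

The filters abstract recurring survey-data pathologies:

* a feature is constant if it has fewer than two distinct non-missing
  values; all-missing columns count as constant;
* the missingness fraction uses the total case count as denominator and the
  threshold is inclusive (`<=`), matching an "at most X% missing" rule;
* the level census never counts `NA` as a level;
* pseudo-binary features coded with sentinel levels (e.g. 0, 1, -1, -3) are
  recoded by dropping the sentinels; affected cases become missing, unless
  the feature is the outcome, in which case they are removed;
* subsample imputation uses training-block statistics only (median for
  numeric features, mode for features with at most two levels), applied
  unchanged to the paired validation block — leakage-free, cheap, standard.
  The imputation rule is this package's choice; nothing in the protocol
  depends on it beyond completeness of the blocks.

All filters preserve the order of surviving rows and columns and are
idempotent.

## Determinism and parallelism

Every subsample's seed is an affine hash of `(master_seed, id)` over a
prime modulus below 2^31, so any subsample can be recomputed in isolation
and the full record set is a pure function of the plan and the data —
independent of the worker count and of checkpoint interruptions. The
training stage appends one JSON line per completed record; rerunning skips
completed ids. Features are drawn *without* replacement within a block
(duplicate identical columns are degenerate for every learner); the
with-replacement character of the protocol lives across blocks, which is
where it matters.

## Sizes used by the test suite

The package's own checks run at desk scale, chosen once as realistic
miniatures of the benchmark family: Binomial runs at `n = 10000`,
`p = 1000`, `M = 500` blocks of 300 x 30 with 600-case validation and
3-fold internal CV under the lean registry; Null false-discovery runs at
`n = 2000`, `p = 500`, `M = 200`; the overfitting curve uses a
3000/1000-case split. At these sizes the training stage recovers at least
8 of the 10 generative features among the top 10 frequencies in nearly
every seed, the Null runs flag nothing at `alpha = 1e-6`, and the nested
curve plateaus at the oracle ceiling by `k = 10`. Full-scale runs
(`M = 5000`, 10-fold CV, the ~12-learner registry) are configuration
changes, not code changes.

## What the synthetic results do and do not show

The generators produce i.i.d. Gaussian features. Real survey data are
correlated, mixed-type, and missing-not-at-random; with strongly collinear
blocks the per-block feature draw can be enlarged via the variance
inflation factor (`vif`), trading computation for the chance of co-sampling
correlated features, and recovered rankings should be read as
representatives of correlated clusters rather than unique causal features.
Passing the synthetic checks demonstrates calibration of the frequency
machinery and the mining read-out under known truth; it does not certify
performance under strong collinearity or informative missingness.

## Known limitations

* The dataset must fit in memory; the subsampling API is the natural
  streaming hook, but no out-of-core reader is provided.
* Binary and continuous outcomes only; no multinomial or survival support.
* The overfitting stage uses a single fixed split by design (differences
  along the curve then reflect feature sets only), so its curve carries
  split noise of order `sqrt(0.25 / val_size)`.
* No permutation-based alternative to the normal-approximation cutoff.
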