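---
title: "Debiasing by feature-weighted subsampling: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Debiasing by feature-weighted subsampling: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwmrs)
```

## The problem and the model

Two samples are drawn from the same population: a non-representative sample
`N` that carries the outcome of interest, and a representative reference
`R` that does not. The goal is a reweighting of `N` under which its
distribution matches `R`'s, so that models trained on reweighted `N`
generalize to the population.

MRS solves this discriminatively. A domain classifier is trained to tell
`R` (label 1) from `N` (label 0); as long as it succeeds better than
chance, the rows of `N` it scores as most confidently non-representative
are removed (their sample weights set to exactly 0), and the process
repeats. Framing matters: because `N` may contain perfectly representative
rows, the task is positive-unlabeled learning — `R` supplies the positives,
the active rows of `N` are treated as negatives even though some are not.
Per iteration the pooled active rows are split into k folds stratified by
source; the weighted domain classifier is trained on k−1 folds and scored
on the hold-out, and only these out-of-fold scores are used both for the
stopping statistic (fold-mean AUROC) and for the drop ranking, so no row is
judged by a model that saw it.

The feature-weighted extension observes that when only a few features are
strongly biased, aligning them costs disproportionately many samples and
can distort already-representative features. It therefore computes
per-feature importances `I` of an *unweighted* domain classifier once,
before the loop, and passes `softmin(I, t)` as feature weights to every
weighted classifier inside the loop and to the downstream model. Low
temperatures concentrate weight on the least biased features (few drops,
but biased features go uncorrected and underused); high temperatures
approach uniform weights and plain MRS behavior. Importances are not
refreshed inside the loop: the weights describe the bias of the *original*
`N`, which is also what the downstream model must compensate.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `temperature` | 0.25 | softmin scale; the searched grid is 0.001–0.5. Because importances are normalized to the simplex, the peakedness of a given `t` grows with the importance contrast and shrinks with dimension: on a handful of encoded columns, `t = 0.05` is already close to a hard argmin selection. 0.25 is the conservative default — mild weighting that preserves downstream performance — and aggressive weighting is an explicit opt-in |
| `k` | 5 | CV folds per iteration |
| `d` | 1 | rows dropped per iteration (5 for datasets above the 6000-row subsample cap in the benchmark plan; an empirical runtime choice, not a statistical one) |
| `auroc_stop_threshold` | 0.5 | stop once fold-mean AUROC ≤ threshold. "No better than random" includes equality, and finite-sample AUROC jitter makes the `<` vs `≤` distinction immaterial; the field exists for testing and is deliberately not promoted as a user knob — it would be one more hyperparameter with no principled setting |
| `n_trees` | 200 | domain-classifier forest size |
| `min_weight_fraction_leaf` | 0.01 | leaf regularization, mapped to `min.node.size = ceiling(fraction × n)`; 0.01 is a mid-grid value that also bounds tree depth, keeping Shapley attribution affordable |
| `C` | 1 | SVM / PSA regularization; grids span 1e-2–1e2 logarithmically |

## Numerical and design choices

**Encoding.** Categorical features are one-hot expanded over the union of
levels across the input datasets; z-scoring uses pooled statistics so `N`
and `R` share one space (per-dataset centering would erase exactly the
shifts the methods must detect). Standardization is applied only for the
kernel and linear methods (SVM, KMM, PSA, MMD); forests get raw encodings.
Missing values are a hard error, never imputed — imputation would silently
alter the distributions being compared. Feature weights live on encoded
columns; `estimate_importance(aggregate = encoding_groups(map))` optionally
pools a one-hot group's importance before softmin so a categorical is
weighted as one feature. We default to per-column weights and make no claim
that either convention matches other implementations.

**Importances.** Global importance is the mean absolute Shapley
attribution over the pooled rows — the standard global reduction. For the
forest variant, attributions are exact interventional tree Shapley values
(implemented in C++): absent features take values from a background row
and attributions are averaged over a seeded background subsample of the
pooled rows, capped at 100 rows, the customary budget for interventional
attribution, beyond which estimates change negligibly while cost grows
linearly. Linear SHAP for the SVM variant is `beta_j (x_ij - mean_j)`. A
permutation importance (mean AUROC drop over 5 shuffles) is selectable for
large inputs. An all-zero importance vector (classifier at chance) falls
back to uniform weights with a warning, so the loop degrades gracefully to
MRS rather than erroring.

**Weighted forest.** The forest is implemented natively (C++): at every
split, `candidate_features_per_split` candidate features are drawn *with
replacement* with probability proportional to the feature weights
(duplicates collapse), and the best weighted-Gini cut among the candidates
is taken. Drawing with replacement is essential: renormalized
without-replacement sampling would force near-zero-weight (highly biased)
features back into every candidate set, the classifier would keep
discriminating on them, and low temperatures would stop retaining samples —
the soft feature selection only works if peaked weights can effectively
exclude a feature. At exactly uniform weights the candidate law reduces to
ordinary random-forest sampling (up to duplicate collapses), so the MRS
special case uses a bona fide random forest. Zero-weight features are
never candidates. Rows are bootstrapped uniformly; sample weights enter
impurity, leaf values, and the minimum-leaf-weight constraint, which
implements `min_weight_fraction_leaf` exactly on weights. All randomness
uses a platform-independent generator, so fits are bit-reproducible.

**Weighted SVM.** Columns are scaled by `w_f` directly (the kernel of the
weighted MMD scales *squared* differences, which would suggest `sqrt(w_f)`;
both are monotone reparameterizations and we document the choice rather
than claim it). Per-sample weights multiply a squared-hinge loss; the
objective is smooth and minimized with L-BFGS-B. Probabilities come from a
Platt sigmoid on training decision values — calibration is monotone, and
only the ranking matters for the drop step.

**Weighted MMD.** Sample weights are normalized to sum 1 inside the
estimator, so it is a discrepancy between weighted empirical measures
(binary subsampling weights become `1/n_active`, and KMM/PSA weights need
no prior normalization). The summation ranges follow the only reading under
which `MMD(X, X) = 0`; a radicand within −1e-12 of zero is clamped. The
bandwidth heuristic (mean pairwise distance of the pooled rows, exact up to
2000 rows, seeded subsample above) is computed on standardized, feature-
unscaled rows: the heuristic predates the weighting. Reported MMD tables
carry both a uniform-`w_f` variant (comparable across methods) and the
method's own `w_f` (the quantity the feature-weighted loop actually
targets); the temperature analysis reports both because they move in
opposite directions at low temperature — dropping fewer samples raises the
uniform-kernel MMD while the feature-weighted MMD falls, since the kernel
itself stops looking at the biased features.

**Stopping, ties, determinism.** Drops use out-of-fold scores only; ties
are broken by ascending row index for reproducibility (any fixed rule
works; the score ties are measure-zero for continuous scores). All
randomized steps (fold shuffles, bootstrap, candidate pools, background
subsampling) derive child seeds from one master seed, so a run is
bit-reproducible. Total iterations are bounded by `floor((n-1)/d) + 1`
because each non-terminal iteration removes exactly `d` active rows;
`max_iterations` defaults to that bound and exists only to surface
contract violations. If fewer than `d + 1` active rows remain before the
threshold is met, the run returns an explicit infeasible status with *no*
weights — a sample whose bias cannot be mitigated should not be silently
usable downstream.

**Cross-validation design.** Folds partition the pooled active-N ∪ R rows,
stratified by source, because per-fold AUROC needs both classes in every
hold-out; all of `R` participates in each round. A fold whose hold-out
still lacks a source is skipped from the mean (possible only for
pathological sizes); if all folds are skipped the round errors.

**KMM.** The QP uses the method's classical box bound `B = 1000` and slack
`eps = (sqrt(n)-1)/sqrt(n)`, solved by an interior-point method with a
1e-8 diagonal jitter on the Gram matrix. Raw weights are passed downstream
without renormalization (the MMD normalizes internally); PSA propensities
are clipped to `(1e-6, 1-1e-6)` to keep `(1-pi)/pi` finite.

**Corrected t-test.** `t = mean(d) / sqrt((1/(rk) + n_test/n_train) var(d))`
with `rk − 1` degrees of freedom; the inflation term models the correlation
between fold estimates induced by overlapping training sets. Zero variance
is handled explicitly (p = 1 at zero mean, p = 0 otherwise).

## What the synthetic generator emulates — and what it does not

`generate_population()` draws independent Gaussian numeric features and
multinomial categoricals, with a logistic outcome on the numeric features;
`inject_bias()` undersamples the positive class to a retained fraction
(default 10%), emulating, e.g., an underdiagnosed condition. Because the
outcome depends on the predictive features, undersampling positives shifts
exactly those features in `N` — so the biased features are also the
informative ones, which is the regime where feature weighting faces a real
trade-off and where uniform weighting is a strong baseline (it keeps all
predictive information at the cost of keeping the bias). The benchmark
harness (`run_experiment()`) mirrors the full protocol: 5-fold outer CV
repeated, the training rows split 50/50 into a biased `N` (outcome kept)
and a clean `R` (outcome withheld structurally, so leakage is a type error
rather than a discipline), an untouched test fold `T` materialized after
all fitting, joint grid search selected by weighted-forest CV AUROC over
`N`, and a 500-tree downstream forest.

What passing these tests does *not* show about real data: features here
are independent within a sub-population and shifts are location shifts;
real survey bias involves correlated, ordinal and interacting features,
non-monotone selection mechanisms, and reference samples that are
themselves imperfect. The generator validates the machinery and its
qualitative mechanisms (convergence under no bias, alignment under the
undersampling injection, the temperature/retention trade-off), not field
performance.

## Problem sizes used by the test suite and acceptance script

The suite exercises the loop at the scale a single desk CPU handles in
minutes, chosen as the smallest sizes at which the mechanisms are clearly
expressed: 200 + 200 rows for null convergence (20 seeds); a 300-row
source sample (about 165 rows after the 10% positive-retention injection)
against a 250-row reference and 250-row hold-out for the efficacy checks
(20 seeds) — below roughly 100 biased rows the fold-mean AUROC is noisy
enough that the stopping rule can fire before any dropping happens; 60 +
60 rows across the full 9-point temperature grid (20 seeds); and a 600-row
population for the downstream benchmark. Monte-Carlo acceptance bands (e.g. "improved in ≥
90% of runs", Spearman ≥ 0 in ≥ 80% of seeds) are properties of these
stated conditions.

## Known limitations

* The loop retrains k classifiers per iteration; cost grows linearly in
  the number of drops. Large datasets want the SVM variant, larger `d`, or
  permutation importances.
* Binary sample weights discard information a soft reweighting could keep;
  this is by design (robustness to extreme weights) but means `fwmrs` will
  not outperform KMM/PSA on pure distribution-alignment metrics.
* AUROC ≤ 0.5 is a one-sided stopping rule on a noisy statistic; with very
  small samples it can fire an iteration early or late. The trace records
  every fold-mean so the trajectory can be inspected.
* Feature weights are per encoded column by default; a dominating
  categorical can therefore spread its importance across its levels before
  softmin unless aggregation is requested.
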