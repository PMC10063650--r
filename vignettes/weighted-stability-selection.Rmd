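---
title: "Weighted stability selection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted stability selection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wstabsel)
```

## The problem

In high-dimensional binary-outcome studies (radiomics signatures, speech
biomarkers, omics panels) with $p \gg n$, a single cross-validated LASSO fit
selects variable sets that fluctuate strongly between datasets drawn from
the same population. Stability selection addresses this by repeating the
base selector on subsamples and keeping variables that are selected in a
high fraction of them. Complementary-pairs subsampling strengthens this
idea: the sample is split $B$ times into two disjoint halves and a variable
only counts for a split when both halves select it.

wstabsel implements a weighted variant of that scheme for logistic models.
Classical stability selection treats all subsampling iterations equally;
here, each iteration is weighted by how well its selected variable set
actually predicts the outcome, measured by the AUC of a refit model, so
iterations that land on predictive sets count more.

## The estimator

Given data $\{(x_i, y_i)\}_{i=1}^n$ with $y_i \in \{0, 1\}$, for
$b = 1, \dots, B$:

1. Split the sample into halves of sizes $\lfloor n/2 \rfloor$ and
   $n - \lfloor n/2 \rfloor$. Fit a cross-validated logistic LASSO on each
   half and intersect the two supports.
2. Refit the intersection by unpenalized logistic regression on the full
   data and keep the variables significant at the 5% level (two-sided Wald
   test); call this set $\hat S^w_b$.
3. Refit $\hat S^w_b$ on the full data and record the in-sample AUC of its
   fitted probabilities, $\widehat{AUC}_b$.

The AUCs are min–max rescaled to weights
$\hat w_b = (\widehat{AUC}_b - \min_b)/(\max_b - \min_b) \in [0, 1]$, and each
variable accumulates the weighted frequency
$\hat A^w_j = \sum_b \hat w_b \, 1\{j \in \hat S^w_b\}$ (a weighted sum, not
an average). With $p^w$ the number of variables selected in at least one
iteration, the selected set is
$$\Big\{ j : \hat A^w_j \ge \frac{\sum_j \hat A^w_j}{p^w} \,\alpha \Big\},$$
so $\alpha$ is a multiplier on the mean weighted frequency of the
ever-selected variables: larger $\alpha$ means sparser selection, and the
selected sets are exactly nested as $\alpha$ grows.

The intersection and Wald-screen steps exist because the raw union of
half-sample LASSO supports is large and unstable in the $p \gg n$ regime;
screening at the conventional 5% level keeps only variables whose effect
survives an unpenalized full-data refit.

### The complementary-pairs baseline

`cpss()` implements the unweighted baseline. The base selector on each half
is "the first $q$ variables to enter the LASSO path", and a variable's score
is the fraction $\tilde\pi_j$ of splits in which it was in both halves'
first-$q$ sets; variables with $\tilde\pi_j \ge \pi_{thr}$ are stable. Rather
than choosing $q$ directly, the user states a tolerable per-family error
rate (the expected number of falsely selected variables) and $q$ is derived
by inverting the bound
$$E(V) \le \frac{q^2}{(2\pi_{thr} - 1)\, p}
\quad\Longrightarrow\quad
q = \big\lfloor \sqrt{\text{bound} \cdot (2\pi_{thr} - 1)\, p} \big\rfloor .$$
The floor is conservative (a smaller $q$ can only shrink the bound).

Three reported error bounds are available through `error_bound()`:
the assumption-free bound above; a closed-form tightening under the
assumption that a noise variable's simultaneous selection frequency is
unimodal; and a further tightening under $r$-concavity ($r = -1/2$ for the
simultaneous frequency on the $B$-pair grid, $r = -1/4$ for the simple
frequency over the $2B$ half-samples). The $r$-concave worst-case tail is
computed by root-finding over the extremal family $f(i) \propto (a + i)^{1/r}$
truncated at a support endpoint $k$: for each $k$ the scale $a$ is solved so
the mean matches its constraint, and the tail is maximized over $k$
(root-finding tolerance `1e-12`). The three bounds satisfy
r-concave $\le$ unimodal $\le$ none on any common input, which the test
suite asserts numerically. The assumption label affects only the reported
bound; $q$ always comes from the assumption-free inversion above, so the
selected set is identical across assumption labels.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `B` | 50 | complementary pairs; the study design throughout uses 50 |
| `alpha` | 1 | threshold multiplier; 1 = "mean weighted frequency"; recommended tuning grid 0–2 by 0.1 on a validation set |
| `lambda_rule` | `"min"` | CV rule for the half-sample LASSO fits (`"1se"` gives sparser half supports) |
| `folds` | 10 | stratified CV folds per half |
| `sig_level` | 0.05 | Wald screening level |
| `pfer_bound` | 1 | (cpss) tolerated expected false selections; study grid {1, 2, 5, 10} |
| `pi_thr` | 0.6 | (cpss) stability threshold; study grid {0.6, 0.75, 0.9} |
| `n_lambdas`, `lambda_min_ratio` | 100, 1e-4 | log-spaced penalty grid from $\lambda_{max}$ |

Decisions taken where the procedure description left room:

* **Per-half $\lambda$ rule.** Whether the half-sample fits use the
  deviance-minimizing penalty or the one-standard-error rule is not pinned
  down by the procedure; both are standard. The default is `"min"` (the
  richer support, letting the intersection and Wald screen do the
  pruning), exposed as `lambda_rule`.
* **Ever-selected candidates at small $\alpha$.** At $\alpha = 0$ the
  threshold is 0; restricting candidates to the ever-selected union makes
  "start at 0 and increase by 0.1" a sensible tuning path (otherwise
  $\alpha = 0$ would select all $p$ variables, including never-selected
  ones).
* **$p^w$ counts ever-selected variables**, including a variable whose
  every appearance carried zero weight; that is the literal reading of
  "selected at least once", and such a variable can still only be selected
  at $\alpha = 0$.
* **Degenerate iterations.** An empty intersection or an empty post-screen
  set yields an intercept-only model; all fitted probabilities tie, and the
  midrank AUC is exactly 0.5. The iteration is kept (flagged), and its
  weight follows from the min–max rescaling like any other.
* **All iteration AUCs equal.** The min–max scaler is undefined; weights
  degenerate to all 1, which reduces the estimator to unweighted
  complementary-pair counting. All-zero weights would instead select
  nothing and break the threshold's denominator semantics.
* **Separation.** If the unpenalized refit fails to converge or separates,
  a ridge-stabilized Newton fit (fixed small L2 on the slopes, never the
  intercept) replaces it so the AUC stays computable, and the iteration is
  flagged rather than discarded.
* **Tie-breaking in validation tuning.** `tune_on_validation()` maximizes
  validation AUC; ties go to the sparser selection, then to the larger
  parameter value. The final model is refit on the combined training and
  validation data.

## The synthetic-data generator

`generate_dataset()` emulates the simulation design the methods are
compared under: rows of $X$ i.i.d. $N_p(0, \Sigma)$ with $\Sigma$ either the
identity or Toeplitz $\Sigma_{kl} = 0.9^{|k-l|}$; `p_signal` coefficients
drawn from $U(0.5, 1.5)$ or $U(-3, 3)$ at uniformly random positions, the
rest exactly zero; and $y_i \sim \text{Bernoulli}(\text{logistic}(\beta_0 +
x_i'\beta))$ with target prevalence in {10%, 30%, 50%}.

Two implementation notes:

* **Prevalence calibration.** A zero-intercept logistic model with a
  symmetric predictor distribution cannot produce a 10% or 30% event rate,
  so the generator calibrates an intercept $\beta_0$ by bisection until the
  Monte-Carlo marginal event probability matches the target within
  ±0.005. Because $x'\beta \sim N(0, \beta'\Sigma\beta)$ exactly, the
  Monte-Carlo draw is a scalar Gaussian sample ($10^5$ draws), not an
  $n \times p$ matrix. This preserves the stated linear predictor and
  covariance while making every prevalence attainable.
* **Signal placement.** Signal positions are drawn uniformly at random
  rather than contiguously; under the Toeplitz band, contiguous signals
  would be mutually correlated at 0.9, which is a different (and easier to
  confound) problem than scattered signals. Random placement avoids
  building that choice silently into every scenario.

The Toeplitz draw uses the exact AR(1) recursion
$x_k = \rho x_{k-1} + \sqrt{1-\rho^2}\,\varepsilon_k$ (no Cholesky factor),
and each scenario seed is split into independent streams for coefficients,
predictors and responses, so a validation set (`role = "validation"`)
shares the true model but nothing else.

What the generator does **not** emulate: non-Gaussian or discrete
predictors, heteroscedastic noise, missingness, and the block/cluster
correlation patterns of real radiomics or speech features. Passing tests on
these simulations therefore demonstrates correctness of the algorithms and
calibration under the stated Gaussian design, not performance on any
particular real dataset.

## Evaluation metrics

`tpr()`/`ppv()` compare a selection against the generative signal set;
`pairwise_stability()` averages Jaccard, Ochiai or Dice similarity over all
$D(D-1)/2$ pairs of replicate selections (computed exactly, no
subsampling); `auc_mw()` is the Mann–Whitney AUC with midrank tie handling;
`validation_auc()` refits the selected set without penalty on the training
data and scores held-out data. Edge conventions: PPV of an empty selection
is 0; two empty sets have similarity 1 and exactly one empty set 0 (total
failure is penalized, while consistently selecting nothing counts as
stable); single-class AUC inputs return 0.5 with a warning.

## Numerical choices and degenerate inputs

* LASSO paths and CV fits are delegated to glmnet (standardization inside
  the solver, coefficients on the original scale, convergence threshold
  `1e-7`); CV folds are stratified by outcome and deterministic given a
  seed. If a class has fewer members than the requested folds, the fold
  count is reduced with a warning.
* Zero-variance columns are dropped from paths with a warning and reported
  as never active; aliased columns in refits are dropped with a warning.
* Half-samples with a single class are redrawn (up to 20 times per pair)
  rather than skipped, keeping the effective number of pairs at `B`.
* Entry-order ties (two variables activating at the same grid point) break
  by the larger absolute coefficient at activation, then by column index,
  making `first_q_active()` deterministic.
* `derive_q()` adds `1e-9` before the floor so exact squares survive
  floating-point (e.g. bound 1, $\pi_{thr} = 0.6$, $p = 500$ gives exactly
  $q = 10$).

## Problem sizes used by the test suite

The suite exercises the full algorithms at reduced problem sizes chosen to
keep a complete run in the low tens of minutes on one CPU while leaving the
statistical claims testable: null-calibration at $n = p = 200$ over 100
replicate datasets; signal recovery at $n = 500$, $p = 100$, 5 signals over
15 seeds; the Toeplitz comparison at $n = 500$, $p = 200$, 20 signals over
10 replicates; and property checks (nestedness in $\alpha$, oracle
equalities, hand-computed values) at toy sizes. The full study grid
(`default_grid()`) runs the same code paths unchanged at larger sizes.

## Known limitations

* The selector is specific to binary outcomes and the logistic LASSO;
  other base selectors, GLM families and survival outcomes are out of
  scope.
* In-sample AUC (step 3) is an optimistic estimate of each iteration's
  predictive value; it is used only *relatively*, via min–max rescaling
  across iterations, but iterations that overfit larger sets can still
  attract weight.
* The r-concave worst-case tail maximizes over the extremal truncated
  family described above; values were verified against the published
  closed-form cases and orderings, but not against an independent
  implementation of the same bound.
* Weighted stability selection has no analytic error bound: its false
  positives are controlled empirically (choose $\alpha$ on a validation
  set), not by a PFER guarantee.
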