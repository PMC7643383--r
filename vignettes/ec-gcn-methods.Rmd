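---
title: "Methods: group-sparse effective connectivity and population-graph GCN classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-sparse effective connectivity and population-graph GCN classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcn)
```

# Overview

`ecgcn` implements a diagnostic pipeline for resting-state fMRI ROI time
series, aimed at distinguishing patients with major depressive disorder
(MDD) from healthy controls (HC). The chain is:

1. **Signals** — read a cohort manifest and per-subject T x R ROI series;
   optionally regress out nuisance signals, band-pass filter, and
   standardize.
2. **Effective connectivity (EC)** — estimate, for every destination ROI,
   a sparse directed regression on all other ROIs, jointly over subjects
   with a group penalty that enforces a shared connection skeleton.
3. **Feature selection** — supervised least-squares LASSO on the
   vectorized connectivity, fitted per cross-validation fold on training
   subjects only.
4. **Population graph** — subjects become vertices; edge weights combine
   a Gaussian similarity of the selected imaging features with
   phenotypic agreement (gender match, age gap below a threshold).
5. **Classification** — a Chebyshev spectral graph convolutional network
   (GCN) trained transductively: all subjects participate in the
   convolutions, only training labels enter the loss.
6. **Interpretation** — gradient sensitivity analysis of the trained
   network, thresholded at mu + 1.5 sigma, mapped back to directed
   source-to-destination ROI connections.

A seeded simulator (`simulateCohort`, `simulateRegressionFixture`)
generates cohorts with known ground truth so that every stage is testable
without access to clinical data.

# Group-constrained sparse effective connectivity

For destination ROI $r$, subject $n$ contributes the regression
$x_n^r \approx X_n^{\setminus r} w_n^{\setminus r}$ of its signal on the
other $R-1$ ROI signals. All subjects are fitted jointly by minimizing

$$
\tfrac12 \sum_{n=1}^N \big\|x_n^r - X_n^{\setminus r} w_n^{\setminus r}\big\|_2^2
 + \alpha \sum_{j \ne r} \big\|(w_{1j},\dots,w_{Nj})\big\|_2 ,
$$

an $\ell_{2,1}$ group-LASSO penalty whose groups are *connections across
subjects*: a source ROI either predicts the destination in every subject
(with individual weights) or is dropped for everyone. This encodes the
assumption that the anatomical skeleton is shared while coupling
strengths vary between individuals.

Numerical choices:

* **Solver** — proximal gradient with group soft-thresholding (FISTA),
  step $1/L$ with $L$ the largest per-subject Gram eigenvalue, and a
  monotone safeguard: if the momentum step would increase the objective,
  the iteration falls back to a plain proximal step (which cannot
  increase it at step $1/L$) and momentum restarts. The recorded
  objective trajectory is therefore non-increasing, which the test suite
  asserts per iteration. Convergence is declared at a relative objective
  change below `tol` (default 1e-6, at most `maxIter = 1000` iterations);
  non-convergence yields a warning carrying the last objective value.
* **Standardization** — predictor and response columns are z-scored
  before solving (`standardizeInputs = TRUE`), so a single $\alpha$ is
  comparable across destination ROIs; coefficients are in standardized
  units.
* **Penalty scale** — `alphaMax(series, r)` returns
  $\max_j \sqrt{\sum_n (x_n^{j\top} x_n^r)^2}$, the smallest penalty
  whose all-zero solution satisfies the subgradient condition; the
  automatic default is $\alpha = 0.1 \times \mathrm{median}_r\,
  \alpha_{\max}(r)$, chosen once because no penalty value is available
  from the study this design follows.
* **Diagonal** — self-connections are structurally zero; vectorized EC
  keeps all $R^2$ positions (the $R$ structural zeros are constant
  features that the downstream LASSO can never select) so the
  index-to-connection mapping stays a pure arithmetic bijection.

Pearson correlation (`pearsonFC`, upper-triangle vectorization of
$R(R-1)/2$ entries) and pairwise Granger causality (`grangerEC`, log RSS
ratio of lag-$p$ autoregressions with and without the source's lags,
default $p = 1$) are provided as alternative feature kinds. The Granger
statistic is reported as a non-negative connectivity strength rather than
an F-test p-value because it is consumed as a feature, not as an
inference.

# Feature selection

`fitLassoSelector` solves a least-squares LASSO of 0/1 labels (MDD = 1)
on column-standardized features — the canonical form when "LASSO feature
selection" is specified without a link function. `lambda = "auto"` picks
`lambda.min` by 5-fold cross-validation *within the training fold*
(glmnet). The training-fold column means and SDs are frozen in the model
and reapplied to test subjects, so no test statistics leak into the
transformation. Inside `runPipeline`, if a fold's automatic penalty
selects nothing, the penalty is halved (up to 8 times) until the
selection is non-empty; this touches training data only.

# Population graph and spectral operators

Edge weights are

$$
W_{ij} = \exp\!\big(-\|f_i - f_j\|^2 / (2\sigma^2)\big)\,
 \sum_h \delta_h(p_i^h, p_j^h),
$$

with $\delta$ an exact-match indicator for gender and the indicator of
$|\mathrm{age}_i - \mathrm{age}_j| < \gamma$ for age (an optional
`education` column adds a third categorical measure). Defaults
$\sigma = 1$, $\gamma = 2$ years. Two conventions were genuinely open and
are resolved as follows:

* the Gaussian denominator is $2\sigma^2$ (the standard similarity
  kernel);
* self-weights are set to 0 — self-similarity is vacuous, and the
  *normalized* Laplacian is not insensitive to the diagonal.

The symmetric-normalized Laplacian is
$L = I - D^{-1/2} W D^{-1/2}$; its eigenvalues lie in $[0, 2]$ (a
sometimes-misstated range), so the Chebyshev filters operate on the
rescaled operator $(2/\lambda_{\max}) L - I$, whose spectrum lies in
$[-1, 1]$, the natural domain of the Chebyshev basis. Zero-degree
vertices keep an identity row in $L$, which isolates them from
convolution instead of dividing by zero.

By default the graph's feature vectors are the LASSO-selected
connectivity features of *all* subjects, recomputed per fold. This is
intentional transduction — test subjects' features (never their labels)
shape the graph and the convolutions, which is the point of
population-graph semi-supervised learning with small cohorts.

# The Chebyshev spectral GCN

Each layer computes
$H^{(l+1)} = \sigma\big(\sum_{k=0}^K T_k(\tilde L)\, H^{(l)}\, \Theta_k^{(l)} + b^{(l)}\big)$
with the recurrence $T_0 = I$, $T_1 = \tilde L$,
$T_k = 2 \tilde L T_{k-1} - T_{k-2}$; hidden layers use ReLU and the
output layer a row-wise softmax. The default architecture is one hidden
layer of 16 units with third-order filters ($K = 3$, so 4 basis terms);
the hidden width is a package default chosen for the small-cohort regime
(a few dozen subjects support little capacity) and is configurable.

Training minimizes the mean cross-entropy over labeled vertices plus
$\tfrac{\mathrm{wd}}{2}\sum \Theta^2$ (biases unpenalized; gradient
$\mathrm{wd}\,\Theta$, the `l2_loss` convention of the GCN code family).
Defaults: full-batch gradient descent at learning rate 0.05, dropout 0.3,
weight decay 5e-4, 200 epochs, no early stopping. Adam is available by
configuration. Inverted dropout is applied to the input features and
hidden activations during training only — never to the softmax output,
and never at prediction or sensitivity-analysis time. Dropout masks are
drawn from per-epoch seeds derived from the configuration seed, so
training is bit-reproducible.

Gradients are hand-written reverse-mode passes through the forward graph
(the Chebyshev operator matrices are symmetric, so each is its own
adjoint); `gradientCheck` verifies them against central finite
differences, and the test suite also checks the $K=0$ case against the
closed-form softmax-regression gradient. The per-epoch loss trajectory is
recorded from an extra dropout-free forward pass, so it reflects the
deterministic objective rather than dropout noise.

The recorded trajectory, prediction and relevance passes all reuse one
dense Chebyshev basis per training run; at cohort scale ($N \le$ a few
hundred) dense $N \times N$ operators are cheaper and simpler than sparse
ones.

# Sensitivity analysis

For subject $n$ and feature $d$, the relevance score is
$\big|\partial\, g_c(F)_n / \partial F_{nd}\big|$ — the absolute gradient
($\ell_1$ norm per coordinate) of the target-class softmax probability
with respect to the subject's own feature, computed by one reverse pass
per subject through the full transductive graph. The target class is MDD
by default (configurable to each subject's predicted class). Scores are
averaged over subjects; features whose mean score strictly exceeds
$\mu + 1.5\sigma$ are reported, sorted by descending score, with
$\sigma$ the *population* SD of the mean scores (no Bessel correction is
implied by the rule's phrasing; `sdType = "sample"` switches). Across
cross-validation folds, per-fold scores over all subjects are averaged
across the folds that selected each feature before thresholding, and the
threshold is applied once to the fold-averaged union.

# Evaluation statistics

MDD is the positive class throughout. ACC, SEN and SPE follow the
confusion-matrix formulas; AUC is the Mann-Whitney rank statistic with
ties averaged. `mcnemarTest` uses the continuity-corrected chi-square
when the discordant count is at least 25 (a common convention,
configurable) and the exact two-sided binomial otherwise. `twoSampleT`
computes pooled or Welch statistics from printed summary rows — both are
exposed because demographic tables in the literature mix the two
conventions (age-type rows match the pooled form, high-variance-ratio
rows like symptom scores match Welch). `sensitivityCi` is the
normal-theory interval $\mathrm{mean} \pm z\,\mathrm{SD}/\sqrt{n}$.
`diagnosticPower` is a simple large-sample normal approximation for how
often a study of a given case count pins the sensitivity within a stated
marginal error; it is deliberately not a reimplementation of any
specific published power procedure.

# The cohort simulator

`simulateCohort` draws a shared directed skeleton at the requested
density, base weights uniform in magnitude 0.3–0.8 with random sign,
subject-level Gaussian jitter (SD 0.1) on the skeleton, and adds
`effectSize` to a small subset of edges (10% of the skeleton, at least 3
edges) for MDD subjects. Signals follow the instantaneous linear model
$x_t = (I - A_n^\top)^{-1}\varepsilon_t$ with
$\varepsilon_t \sim N(0, \mathrm{noiseSd}^2 I)$ and each $A_n$ rescaled
to spectral radius at most 0.9 — the same contemporaneous structure the
EC estimator regresses, which is why an instantaneous generator rather
than a lagged VAR is the primary mode (`simulateVar1` exists for
exercising the Granger estimator). Ages are uniform integers on 20–60
and genders Bernoulli(0.6 female); by default the groups are
age-matched, with `ageShift` available to make phenotypes
class-informative. Defaults mirror a realistic small clinical cohort:
29 + 44 subjects and T = 170 time points; R defaults to 20 so the
simulations used by the tests and the acceptance script complete in
seconds on one CPU (the atlas this design targets has R = 114, and all
index arithmetic is exercised at that size).

**What the simulator does not emulate:** hemodynamics, autocorrelated
fMRI noise spectra, motion artifacts, site effects. Passing tests
therefore demonstrate correctness of the estimation and learning
machinery under the model's own assumptions, not clinical performance.

**Identifiability caveat.** With contemporaneous Gaussian data, the
population regression of one ROI on the rest has support equal to the
*moral graph* of the skeleton — true edges, their reversals, and
common-child pairs — so edge *orientation* is not identifiable from this
estimator, and directed support-recovery scores are structurally bounded
well below 1 even for an oracle. Orientation-agnostic (symmetrized)
recovery is the informative measure on simulated cohorts; the strict
recovery test uses `simulateRegressionFixture`, which generates data
from the estimator's exact single-destination model and where support
and weights are recovered to tight tolerances.

# Known limitations

* Directed interpretation of EC coefficients inherits the
  identifiability caveat above; reported source/destination roles follow
  the regression convention, not a causal discovery guarantee.
* The GCN is full-batch and dense; cohorts beyond a few thousand
  subjects would need sparse operators and minibatching, which are out
  of scope.
* LASSO selection uses the least-squares form on 0/1 labels; logistic
  LASSO, elastic net and stability selection are not provided.
* No head-motion exclusion rule is built in; subject exclusion is left
  to the user upstream of the manifest.
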