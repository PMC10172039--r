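---
title: "Inferring executable Boolean threshold networks from binarized expression series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring executable Boolean threshold networks from binarized expression series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btnet)
```

## The model

btnet infers gene regulatory networks as *Boolean threshold networks*: each
gene carries a binary state (expressed / not expressed), and gene $i$'s state
at time $t+1$ is a linear threshold function of the full network state at
time $t$,

$$x_i(t+1) = \left[\; \sum_k w_{k} \, l_{k}(t) \;\ge\; \theta_i \;\right],$$

where every weight $w_k$ is strictly positive and the literal $l_k$ is either
the regulator's state $x_k$ (activation) or its complement $1 - x_k$
(inhibition). Ties fire: a sum exactly equal to the threshold yields 1. All
genes update synchronously from the same input state. The rule class is
small enough to be interpretable — each inferred rule can be printed,
simulated and compared against observations — yet expressive enough to
encode the AND/OR-like regulatory logic that pure correlation networks
cannot represent.

The estimation trick is that a threshold rule is exactly the decision rule
of a logistic regression on the binary states. Writing the one-step-ahead
regression for target $i$ with coefficients $\theta_{ki}$ and intercept
$\theta_{0i}$, the maximum-likelihood decision boundary
$\sum_k \theta_{ki} x_k + \theta_{0i} \ge 0$ converts term by term:

* $\theta_{ki} > 0$: activating term with weight $\theta_{ki}$;
* $\theta_{ki} < 0$: inhibiting term with weight $-\theta_{ki}$ on the
  complemented literal;
* threshold $\theta_i = -\theta_{0i} - \sum_{\theta_{ki} < 0} \theta_{ki}$.

`ruleFromCoefficients()` implements this conversion, and the package's
property tests verify the equivalence exhaustively over all binary states
for thousands of random coefficient vectors. Because the conversion is
exact, the inferred network is simultaneously a signed, weighted, directed
graph *and* an executable dynamical model.

## The pipeline

Given a genes-by-time 0/1 matrix (from `binarizeSingleCell()`, which maps
every non-zero count to 1 and keeps dropouts at 0 without imputation, or
from `binarizeBulk()` for continuous profiles), `inferNetwork()` runs per
target gene:

1. **Design construction** — states at times $1..T-1$ predict the target's
   state at $2..T$; the target's own column stays in the design, so
   self-regulation is representable.
2. **Design perturbation** (optional) — binarized matrices frequently
   contain duplicated gene profiles, which makes the design rank-deficient.
   Adding i.i.d. $\mathcal N(0, \sigma^2)$ noise with a tiny $\sigma$
   restores full column rank with probability 1 while moving fitted effects
   by a negligible amount. One draw is shared by all genes, since they share
   the design.
3. **Penalized logistic fit** — elastic net via glmnet on the unstandardized
   0/1 scale; the intercept is never penalized. The penalty is either fixed
   or selected by stratified cross-validation on binomial deviance over an
   $\alpha$ grid and a 100-value $\lambda$ path (`cv = TRUE`).
4. **Edge calling** — see the next section.
5. **Aggregation** — surviving coefficients become the executable rule; the
   weight matrix column is the coefficient vector scaled by its maximum
   absolute entry, so the strongest regulator of each target has weight
   $\pm 1$.

Degenerate targets (constant response) cannot be regressed; they yield a
constant rule and an all-zero weight column. Failures in one gene never
abort the others.

## Edge calling

Which coefficients count as edges is the step that most affects structural
accuracy, and it is deliberately conservative. Three filters apply:

* **Perturbation cutoff** — coefficients with $|\theta| < \sigma$ are
  zeroed, on the raw and on the max-normalized scale. This removes the
  echo of the design perturbation (both scales matter because unpenalized
  fits on separable data have arbitrary overall scale). The default
  $\sigma = 10^{-4}$ is far below any meaningful effect on the
  normalized scale, where weights live in $[-1, 1]$.
* **Significance screen** (`screen = TRUE`, the default) — each candidate
  regulator is refitted out of the unpenalized model and kept only when the
  deviance increase exceeds a $\chi^2_1$ quantile at a Bonferroni-corrected
  familywise level of $10^{-4}$ across the $N^2$ candidate edges
  (`screenLevel`). Two properties motivate this design. On noiseless
  transition data from a realizable rule, removing an essential regulator
  breaks perfect separation, so the deviance jump is large and every true
  edge survives — exact recovery is untouched. Under state-flip noise the
  fit is finite and weakly supported edges fail the test, so the called
  edge set keeps precision near 1 at the cost of recall, the right
  trade-off for a sparse prediction problem in which false regulatory
  claims are costlier than missed ones. The stringent familywise level
  reflects that each of the $N^2$ pairs is an implicit hypothesis.
* **Separation handling** — "unpenalized" fits actually carry a ridge floor
  of $10^{-8}$, because the true maximum-likelihood optimum diverges on
  separable data. The floor leaves the sign pattern and the classification
  of every observation unchanged (the coefficient vector follows the
  max-margin direction) and makes the fit well defined and reproducible.

The relative order of pruning and normalization is exposed
(`pruneAfterNormalize`) for sensitivity checks; the default prunes raw
coefficients first so that surviving weights rescale to a maximum of 1.

## Evaluation

Structural metrics compare the called edges against a gold standard over
all $N^2$ ordered gene pairs *including self-loops* — self-regulation is
representable, so a self-pair is as falsifiable a hypothesis as any other.
`SIGN0` scores presence/absence; `SIGN1` additionally requires the correct
activation/inhibition sign, and a present-but-mis-signed edge is counted
against both precision and recall (this convention is the package's own
choice; with it, the four counts can exceed $N^2$ in total, so the
accuracy denominator is carried explicitly). For hard (unranked) edge
predictions the ROC curve has a single operating point, and
`aurocBinary()` reports the exact area of the two-segment curve through
it, $(\mathrm{TPR} + 1 - \mathrm{FPR})/2$; `auprScore()` similarly
integrates the three-point precision-recall curve, or a full ranked curve
when scores are meaningful. Dynamics are scored by one-step-ahead
('teacher-forced') prediction accuracy, `dynamicAccuracy()`: each observed
state predicts the next, so errors do not compound as they would in a
free-running simulation.

## The synthetic benchmark

`exampleNetwork9()` is a fixed nine-gene threshold network with 25 signed
edges, three self-loops and non-unit weights; `generateBenchmark()`
enumerates all $2^9 = 512$ states with their synchronous successors and
optionally flips every entry of both matrices independently with
probability $\delta$ (the state and successor matrices are both part of
the observed series, so both are corrupted; a targets-only mode exists for
sensitivity analysis). With complete noiseless data the design is full
rank, penalization is unnecessary (`lambda = 0`), and the package recovers
the generating network exactly — identical truth tables gene by gene — a
result the acceptance tests recompute from scratch.

What the generator emulates: exhaustive, uncorrelated state coverage;
symmetric measurement noise; paired state/successor observations. What it
does not emulate: trajectory-correlated sampling (real pseudo-time series
revisit similar states), zero-inflation (covered separately by
`induceDropout()`, which zeroes sub-threshold entries per gene with
probability 0.5 at a default 45th-percentile threshold, landing near a
20–25% realized dropout ratio), library-size variation, or continuous
expression dynamics. Passing the benchmark therefore demonstrates
correctness of the estimator and its edge-calling logic, not performance
on any particular real data set.

`randomBTN()` generates networks for property testing. It rejection-samples
thresholds until every rule is non-constant *and* every regulator is
essential — an inessential regulator (one whose value never changes the
rule's output) leaves no trace in the dynamics and is information-
theoretically unrecoverable, so demanding exact recovery of such an edge
would be meaningless.

## Numerical choices and problem sizes

* State enumeration order: binary counting with gene 1 as the
  least-significant bit. Any fixed order works (the regression is
  permutation-invariant); one is fixed for reproducibility.
* Tie semantics: `>=` everywhere, never configurable.
* Pseudo-time sorting is stable (ties broken by original column index).
* Boundary pruning: a coefficient exactly at $\sigma$ is kept.
* All randomness (perturbation, noise, CV folds, subsampling) flows through
  explicit seeds; identical seeds give bit-identical results, and run
  metadata records everything needed to reproduce an inference.
* Test problem sizes: the property suites use exhaustive state spaces at
  $N \le 8$ (where an essential regulator's minimum deviance signal,
  $2^{N-k+1}\ln 2$ for in-degree $k \le 4$, safely exceeds the screening
  cutoff) and average noisy-benchmark metrics over 20 noise seeds; these
  sizes make exact recovery provable rather than merely observed, while
  keeping the full suite inside a few minutes on one core.

## Limitations

* Synchronous updates only; asynchronous and probabilistic schemes are out
  of scope.
* One literal per (regulator, target) pair: a regulator cannot appear both
  activating and inhibiting in the same rule — a restriction inherited
  from the sign of a single regression coefficient.
* Pseudo-time is consumed, not computed; upstream ordering quality bounds
  everything downstream.
* The binarization for continuous (bulk) profiles — per-gene mean
  thresholding or a two-cluster split — is a simple stand-in; data with
  known bimodal structure may deserve a dedicated binarizer.
* Attractor analysis beyond fixed-point detection is not provided.
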