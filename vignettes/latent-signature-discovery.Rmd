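---
title: "Discovering latent clinical signatures and patient-specific causes from EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering latent clinical signatures and patient-specific causes from EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrsig)
```

## The model

`ehrsig` treats a patient record as the observable imprint of a set of
unobserved *latent disease sources*. Each source is a root node in the causal
graph over the observed EHR variables: mutually independent of every other
source, and injecting all outside information into the graph. A one-unit
increase in a source's *expression* changes the observed variables by a fixed
pattern — its *signature*. With linear effects and non-Gaussian expressions,
the observed cross-section matrix decomposes as

$$X = A\,S,$$

where the columns of $A \in \mathbb{R}^{n \times m}$ are signatures, the rows
of $S \in \mathbb{R}^{m \times t}$ are expressions, and mutual independence of
the rows of $S$ identifies the decomposition up to permutation, sign and
scale. Because the sources are independent root causes, a supervised model
$Y = H_c(S)$ on the expressions is a causal model of the outcome regardless
of $H_c$'s architecture, whereas the same model on the entangled variables,
$Y = H_s(X)$, is only associational. Per-sample Shapley values of $H_c$
therefore estimate patient-specific causal contributions of each source.

## From irregular events to a dense matrix

Raw EHR events are sparse, irregular and asynchronous. Each record's events
are converted to continuous curves, one transformation per mode:

* **Laboratory values** — shape-preserving cubic Hermite interpolation with
  Fritsch–Carlson slope limiting (exact at observations, monotone between
  them, no overshoot), constant extrapolation beyond the observed range, and
  a constant population median when a record never had the test. We
  implement the limiter directly because the slope filter must stay
  shape-preserving for *non-monotone* observation sequences, which R's
  `splinefun(method = "monoH.FC")` does not guarantee.
* **Billing codes** — the event stream is treated as a probabilistic signal,
  not ground truth: a Gaussian-kernel intensity estimate (events/year,
  bandwidth 180 days) with reflection boundary correction so that the
  integrated rate conserves the event count, stored as
  $\log(\text{rate} + \text{floor})$ with floor 0.01/yr. The log scale makes
  signature weights back-transform multiplicatively (a weight of
  $\log 2 / \sigma$ is "$\times 2$ code intensity").
* **Medications** — piecewise-constant 0/1 presence, each mention switching
  the curve on for a 90-day persistence window; overlaps merge.
* **Demographics** — constant 0/1 indicators per declared sex/race level
  (unknown levels give all-zero indicators) and a linearly increasing age
  curve.

Bandwidth, floor and persistence are exposed parameters; the defaults above
are package choices where no published convention exists, and each
transformation is a swappable strategy behind its constructor.

Curves are sampled at uniformly random times at a mean density of one sample
per three record-years (a record may be sampled several times or not at
all), stacked into an $n \times t$ matrix, and standardized **per variable**
to zero mean and unit variance. "Standardize each column" is ambiguous when
columns are samples; only the per-variable reading puts variables on a
common scale, so that is what `fitStandardizer()` implements. Evaluation
cohorts are sampled exactly once per record at the index day (the event that
anchors prediction), because prediction may use only information from the
index event and earlier.

## Discovery

`discoverSignatures()` performs PCA reduction/whitening to $m$ components
followed by symmetric fixed-point ICA with the logcosh contrast
($\alpha = 1$, tolerance $10^{-4}$, 500 iterations, explicit seed). Three
conventions fix the indeterminacies:

* **Sign** — each signature is flipped so its dominant (largest $|w|$)
  element is a positive change; ties break to the lowest variable index.
  The matching expression row is negated, leaving $A S$ invariant. Signs are
  oriented *before* scaling, so the stored affine parameters inherit the
  oriented polarity.
* **Scale** — expressions are pinned to mean 0, SD 0.5 on the discovery set;
  the per-source affine is stored and applied to all later inference. (The
  often-quoted "95% of expressions in $[-1, 1]$" is exact only for Gaussian
  expressions; for heavy-tailed sources it is descriptive, and we do not
  assert it.)
* **Inverse** — the non-square $A$ is inverted through the retained PCA
  subspace: `unmixing %*% mixing` is the identity on that subspace, and
  expressions for new standardized cross-sections are
  `affine(unmixing %*% (x - mean))`.

For display, `pruneSignature()` keeps the smallest top-$k$ by $|w|$ whose
retained $L_2$ norm is at least 97.5% of the full vector's, and
`backTransformEffects()` converts standardized weights to original units —
additive for labs/medications/demographics, multiplicative factors for code
intensities.

## Attribution

Three architectures (random forest, gradient-boosted trees, elastic-net
logistic) are trained in two input spaces (source expressions = causal; raw
variables = associational baseline; six configurations). Hyperparameters
come from small cross-validated grids (3–5 values per dimension) selected
once; training is then repeated across seeds on a common held-out test set
(`compareModels()`), defaulting to 10 repetitions as a desk-scale stand-in
for large seed studies.

Shapley values use a Monte-Carlo permutation estimator of
marginal-expectation (interventional) attributions with a fixed random
background subsample (default a few hundred training rows). The full
background is reused at every coalition, so the per-permutation
contributions telescope and the efficiency identity
$\text{base} + \sum_i \phi_i = f(x)$ holds exactly for every sample — the
`ShapleyExplanation` class enforces it. The estimator is validated in the
test suite against exact enumeration over all feature subsets at $d = 3$ and
against the closed form $\phi_i = w_i (x_i - \bar b_i)$ for additive models.
Whether conditional rather than marginal expectations better match clinical
deployment is an open modeling question; marginal expectations are the
variant consistent with treating sources as independent and intervenable.

`aggregateEffects()` applies the polarity convention: a source's
*malignant-direction* effect is the mean of its strictly positive per-sample
attributions, its *benign-direction* effect the mean of the strictly
negative ones, with ranks by $|$effect$|$ within each polarity (ties to the
lower source id; sources with no qualifying attributions get 0).
`expressionVsAttributionReport()` emits the per-record
(expression, attribution, outcome) triples and an expression-binned outcome
probability with exact binomial intervals — the view in which
partial-signature expression shows up: a record matching a cancer signature
*except* its dominant billing-code elements can express the source
negatively, because the inverse map $S = A^{-1}X$ is dense even though $A$
is sparse. The test suite reproduces this phenomenon qualitatively on
synthetic data.

## The synthetic cohort generator

Because institutional EHR data cannot be shipped, every downstream stage is
validated against a generator with known ground truth. A `GroundTruth` holds
a sparse mixing matrix with unit-norm, pairwise well-separated columns over
a catalog split roughly 40/40/10/10 across labs, codes, medications and
demographics; two dedicated sources drive sex (by sign) and race (by
terciles) so demographic signatures exist to recover.

Defaults define the study conditions used throughout the tests and the
acceptance script, chosen once on mechanistic grounds:

| parameter | default | rationale |
|---|---|---|
| source activity probability | 0.5 | expressions are sparse but common enough to learn from |
| active-expression law | Laplace, SD 1 | super-Gaussian, as identifiability requires |
| signature amplitude | 3 | one expression unit shifts a loaded lab by ~2–3 measurement-noise SDs and multiplies a loaded code rate severalfold — clinically meaningful effect sizes; far smaller effects are unobservable in principle |
| causal sources / weights | 3 of m; log-odds (4, 4, −4) | Bayes-optimal AUC ≈ 0.92 at positive rate 0.50, so the outcome carries clearly learnable signal with one protective source |
| record spans | exponential, mean 10 y, truncated to [60 d, 60 y] | long-tailed like real cohorts, bounded by the EHR era |
| lab observations | 4 per variable-year | each synthetic variable stands for an aggregate of many real ones |
| code base rate / med base logit | 2 per year / −2 | order-of-magnitude realism for aggregated concepts |
| lab noise SD | 0.25 | assay-scale noise below disease-scale effects |

Expressions are constant within a record (the discovery operates on
cross-sections; per-record constancy is the minimal structure that exercises
it), modes are generated independently given the expressions, and everything
is bitwise reproducible under a fixed seed. The generator deliberately omits
informative ("not at random") observation timing, within-record disease
dynamics, and inter-source causal edges — so passing tests demonstrate
correct machinery under the stated model, not robustness to those
real-data features.

`simulateCohort()` generates full event-level records;
`simulateCrossSections()` / `simulateEvaluationSet()` emit the matrix-level
regime (`amplitude * A %*% s` plus Gaussian noise, SD 0.1) directly.

## What the benchmarks do and do not show

* **Decomposition recovery** runs on 20,000 directly simulated
  cross-sections (8 Laplace sources, 60 variables): Hungarian-matched
  mean $|r|$ between true and estimated expressions is ~0.99. This is the
  regime where the ICA consistency theory applies.
* **Causal attribution** (n = 5,000 records, 3 causal sources, 10 training
  seeds) also runs on inferred expressions from that regime: held-out AUC of
  the sources-input forest is ~0.90 against a Bayes bound of ~0.92, and all
  causal sources rank in the top 6 of their matching polarity in every seed
  (positively-weighted sources in the malignant-direction ranking,
  the protective source in the benign-direction ranking).
* **The event-level pipeline** (events → curves → sampling → discovery →
  attribution, exercised end-to-end by `runPipeline()`) is reported
  *unthresholded*: with the generator's observation noise the curve stage
  leaves per-variable SNR near 1 for billing codes, and the inferred
  expressions reach only $|r| \approx$ 0.7–0.9 per source even though a
  supervised ridge oracle recovers ~0.97 from the same curves. The loss is a
  property of the estimator, not of the data: fixed-point ICA assumes
  noiseless mixing and searches only orthonormal rotations of the whitened
  data, so heteroscedastic observation noise attenuates and rotates the
  inferred expressions. Raising the number of retained components m helps
  the worst sources but plateaus; this mirrors the known need to retain far
  more components than "true" sources and is listed below as a limitation.

## Numerical choices and degenerate inputs

Zero-variance variables standardize to 0 with scale 1 (never NaN) and are
flagged. PCA rank deficiency produces an error naming the achievable rank.
Non-converged ICA warns and returns the partial result with iteration
diagnostics. Duplicate same-day lab observations are averaged before
fitting. Constant expression rows are excluded from recovery matching with
a warning. `scaleExpressions()` is guarded against double application. The
label rule is a closed window, `[4, 1095]` days after the index event;
records with a malignancy code *before* the window opens are excluded
rather than labeled negative, the reading consistent with a no-prior-cancer
cohort (both boundary families are tested). The pipeline derives every
stage seed deterministically from one global seed, caches stages by
config-and-input hash, and refuses to resume over a mismatching manifest
unless forced.

## Problem sizes

Test-suite and acceptance runs use 30–60 variables, 6–8 sources, cohorts of
250–5,000 records and up to 20,000 cross-sections — the scale at which every
property above is sharp while a complete run stays in the minutes range on
one core. The same code paths take the dimensions as parameters; nothing in
the implementation is specific to these sizes.

## Known limitations

* Linear, noiseless-mixing ICA: observation noise biases inferred
  expressions (quantified above); noisy-ICA or GLS-style inference would be
  a natural extension.
* `m` must be chosen by the user; there is no automatic selection.
* The generator's constant-within-record expressions and root-only causal
  structure are simplifications; informative visit timing is absent.
* Signature naming/interpretation and literature evidence grading are
  human steps: the package scores against a *provided* reference list but
  does not match signatures to etiologies automatically.
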