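---
title: "Local connectome phenotype mapping: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local connectome phenotype mapping: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A local connectome fingerprint is a subject-level vector of fiber-wise
diffusion-density estimates: in every cerebral white-matter voxel of a common
atlas space, the spin-distribution-function magnitude is sampled along each
atlas-defined axonal direction, and the samples are concatenated (in
left-posterior-superior voxel order) into one long vector. With hundreds of
subjects and hundreds of thousands of fiber elements, the cohort matrix
\(X \in \mathbb{R}^{n\times p}\) has \(p \gg n\). Because the density units
are arbitrary, each subject's vector is rescaled to sample variance 1
(`scale_to_unit_variance()`); rescaling is a positive per-row multiplication,
so it preserves each fingerprint's direction and is idempotent.

`lcpr` asks whether such fingerprints carry shared, predictable structure:
can a subject attribute \(y\) (continuous or binary) be predicted from
\(X\), and which fiber elements carry the association? The answer is
computed by a four-step pipeline (LASSO-PCR) wrapped in five-fold
cross-validation, with permutation, bootstrap and FDR machinery around it.

## The pipeline

**Step 1 — economical SVD.** On each training split the raw (uncentered)
matrix is decomposed as \(X = USV^{\top}\), keeping the \(\min(n,p)\)
economical factors (`economical_svd()`). Component scores \(Z = US = XV\)
are the regression inputs. Two numerical choices matter:

* *No column centering.* The shared mean fingerprint then lies in the span
  of the leading principal axes, so the cohort mean is recoverable as a
  linear combination of components — a property we assert on synthetic
  cohorts (relative projection residual below 0.1 at the 90%-variance rank).
  A `center` flag exists for comparison with conventional PCA.
* *Deterministic signs.* Each axis is flipped so its largest-magnitude entry
  is positive; repeated runs are bit-identical. Singular values below
  \(10^{-10}\,S_{\max}\) are truncated.

**Step 2 — sparse fit with confound isolation.** The response is regressed
on \(Z\) *plus intracranial volume (ICV)* with an L1 penalty on all slopes
and an unpenalized intercept:
\(\hat\beta = \arg\min_\beta \{\lVert y - Z_{aug}\beta\rVert^2 +
\lambda\lVert\beta\rVert_1\}\). Fitting uses glmnet; predictors are
standardized internally (ICV is measured in mm³ and would otherwise carry a
vanishing effective penalty) and coefficients are reported back on the
original scale. All \(r\) economical components enter the fit — sparsity is
the penalty's job, not a variance cutoff's.

The penalty is chosen on the training split only, by inner cross-validation
over a log-spaced path (defaults: 10 inner folds, 100 path values spanning
4 decades). The default rule is the conservative one-SE rule; on weak
signals it frequently returns intercept-only models, which is informative
rather than pathological — an intercept-only model predicts a constant, its
prediction-observation correlation is undefined, and the evaluation layer
tracks that explicitly. The inner-CV computation reproduces `cv.glmnet`
exactly under a shared fold assignment (each fold fits its own path,
predictions interpolated onto the full-data grid, fold-size-weighted mean
deviance, probabilities clamped at \(10^{-5}\) for the binomial deviance);
the test suite pins this equivalence, and pins the orthogonal-design case to
closed-form soft-thresholding.

For continuous responses the fitted coefficient vector is truncated
(`truncate_confound()`): the ICV coefficient and the intercept are dropped
so predictions derive only from fingerprint components. Truncation is
refused for logistic models — removing a coefficient inside a nonlinear link
distorts the probabilities — so binary responses are instead evaluated by
comparing an ICV-only model against the full model (both penalized, same
machinery, the ICV-only variant simply excludes the component columns via
infinite penalty factors).

**Step 3 — phenotype map.** The truncated coefficients are back-projected
into fiber space, \(\hat w = V\hat\beta^{*}\) (`build_phenotype_map()`): one
weight per fiber element, the local connectome phenotype (LCP) for that
attribute. Maps can be rendered per voxel (mean weight of the fibers in the
voxel, `project_to_voxels()`) and exported as NIfTI-1.

**Step 4 — prediction.** Held-out subjects are predicted by
\(\hat y_i = x_i \cdot \hat w\) — no intercept, no ICV. Continuous
performance is the Pearson correlation between observations and held-out
predictions, which is location/scale-free, so the missing intercept is
irrelevant by construction. Binary predictions use the full logistic model,
with the probability-0.5 tie broken toward class 1 (a fixed convention so
runs are deterministic).

## Evaluation machinery

* **Folds.** Random k-fold partition with sizes differing by at most one.
  For binary runs the draw is repeated (up to 100 times) until every fold's
  minority fraction is within `max(0.25 * global, 1/fold_size)` of the
  global fraction; the absolute widening acknowledges that 25% relative
  slack can be narrower than one subject in a small fold.
* **Permutation test.** Each trial permutes \(y\) (fingerprint/ICV rows stay
  paired) and reruns the entire model-fitting procedure — penalty selection
  included — on every fold. Trials whose statistic is undefined
  (intercept-only everywhere) are excluded from the p-value denominator; a
  `conservative` flag counts them as non-exceeding instead. The outer fold
  assignment and per-fold training SVDs depend only on \(X\), so they are
  computed once and shared across trials; this is what makes thousands of
  refits tractable, and it changes nothing statistically because only
  \(y\) is permuted.
* **Bootstrap.** Percentile intervals over resampled prediction-observation
  pairs; undefined resamples (constant vectors under Pearson r) are redrawn
  and counted. An exhaustive mode enumerates all \(n^n\) resamples for tiny
  n, which the tests compare against independent enumeration.
* **FDR.** Benjamini-Hochberg step-up via `p.adjust`, verified against a
  brute-force implementation in the tests.
* **Seeds.** One top-level seed fans out through `derive_seed(seed, ...)`
  (a 31-bit hash of the parent seed and a purpose string) to fold
  assignment, inner folds, permutations and bootstrap, so a single integer
  reproduces an entire analysis.

## The synthetic cohort generator

Real fingerprint cohorts are access-restricted, so the package ships a
generator whose defaults emulate the statistical structure that matters to
the pipeline, with known ground truth. Subject \(i\)'s raw fingerprint is

\[x_i = a\,\mu + \sqrt{p}\sum_{k=1}^{K}\sigma_k s_{ik} v_k + \varepsilon_i,\]

with a shared profile \(\mu\) (iid standard normal entries), orthonormal
latent axes \(v_k\), standard-normal subject scores \(s_{ik}\), and iid
noise (SD \(\tau\), default 1). Rows are then unit-variance scaled. Under
this model the expected pairwise inter-subject correlation is
\(\rho \approx a^2/(a^2+\sum_k\sigma_k^2+\tau^2)\), so the profile strength
\(a\) is calibrated in closed form from the target \(\rho\) (default 0.42);
the *spread* of pairwise correlations grows with
\(\sqrt{\sum_k \sigma_k^4}\) relative to the total variance, and the default
decaying spectrum \(\sigma_k = 0.3\cdot 0.85^{k-1}\), \(K = 5\), keeps the
middle-95% interval near 0.32–0.50 while leaving each axis far above the
Marchenko-Pastur bulk (at \(n = 400\), \(p = 2000\):
\(\sigma_1\sqrt{np} \approx 268\) versus a noise edge near 65), so the axes
are recoverable. Monte-Carlo checks across seeds confirmed the calibration
(means 0.41–0.44 at the default settings) before the constants were frozen.

Attributes are linear functions of the latent scores plus noise, optionally
confounded with ICV (`icv_loading` adds standardized log-ICV *to the
attribute only*, never to the fingerprints, so confound-truncation tests
are clean). Binary attributes threshold the latent variable at the
empirical quantile implied by the class fractions, making realized class
counts exact — important for base-rate identities below. The planted
fiber-space direction for each attribute is recorded as unit-norm ground
truth. Repeat scans add fresh noise (default within-subject SD 0.2) and
rescale; rescan noise with SD \(w\) shrinks correlations by
\(1/\sqrt{1+w^2}\), so the default leaves intra-subject correlations near
0.98 and moves the inter-subject mean by under 0.02.

What the generator does *not* emulate: spatial autocorrelation along
fascicles, non-Gaussian density distributions, registration artifacts, and
site/protocol effects. Passing tests therefore demonstrate correctness of
the estimation machinery under a faithful covariance structure, not
robustness to every property of real diffusion data.

The ICV distribution is lognormal (median 1.5×10⁶ mm³, log-SD 0.05),
independent of the fingerprints by default.

## Problem sizes used by the checks

The automated checks run the pipeline at sizes chosen to exercise each
property meaningfully on a single CPU:

* *Base-rate identities:* two null-label cohorts at \(p = 5000\) with
  n = 833 (761/72 split) and n = 840 (468/372), five-fold CV, one-SE rule.
  Null logistic fits are intercept-only, always predict the training
  majority class, and the CV accuracy equals the majority fraction exactly.
* *Permutation calibration:* 50 replications × 100 trials at \(n = 60\),
  \(p = 400\), with the `min` rule and a shortened path (5 inner folds, 30
  path values over 2 decades). The `min` rule keeps the observed statistic
  defined under the null (a rep contributes only if its observed correlation
  exists); the calibration property — rejection rate ≈ 0.05 at
  \(p \le 0.05\) — is invariant to these pipeline settings.
* *Parameter recovery:* planted effect explaining 25% of response variance
  at \(n = 400\), \(p = 2000\), default pipeline, 10 seeds: median
  truth-map cosine ≥ 0.7 and held-out r near the \(\sqrt{0.25} = 0.5\)
  ceiling.
* *Specificity:* two attributes planted on disjoint axes (\(n = 300\),
  \(p = 1500\), 50% response variance each); full-sample maps should be
  near-orthogonal (|r| < 0.2).

## Open design points, resolved

* *Full-sample versus fold-wise maps for specificity:* phenotype maps are
  refit on the full sample by default (training metrics are also
  full-sample fits); per-fold maps remain available via the CV result.
* *Per-subject versus global variance scaling:* per-subject, because the
  fingerprint is defined per subject and scaling must not leak across
  subjects or folds.
* *Undefined statistics:* intercept-only models are first-class outcomes.
  Correlation metrics are flagged undefined, never coerced to zero, and
  permutation denominators exclude undefined trials by default.
* *Container format:* a plain-text directory container (`matrix.tsv` at
  `%.17g`, `subject_ids.txt`, `element_map.tsv`, `meta.json`) keeps
  round-trips bit-exact and the toolchain dependency-free; attributes
  travel as UTF-8 CSV keyed by `subject_id` with an `icv` column.

## Known limitations

Per-fold SVD at full-brain scale (hundreds of thousands of fiber
elements) is memory-heavy but
\(O(n^2p)\); the package targets desk-scale feature counts and does not
implement randomized or streaming decompositions. Logistic phenotype maps
are constructed but their predictive value is only assessed via the
ICV-only/full-model comparison, not via truncation. The permutation test
fixes the outer fold assignment across trials; redrawing folds per trial
would multiply cost with no change under the null hypothesis being tested.
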