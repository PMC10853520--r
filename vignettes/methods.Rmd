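---
title: "Methods: measuring drawing production and recognition development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring drawing production and recognition development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `sketchdev`, the choices that
were genuinely open when implementing them, and what the synthetic-data
generators do and do not emulate. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The measurement problem

Children's drawings are collected as ordered stroke data (touch-point
sequences with timestamps) under a category prompt, together with
shape-tracing trials, multi-rater part annotations for a subset of
drawings, and four-alternative forced-choice (4AFC) guessing-game logs in
which other children try to recognize the drawings. The analysis pipeline
turns these into: a per-drawing *recognizability* (binary classification
score) and graded *classifier evidence*; a per-child *tracing score*
capturing visuomotor control; per-drawing *part* statistics; and
trial-level *recognition* outcomes — and then models how production and
recognition covary with age.

## Rasterization and effort covariates

Strokes are rendered as connected polylines, black on white, with the
origin at the canvas top-left, x rightward, y downward, 0-based pixel
indices. Defaults: 224×224 raster, 3 px pen, no anti-aliasing. Binary
coverage makes the "ink" covariate (fraction of non-white pixels) exactly
reproducible, and overlapping strokes are idempotent. The source data do
not fix a render resolution or pen width; these are package defaults, with
224 chosen to match standard encoder input sizes. Drawings that exceed
the 30 s trial cap are clipped to the cap with a warning rather than
dropped, mirroring kiosk behavior.

## Tracing accuracy

A tracing `T` is aligned to its target shape `S` by the affine transform
maximizing the pixel-wise normalized cross-correlation; the loss is the
correlation distance `1 − NCC` (the printed form of the loss in the
source literature has an ambiguous normalization; Pearson correlation
over pixels is the reading consistent with its name, and is what we
implement). The transform family is translation + rotation + anisotropic
scale about the raster center, **without shear**, which makes the
decomposition into translation/rotation/scaling error magnitudes unique.
Two composition orders exist for rotation and anisotropic scale; the
registration family applies rotation first and scaling second, which is
exactly the family containing the inverses of generated tracing
transforms (scale first, rotate second), so ground-truth recovery is
well-posed (`alignment_inverse()` maps one to the other).

Numerical choices:

* optimization is Nelder–Mead over `(t_x, t_y, θ, log s_x, log s_y)` on
  Gaussian-smoothed rasters (σ = 3 px), on a three-level pyramid
  (quarter, half, full resolution), with five rotation starts
  (0°, ±15°, ±30°) at the coarse level;
* translation and per-axis ink-spread moments seed the coarse search;
* rotations are softly penalized beyond ±45°: a square maps onto itself
  at 90° with swapped axis scales, so the decomposition reports the
  smallest-magnitude equivalent branch;
* when stroke data are available, a final refinement stage optimizes the
  NCC of the *re-rasterized warped strokes* against the target. The pen
  does not scale with the tracing, so the image-based optimum is slightly
  biased under scaling; re-rendering at the standard pen width isolates
  shape mismatch, and the reported shape error is computed on this
  stroke-based route (lightly blurred, σ = 1 px, to forgive sub-pixel
  rounding). Raster-only input falls back to the smoothed-image NCC;
* a blank (constant) tracing is flagged and returns an identity transform
  with undefined NCC rather than an error; a constant target is an error.

Error magnitudes: `‖t‖` in pixels of the working resolution, `|θ|` in
radians, and `|log s_x| + |log s_y|` — symmetric in expansion and
shrinkage. Whether the original magnitudes were computed in normalized or
pixel units is unstated in the source; the choice rescales calibration
coefficients but not rank order.

### Ordinal calibration and tracing scores

Ratings (1–5) of tracing quality are modeled as proportional odds:
`logit P(rating ≤ k) = ζ_k − (x'β + u_rater)` with `x` the four error
components plus target-shape identity. No mixed-ordinal fitter is
assumed: rater intercepts are ridge-penalized maximum likelihood, with
the penalty set to the reciprocal of the fitted intercept variance in a
single PQL-style update. In the fixed-effects mode the fit matches
`MASS::polr` to numerical precision (a test asserts this), and
duplicating every observation leaves estimates exactly unchanged; with
penalized rater intercepts duplication changes shrinkage slightly, as in
any mixed model. The tracing score is the latent-scale predictor `x'β`
(rater effects excluded): monotone in predicted quality, unbounded, and
suitable as a model covariate. Session scores average the session's
tracings; sessions without tracings are missing, not zero.

## Recognizability and evidence

Embeddings are z-scored per column over the corpus (convolutional maps
are spatially averaged per channel first; zero-variance columns are
dropped with a warning). Classification is K-way logistic regression
with L2 penalty on a category-balanced subsample, in disjoint folds of
`holdout_per_category` items per category (default 2), each item
classified exactly once by a model never trained on it. The published
hyperparameters "regularization = 0.1, tolerance = 0.1" are read as
inverse regularization strength C = 0.1 (λ = 1/(nC)) and optimizer
convergence tolerance; both are exposed. Three implementation notes:
training sets are balanced, so class intercepts are redundant and are
omitted (unpenalized intercepts diverge under perfect separation); the
backend (glmnet) is warm-started down a short λ path because
single-λ multinomial fits can stall at the degenerate equal-coefficients
solution; and probabilities are computed by a stable softmax on the link
scale. Where a design has classes with a single training observation —
leave-one-out games — an internal penalized-likelihood optimizer with
the same objective is used instead.

Evidence is `ln(p/(1−p))` for the probability assigned to the target,
with p clipped at 10⁻¹². Zero-shot classification ranks cosine
similarities between image and label embeddings; its probabilities are a
softmax over cosines at temperature 100 (a documented constant — only the
argmax is substantive), and exact ties break toward the lowest label
index and are flagged.

## Semantic information in misclassifications

For each misclassified drawing, the top (non-target) predicted category
either shares the target's attribute — animacy, or big/small real-world
size for inanimate targets — or not. Match proportions per (age,
category) are corrected by the baseline prevalence of the target's
attribute class. The source wording leaves open whether that baseline is
over candidate *categories* or over *drawings*; both are implemented,
with the category-level baseline (prevalence among the other K − 1
categories) as default, since categories are the confusion candidates.
Size is metadata (defined only for inanimate categories), never
inferred. Confidence intervals are percentile bootstrap across
categories (B = 1000, seeded).

## Part annotations

Consensus requires the *same label set* from at least two raters (exact
set match); the parenthetical "label(s)" in the annotation instructions
is ambiguous, so a per-label majority mode is provided as a switch.
Unique parts exclude unintelligible and no-consensus strokes and (when a
vocabulary is supplied) custom free-text labels. Emphasis divides each
consensus stroke's Euclidean arc length (in canvas units — resolution
independent) equally among its labels and normalizes by the total length
of *all* strokes, so emphasis plus the unattributed fraction is exactly
1 — a conservation law the tests assert to 10⁻⁹. Zero-length drawings
have undefined (missing) emphasis.

## Recognition games

Exclusions are staged in the narrative order of the study's inclusion
rules: interference sessions; recognizers under 3 and adults;
participants with ≤ 1 post-practice trial; trials with RT < 100 ms or
> 10 s; participants under 75% accuracy on photograph trials (practice
and catch pooled) — exactly 75% is retained. Counts at every stage
reconcile exactly with the input totals. "Don't-know" responses are
retained as incorrect drawing responses (their treatment in accuracy is
not explicit in the source; this is the conservative reading and is
flagged here). Per-game evidence uses leave-one-out 4-way classifiers
with the same hyperparameters as the main classifier; categories with a
single drawing in a game are skipped with a warning. Evidence deciles for
summaries are computed over the distinct presented drawings, then mapped
onto trials.

## Mixed-effects models

The model specifications are the contract; fitting is delegated to lme4
(GLMMs, Wald z tests) and lmerTest (LMM, Satterthwaite degrees of
freedom), as is standard. Production: binary recognizability ~ age ×
drawing frequency + tracing score + time + ink + strokes, random
intercepts for child and category, predictors z-scored. Conditional
evidence: the same design on the evidence of correctly classified
drawings. Recognition: correct ~ evidence × recognizer age, random
intercepts for recognizer and category plus a random evidence slope by
category. One section of the source scales recognition predictors to
[0, 1] while the model tables standardize them; z-scoring is the default
and `scale = "unit"` is available. Singular random-effect fits warn but
are retained; no multiple-comparison correction is applied, matching the
source analyses. The production–recognition correlation restricts the
recognition side to the top 30% most recognizable drawings per category
(ranked by evidence, ties broken by drawing id) and reports Pearson r
across categories with a two-tailed test.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical structure* the analyses
assume, not visually realistic child art:

* **Drawings**: each category is a set of polyline part templates in a
  unit square; parts are included independently with a probability that
  rises linearly with age (default 0.35 at age 2, +0.07/year) and are
  jittered with Gaussian contour noise that falls with age (4 px at age
  2, −0.35 px/year, floor 0.5 px). These functional forms are package
  choices; the source gives no quantitative motor-noise model.
* **Class structure**: categories within an animacy class share parts
  from a class pool (and inanimate categories from size sub-pools), and
  the toy encoder maps shared parts to shared embedding directions, so
  classifier confusions concentrate within class — the structure the
  attribute-decoding analyses require. The encoder's `signal` parameter
  interpolates between pure noise (chance behavior) and noiseless
  prototypes (perfect classification).
* **Defaults mirror the study scale**: 48 categories with 22 animate and
  26 inanimate, 16-category subsets for part/recognition fixtures, ages
  2–10, a 30 s trial cap, 4AFC games over 4 categories with four practice
  photograph trials and periodic catch trials, three raters per stroke,
  rating scales 1–5.
* **Not emulated**: curvature/pressure/color of real strokes, visual
  realism, part co-occurrence grammar, category-specific drawing
  conventions, or any property of real pretrained-encoder embeddings.
  Passing tests therefore demonstrate that the *pipeline* measures what
  it claims under known ground truth — not that any particular empirical
  effect in real data is reproduced.

All generators are pure functions of their parameters and a single seed;
independent streams derive from it by a documented arithmetic hash
(`child_seed()`).

## Problem sizes and tolerances

The test suite and acceptance script run at desk scale: a 60-case
registration grid (translations to 20 px, rotations to 30°, per-axis
scales 0.7–1.4; tolerances 0.5 px, 1°, 2% scale, ≥95% of cases, shape
error < 0.01 throughout); ordinal calibration recovery at 1500 ratings
(within 2 SE); chance calibration with 576 drawings over 48 categories
and 80 drawings per 4AFC game (within 3 binomial SE); evidence
monotonicity at 200 drawings per category over 8 categories; attribute
decoding with 1152 drawings (the structured case needs enough
misclassified drawings per category for a stable category-level
bootstrap); and mixed-model recovery at 2800 drawings / 3000 trials with
200 reduced-n replicates for type-I calibration. The tracing targets
place contours at radius 0.16 × canvas so that every grid transform stays
fully on canvas; larger targets would clip under combined rotation,
scaling and translation and conflate truncation with shape error.

## Known limitations

* The registration family excludes shear; tracings with genuine shear
  load onto the shape error instead.
* The rater-intercept penalty is a one-step PQL approximation; the
  intercept variance is shrunk relative to a full integral likelihood,
  though coefficient recovery is unaffected at the tested sizes.
* The proportional-odds calibration assumes parallel thresholds;
  calibration against raters with strongly different scale use is
  absorbed only as intercept shifts.
* Real-encoder embeddings (deep network features) are supported through
  the same interfaces but are not required anywhere; conclusions about
  real drawings require real embeddings and the deposited behavioral
  data.
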