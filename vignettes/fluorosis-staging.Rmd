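---
title: "Color-based tooth segmentation and fluorosis staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-based tooth segmentation and fluorosis staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoroseg)
```

# Overview

`fluoroseg` grades dental fluorosis from mouth photographs in four
steps: six-dimensional color features, possibilistic fuzzy clustering
into labeled multi-prototypes, fuzzy k-NN pixel classification with
morphological post-processing, and a threshold rule on the opaque and
brown pixel fractions. This vignette explains each model, its
assumptions and tunable parameters, the numerical choices made where
the design was genuinely open, and what the synthetic data used in the
tests does and does not demonstrate.

# Feature space

Every pixel is represented as $(R, G, B, H, S, I)$, the 8-bit RGB
channels rescaled to $[0,1]$ together with the HSI transform. Hue is
computed as $\mathrm{atan2}(\sqrt3 (G-B),\,(R-G)+(R-B))$ wrapped to
$[0, 2\pi)$ — equivalent to the classical $\cos^{-1}$ form, which the
tests verify to $10^{-9}$ radians on random pixels — so the full hue
circle is reachable. Achromatic pixels ($R=G=B$, including black) take
$H = 0$, $S = 0$ by convention: the hue formula is $0/0$ there, and
zero saturation makes any fixed hue equivalent.

Two numerical choices matter downstream:

* **Hue scaling.** Euclidean distances mix hue with the five other
  unit-interval features, so by default hue is divided by $2\pi$
  (`scale_hue = TRUE`); unscaled radians would dominate every distance.
  The flag is recorded in trained prototype sets so training and
  inference always agree.
* **Hue wrap-around and near-achromatic noise.** Hue is an angle:
  values near 0 and near 1 (scaled) are close on the color circle but
  far in Euclidean distance, and for near-achromatic pixels (white,
  opaque-white enamel) hue is dominated by sensor noise. Both effects
  are genuine properties of this feature design; multi-prototype
  classifiers absorb them by placing several prototypes along the hue
  axis, single-prototype ones do not.

# Unsupervised possibilistic fuzzy clustering

UPFC minimizes, over centroids $c_j$, row-stochastic fuzzy memberships
$\mu_{ij}$ and unconstrained typicalities $t_{ij} \in (0,1]$,

$$J = \sum_{ij}\left(a\,\mu_{ij}^m + b\,t_{ij}^n\right)\lVert x_i - c_j\rVert^2
    + \frac{\beta}{n^2\sqrt{N_C}}\sum_{ij}\left(t_{ij}^n\log t_{ij}^n - t_{ij}^n\right),$$

where $\beta = N_S^{-1}\sum_i \lVert x_i - \bar x\rVert^2$ measures the
spread of the data. The alternating updates are the stationary points:
the familiar fuzzy-c-means membership update, the possibilistic
exponential $t_{ij} = \exp(-(b\,n\sqrt{N_C}/\beta)\lVert x_i - c_j\rVert^2)$,
and a weighted-mean centroid update with weights $a\mu^m + b t^n$.
The exponential form is the derivative-consistent pairing with the
entropy coefficient above; with $b = 0$ the method reduces to a purely
possibilistic scheme, and at $a = 1, b \to 0, m = 2$ the membership
update is textbook FCM (both limits are tested).

Defaults are $m = n = 1.5$, $a = b = 0.5$, at most 300 sweeps, and a
convergence tolerance of $10^{-5}$ on the largest centroid
displacement.

**Monotonicity.** The full objective $J$ is non-increasing across
sweeps — each half-step minimizes it exactly — and `run_upfc` records
it per sweep (`objective_trace`); the tests assert this at $10^{-8}$
slack. The distance term *alone* (`data_term_trace`) is **not**
monotone: the typicality update deliberately trades a larger data term
for a smaller entropy term, and rises of order 1 are observed on pixel
data. Both traces are kept so the trade-off is visible.

**Initialization.** Centroids start from distinct data rows sampled
with squared-distance weighting (k-means++ style) under the caller's
seed. This choice matters more here than in ordinary c-means: the
possibilistic weights keep centroids near their starting basin, so a
uniform draw that misses a minority class (brown pixels are under a
tenth of a typical training set) tends to stay missing. Distance
weighting makes every dense region, including small classes, likely to
receive a starting prototype.

**Coincident centroids.** With many clusters the typicality weights
$\sum_i t_{ij}^n$ dwarf the membership weights $\sum_i \mu_{ij}^m$
(memberships scale like $1/N_C$), so groups of centroids share nearly
identical update targets and collapse onto common positions. This is
the well-known hazard of possibilistic clustering; the package allows
it (a message is emitted when centroids coincide) because the
downstream majority-vote labeling and k-NN classification remain well
defined. Its practical effect is a ceiling of roughly 92% pixel
accuracy on the default synthetic data — consistent with the accuracy
plateau and the high opaque false-negative rate this class of methods
reports on clinical pixels, where opaque and white enamel are the
closest pair.

# Model selection by cuckoo search

The number of clusters $\eta$ is an integer in `bounds` (defaults
$[1000, 2500]$ at full scale). Each nest's fitness is
$(y - \hat y)^2$, where $y$ is the pixel accuracy of the labeled
prototypes on the validation pixels (fuzzy k-NN, $K = 1$) and
$\hat y = 0.99$ the expected accuracy. Per generation every nest
proposes a cuckoo by a Mantegna Lévy-flight step
$s = \alpha(\eta_i - \eta_{best}) \cdot u/|v|^{1/\beta}$ (the incumbent
best takes a pure $\alpha$-scaled step so it can still move), accepted
greedily; then each non-best nest is abandoned with probability
$p_a = 0.25$ and rebuilt uniformly at random. The elite nest is never
abandoned, so the best fitness is non-increasing; the search stops when
it falls below $\varepsilon = 0.001$ or after $T_{max}$ generations.
Steps are real-valued while nests are integers; proposals are rounded
then clamped to the bounds — the minimal reconciliation.

Cross-validation follows the study protocol of training on **one** fold
and validating on the remaining folds (prototype training cost scales
with the training set, evaluation is cheap). UPFC seeds inside the
search derive deterministically from (seed, nest, generation), so whole
searches are reproducible bit for bit.

Validation accuracy saturates near 92% on the default synthetic pixels
(the coincidence ceiling above), which keeps the fitness above
$\varepsilon$; searches therefore run their full generation budget.
The tests and the acceptance experiment use desk-scale settings —
bounds $[20, 120]$, 10 nests, 5 generations, one training fold of a
12,800-pixel budget (4000/4000/2000/1000/1800 per class) — about two
minutes of CPU; the full-scale defaults are retained as the documented
configuration.

# Segmentation pipeline

Per image: (1) every pixel is classified against the prototypes
($K = 1$); (2) non-background pixels form the tooth mask, cleaned by
binary opening and dilation with disc elements; (3) background pixels
*enclosed* by the tooth region — the difference between the hole-filled
and the raw mask — are reclassified with $K = 5$ restricted to the four
tooth classes; (4) white and yellow collapse to a white–yellow class;
(5) 8-connected opaque components smaller than 0.55% of the tooth area
and brown components smaller than 0.05% are turned into white–yellow —
specks that small are segmentation noise, and removal must not create
new disease evidence; (6) $r_{opaque}$ and $r_{brown}$ are computed
over the tooth area (white–yellow + opaque + brown pixels).

Open design points and the choices made:

* **Structuring-element sizes** are not fixed by the clinical
  protocol; the opening disc radius defaults to 0.2% of the image diagonal (at
  least 1 px) so behavior is resolution-invariant, and the dilation
  radius to 1 px. Both are configurable.
* **"Misclassified as background in the tooth area"** is read as
  enclosed background after hole filling, and the reclassification is
  restricted to tooth classes — otherwise $K = 5$ could return
  background again and the step would be a no-op.
* **Connectivity** for component analysis is 8-connectivity (standard
  for blob cleanup); since the available 4-connected labeler would
  split diagonal chains, components are taken over the king-move pixel
  graph.
* Ratio denominators count tooth-class pixels, not mask pixels, so the
  1-px dilation fringe (background-colored pixels inside the mask)
  cannot dilute the ratios.

# Staging rule

With thresholds $0 \le \theta_1 < \theta_2 < \theta_3 \le 1$ and brown
tolerance $\delta$ (defaults 0.05, 0.1, 0.3, 0.007), evaluated strictly
in order:

1. $r_{opaque} \le \theta_1$ → Normal — *unconditionally*, whatever
   $r_{brown}$ says;
2. $r_{opaque} \le \theta_2$ and $r_{brown} \le \delta$ → Normal;
3. $r_{opaque} \le \theta_3$ and $r_{brown} \le \delta$ → Stage 1;
4. $r_{brown} \le \delta$ → Stage 2;
5. otherwise → Stage 3.

All comparisons are inclusive ($\le$), and boundary behavior is pinned
by unit tests. The first branch is the
clinically motivated shortcut: small brown readings at low opacity are
almost always shadow artifacts, and without it a healthy tooth with
1.63% opaque / 1.35% brown pixels would escalate straight to Stage 3.
`classify_fluorosis_ablated()` implements the rule without that branch
for ablation comparisons. Under low brown the stage is monotone in
$r_{opaque}$, and exactly one branch fires for any input (both tested).
Reported percentages round half-up to two decimals
(`round_half_up()`); raw values are kept internally.

# Evaluation metrics

Confusion matrices are oriented rows = actual. One-vs-rest counts
derive from a matrix as TP (diagonal), FN (row remainder), FP (column
remainder), TN (rest); rates are percentages satisfying
TPR + FNR = 100 and TNR + FPR = 100 exactly before rounding. Mask
accuracy is pixel agreement of the binary tooth mask; three-class
accuracy is computed over ground-truth tooth pixels only (the stricter,
label-complete choice — whether the original protocol restricted to
ground-truth or predicted tooth pixels is unstated, so the restriction
is configurable via the mask argument). Per-class summaries aggregate
by image-count-weighted means.

# Synthetic data: what it shows and what it does not

The generator emulates the study conditions: per-class truncated
Gaussian RGB colors (creamy white, light yellow, paper-white opaque,
brown, pink gum background; $\sigma \approx 0.03$ per channel — class
means separated by well over three pooled standard deviations), a
12,800-pixel training budget split 4000/4000/2000/1000/1800, and mouth
scenes of elliptical teeth whose opaque patches and brown spots are
placed until the target area fractions are met exactly. The standard
fixture suite is twelve noise-free scenes, three per stage, with brown
fractions kept clear of the $\delta$ boundary so that sub-half-point
segmentation drift cannot flip a stage. An optional vertical shadow
gradient reproduces the known failure mode of shaded enamel drifting
toward background/brown.

Passing tests on these fixtures demonstrate the *mechanics* — exact
ratio bookkeeping, threshold logic, morphology, end-to-end stage
recovery — not clinical performance: real photographs add illumination
gradients, specular reflections, saliva and plaque artifacts,
inter-camera color shifts and fuzzy class boundaries that flat-colored
ellipses do not model. The recovery tests that demand ≥95% pixel
accuracy use a tighter-noise preset ($\sigma = 0.01$, "well-separated")
so that they measure the pipeline rather than the irreducible
white/opaque overlap of the realistic preset.

# Known limitations

* Possibilistic centroid collapse caps pixel accuracy well below what
  plain nearest-neighbor on the raw training pixels achieves; the
  cluster-count search cannot buy it back. This mirrors the reported
  behavior of the method on clinical data and is kept faithful.
* Hue is linearized, not treated as circular, in all distances (see
  above); the multi-prototype design compensates only partially.
* Image input is PNG (or any in-memory RGB array); no JPEG decoder is
  bundled.
* Per-tooth analysis, illumination correction and instance separation
  are out of scope; the unit of grading is the whole mouth image.
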