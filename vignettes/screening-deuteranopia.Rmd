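---
title: "Screening figures for deuteranopia accessibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening figures for deuteranopia accessibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdscreen)
```

## The problem and the model

Deuteranopia — loss or anomaly of the medium-wavelength (green) cone — is
the most common dichromatic color-vision deficiency. A figure is
*problematic* for a deuteranope when information is carried by a color
contrast that is large for a normal trichromat but small after the deutan
transformation of color space. `cvdscreen` operationalizes that idea as a
pipeline of three components: a colorimetric simulation, a set of five
per-image summary metrics, and classifier layers trained on those metrics
(or on the raw pixels).

### Simulation

Deuteranomalous appearance is modeled by the published 3×3 matrix family
derived from the cone-sensitivity shift theory, tabulated at severities 0,
0.1, …, 1. `deutan_matrix(s)` interpolates linearly between the two
adjacent tabulated matrices, so severity is a continuous dial: 0 is the
identity (normal vision), 1 full dichromacy. Each row of every matrix sums
to 1 (to the 6-decimal rounding of the published table), which guarantees
achromatic colors are fixed points — grays stay gray at any severity.

The default severity is **0.8**. A mild setting would under-detect missing
contrast, while 1.0 models only complete deuteranopia; 0.8 represents the
moderate-to-severe range that a screening tool should protect.

By default the matrix is applied to **gamma-encoded** sRGB values. The
theory prefers linear RGB, but the simulation tooling this pipeline is
calibrated against historically applied the matrix to gamma-encoded values,
and reproducing that operational behavior was prioritized;
`simulate_deutan(..., linear_rgb = TRUE)` provides the linear-space
alternative. Out-of-gamut results are clipped to [0, 1] rather than
rescaled, matching the convention of the simulation tools in this area.

### Color difference

Contrast is measured with CIEDE2000 (ΔE₀₀) on CIE L\*a\*b\* under the D65
white point and 2° observer (the sRGB standard), with parametric weights
kL = kC = kH = 1. ΔE₀₀ is symmetric and zero only for identical colors, but
it is not a metric (no triangle inequality), and the implementation is
validated against the full published 34-pair verification set to ±1e-4
rather than against axioms it does not satisfy. Although ΔE₀₀ is sometimes
described loosely as an RGB difference, its defined domain is Lab; this
package always converts sRGB → linear RGB → XYZ → Lab before evaluating it.

## The five metrics

Images are first standardized: decoded to sRGB (alpha composited over
white, since journal figures render on white), resized to **height 300 px**
(bilinear, aspect preserved, upscaling allowed), then quantized to at most
**256 colors**. Resizing happens *before* quantization so the palette
describes the image at the scale the spatial metric uses; the order is a
design choice of this package. Quantization is deterministic median cut: the
box with the largest single-channel range splits at its weighted median
(channel ties broken R > G > B, box ties by creation order), each box
represented by its pixel-weighted mean color. Determinism was prioritized
over perceptual optimality so results and tests are exactly reproducible;
when an image already has ≤256 distinct 8-bit colors the palette is exactly
those colors. The simulated counterpart is produced palette-wise, so
palettes correspond positionally.

With "original" = resized+quantized and "simulated" = its severity-0.8
counterpart:

1. **Mean pixel-wise distance**: mean ΔE₀₀ between each pixel and its
   simulated self, divided by 100 so typical values live on a 0–1 scale.
2. **Max-distance pair ratio**: among unordered pairs of *chromatic*
   palette colors — achromatic entries (8-bit channel spread ≤ 10) are
   excluded because they cannot lose contrast — the pair with the largest
   original ΔE₀₀ is selected and its original/simulated ratio reported.
   Selecting by largest original distance (the metric's defining title)
   rather than by largest ratio is an ambiguity in this family of metrics;
   the former is the exported metric, and the alternative reading is one
   line away from the pair table `enumerate_pairs()` returns
   (`max(pairs$ratio)`).
3. **High-ratio pair count**: pairs with ratio strictly greater than 5.
4. **High-ratio pixel proportion**: fraction of pixels whose palette color
   appears in any high-ratio pair.
5. **Mean spatial distance**: per high-ratio pair, the mean Euclidean
   distance in resized-image pixels between all pixels of one color and all
   of the other; the metric is the unweighted mean of the per-pair means.
   Pooling all cross pairs instead (weighting pairs by pixel mass) is
   available via `pool = TRUE`; averaging per-pair means was chosen as the
   default because it treats each confusable pair as one piece of evidence
   regardless of its area. Distances stay in pixel units — heights are
   standardized to 300, so units are comparable across a corpus.

Numerical guards: the simulated distance is floored at ε = 1e-6 before
division and ratios are capped at 1e6, so a pair that simulation maps to
identical colors yields a large finite ratio rather than infinity. When the
exact spatial computation would enumerate more than `cap` = 1e5 cross pairs
for a color pair (exact cost can reach 10⁸ pairs), a seeded uniform
subsample of `cap` pairs is used; with the default cap the subsampled mean
tracks the exact mean within ~1% on block fixtures. When an image has *no*
high-ratio pair the spatial metric is `NA` — an explicit undefined marker —
because 0 would falsely assert maximal proximity.

### Rank-based combined score

Within a corpus each image is ranked per metric, rank 1 = most problematic:
largest-first for the four "more is worse" metrics, smallest-first for
spatial distance (confusable colors close together are worse), ties
averaged, `NA` spatial distances ranked least problematic. The combined
score is the mean of the five ranks. Ranks are corpus-relative by
definition, so single-image runs omit the score.

## Classifier layers

Feature-based models consume the five metrics for images labeled
*definitely problematic* or *definitely okay* (the "probably" labels add
noise and are excluded from training). Undefined spatial distances are
imputed as the training-set maximum + 1 — beyond any observed separation,
i.e. "least problematic" — and features are standardized with training-set
statistics only; both statistics are estimated inside each training split,
never from test data. Logistic regression and random forest weight classes
inversely to frequency ("balanced"); k-NN uses k = 5 with no weighting,
its vote fraction converted to a probability of the problematic class.
Feature standardization itself is a choice of this package (it costs
nothing for trees and helps the linear model).

Evaluation follows a repeated-CV protocol: three iterations of stratified
five-fold cross-validation; per fold an AUROC (trapezoidal rule over the
ROC) and AUPRC (precision–recall step integral, whose random-score baseline
is the minority-class frequency); summaries take the **median across each
iteration's folds, then the mean across iterations**. Fold assignment is
seeded and stratified, so reproduction of any external protocol is
statistical rather than bit-exact. Folds whose test half is single-class
(possible at extreme imbalance) are skipped with a warning and the summary
uses the remaining folds.

## CNN harness

The baseline network has eight 3×3 convolutional layers, each with batch
normalization and ReLU. The published width progression lists six values
(32, 64, 128, 256, 512, 728) for eight layers; this package duplicates the
first and last, giving 32, 32, 64, 128, 256, 512, 728, 728, and keeps the
literal 728. Downsampling is stride-2 at every width increase (any schedule
consistent with the width progression is defensible; this one is simple and
halves cost early). Global average pooling feeds a sigmoid unit; dropout,
when enabled, acts on the pooled features. Training is Adam at 1e-3 on
weighted binary cross-entropy for 30 epochs (paper profile), with a 20%
stratified internal validation split; early stopping monitors validation
AUROC with patience 5 and restores the best weights. Augmentation — random
horizontal flips and rotations by a uniform fraction (0.2 or 0.3) of a full
turn, nearest-neighbor with white fill — applies to training batches only.
Transfer learning loads a pre-trained convolutional base from a local
weights file, freezes it, trains the new head, and (with fine-tuning)
unfreezes the base for 15 further epochs at 1e-5 before refreezing.

Two profiles are first-class: the **paper profile** (input 224, full
widths) and the **desk profile** (input 64, widths halved, ≤10 epochs),
which trains in about a minute on one CPU. Tests and the acceptance script
use the desk profile; the paper profile is the same code at larger
constants.

## The fixture generator

Real figure corpora cannot ship with a package, so the generator builds
images with *known* chromatic structure: two-block layouts with a
confusable pair (red/green/orange family along the deutan confusion axis),
a friendly pair (blue/orange, blue/yellow, purple/yellow), grayscale
stripes, labeled variants, and smooth gradients. The crucial design rule is
**certification**: every fixture is re-measured by the metrics module
before it is returned, and generation fails loudly if the promised fact
(e.g. "all pairwise ratios < 5") does not hold — the presence of particular
color names never substitutes for the measurement. Labeled corpora have
exact class counts, deterministic content given a seed, and survive PNG
round trips losslessly (flat palettes).

What the fixtures do **not** emulate: text, axes, anti-aliased curves,
microscopy texture, JPEG noise, multi-panel layout. A classifier that
separates this corpus perfectly has learned the chromatic signal the
generator planted — the protocol and the plumbing are validated, not
real-world predictive performance. Corpus-dependent numbers (e.g. published
AUROC/AUPRC values on reviewed journal images) are therefore out of scope
here; they require the original images and human labels.

One visible consequence of the pipeline defaults: upscaling a small flat
fixture to the standard 300-px height interpolates intermediate shades at
block borders, so a fixture certified at native size with one high-ratio
pair can show a dozen high-ratio pairs of interpolated shades when screened
at corpus defaults. This is faithful behavior of the standardization step,
not an artifact to suppress; certificates are computed at the fixture's
native height.

## Problem sizes used by tests and the acceptance script

Chosen as the package's own desk-scale study conditions: metric-oracle
equivalence on images ≤8×8 with ≤6 colors (exact, uncapped); classifier
protocol on a certified 500-image corpus at 10% problematic (plus a
label-permutation null expected to land near AUROC 0.5); CNN on a 200-image
corpus at 25% problematic, desk profile, ≤10 epochs; CLI chain on 40
fixtures. All randomness flows from a single seed argument.

## Known limitations

* Deutan axis only; protan/tritan simulation is structurally analogous but
  not implemented.
* Simulation fidelity is bounded by the matrix model itself; perceptual
  color-difference formulas are imperfect proxies for lived experience.
* The severity default (0.8) represents moderate-to-severe deficits; milder
  deficits are under-modeled by construction.
* Median-cut quantization is deterministic but not perceptually optimal; an
  image whose problematic contrast survives only in fine detail below the
  palette resolution can evade the metrics.
* The k-NN score is a 5-vote fraction and hence coarsely quantized;
  logistic regression or the random forest give smoother probabilities.
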