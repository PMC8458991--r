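---
title: "Methods: spatial-frequency curriculum training at desk scale"
author: "coarse2fine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-frequency curriculum training at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package operationalizes

Biological vision develops coarse-to-fine: infants first resolve only low
spatial frequencies and acquire sensitivity to finer detail over months.
Standard image classifiers are trained the opposite way — on full-resolution
images from step one — and notoriously lean on fine, high-frequency texture.
`coarse2fine` packages the computational side of this question: what happens
when a convolutional classifier is trained under a curriculum that controls
which spatial-frequency bands it sees at each stage?

The package provides five connected pieces: calibrated Butterworth filtering
of images specified in cycles per degree (c/deg) of visual angle; the three
curriculum regimes (full, gradual, mixed); hybrid low/high-band composite
stimuli with conceptual model RDMs; per-frequency-level accuracy evaluation
with binomial confidence intervals; and representational similarity analysis
(RSA) with permutation and bootstrap inference. A seeded synthetic
shape+texture generator and a small pure-R CNN make the entire pipeline
runnable in minutes on one CPU with no external data.

## Filter model and calibration

Filtering happens in the 2-D discrete Fourier domain with a radial
Butterworth low-pass gain

$$g(D) = \frac{1}{1 + (\sqrt{2}-1)\,(D/r)^{2n}},$$

where $D$ is the Euclidean distance from the DC bin in centered coordinates,
$n$ the order (4 throughout), and $r$ the cutoff radius in cycles per image.
The constant $\sqrt{2}-1$ makes $g(r) = 2^{-1/2}$ exactly — the half-power
point sits at the cutoff for every order.

Cutoffs are stated in cycles per degree and converted by assuming the image
subtends a fixed visual angle $\theta$ (default 60 degrees, a phone-like
viewing geometry): with pixels/degree $N/\theta$ and pixels/cycle $N/r$, the
spatial frequency in c/deg is $r/\theta$, so $r = \mathrm{cutoff} \times
\theta$ — notably independent of the pixel size $N$. The four canonical
levels, chosen to mimic the developing infant contrast-sensitivity peak, are
0.1, 0.3, 0.5 and 0.8 c/deg (`SFL1`–`SFL4`, radii 6/18/30/48 cycles per
image), plus the unfiltered level `UF`. Radii above the Nyquist radius $N/2$
are allowed and act as near-identity filters; at 64 px, `SFL4` ($r = 48$) is
effectively unfiltered.

Numerical conventions, chosen once and tested: the DC bin sits at 0-based
index $\lfloor N/2 \rfloor$ on each axis; the high-pass mask is the exact
complement $1 - g$, so the low- and high-pass bands of an image sum back to
it to machine precision before clipping; channels are filtered
independently; the imaginary residue of the inverse transform is discarded
(inputs are real, the residue is roundoff); outputs are clipped to $[0,1]$
*after* any hybrid summation, never before. Whether to clip or renormalize
filtered images is not dictated by the physics; we clip, and tests rely on
pre-clip values where exactness matters.

## Curriculum regimes

Training runs in five stages over the level bank:

* **full** — unfiltered images in every stage (the standard baseline);
* **gradual** — one level per stage, `SFL1` through `SFL4` then `UF`; each
  switch discards the previous set entirely;
* **mixed** — each switch halves the running mixture and gives the new level
  the other half, so lower-frequency sets are retained throughout. Stage 4
  is read as exact sixths ($1/6, 1/6, 1/6, 1/2$): printed percentage tables
  of this schedule round 16.67 down to 16, but the proportions must sum to
  one and stage 5 shows the same halving pattern at eighths.

The reference stage length is 100 epochs (500 total) with SGD, Nesterov
momentum 0.9, categorical cross-entropy, and a piecewise learning rate of
0.5 / 0.1 / 0.01 switching after 400 and 450 epochs. At other scales the
breakpoints keep their fractional positions (0.8 and 0.9 of the total), so
the schedule shape survives scaling. Mini-batches are composed by
largest-remainder apportionment of the batch over the stage proportions
(deterministic counts) with uniform without-replacement draws inside an
epoch-level pass; whether the retained lower-level images are a fixed subset
or resampled each epoch is an open choice — we resample.

## Synthetic data: what it emulates and what it does not

The generator (`synthSpec()`, `generateDataset()`) produces 64x64 grayscale
images in which the category signal is carried redundantly by two cues in
disjoint frequency bands:

* a **coarse shape cue**: a soft-edged elliptical silhouette whose center
  (on a tight ring, radius 0.04 of the image side), radii (per-class steps
  of 0.008 of the side) and edge are class-specific, plus a small
  class-specific *contour ripple* (a Gaussian-windowed oriented sinusoid at
  11 cycles/image riding on the silhouette boundary);
* a **fine texture cue**: a fixed-phase oriented sinusoid windowed by the
  silhouette, with class-specific carrier (0.50 or 0.53 of the Nyquist
  radius) and orientation (36-degree steps).

Per-image jitter (center, scale) and Gaussian pixel noise (sd 0.08) prevent
pixel-level memorization. Informativeness parameters give the probability
that each cue's family matches the label; lowering one to 0 makes that band
carry no label information, which the tests exploit with a nearest-centroid
oracle.

Because the nominal SFL radii (up to 48 cycles/image) exceed the Nyquist
radius at 64 px, the generator compresses its *cue placement* by a
proportional factor (0.45 Nyquist / 48 at 64 px); the filters themselves
always use the size-independent calibration. Placement is audited spectrally
at generation time: every shape prototype must hold at least 90% of its
non-DC energy below the scaled SFL1 radius and every texture prototype at
least 90% above the scaled SFL4 radius.

The cue geometry was calibrated once, at design time, to produce the
*texture-shortcut* regime the experiment needs, and then frozen:

* the texture is high-amplitude (0.40 against a blob contrast of 0.30) and
  linearly separable — a classifier that sees it learns it almost
  immediately;
* the coarse shape discrimination is deliberately hard (blob centers 2–3 px
  apart under ±3 px jitter, radii steps under scale jitter), so it is
  acquired slowly and only under sustained pressure;
* the contour ripple and the texture carriers sit *between* the SFL1 and
  SFL2 filter radii in visibility: both are erased by the SFL1 filter, while
  the SFL2 view passes the ripple fully and the texture at ~0.8 gain. The
  SFL1 view therefore contains only the hard coarse cue, and every richer
  view contains easy cues — mirroring natural images, where fine detail is
  more discriminative than coarse layout.

What the generator does **not** emulate: natural image statistics (1/f
spectra, clutter, occlusion), intra-class appearance variation beyond
jitter, color, and any semantic structure. Passing the curriculum
experiment here demonstrates the *mechanism* — cue competition across
frequency bands under different schedules — not performance on natural
images.

## The reference classifier

No deep-learning backend is assumed: the package implements a compact
convolutional network in pure R (BLAS-backed im2col matrix products) — three
3x3 convolution + ReLU + 2x2 average-pooling blocks (8/16/16 channels), a
64-unit hidden dense layer, softmax output; He-normal initialization; SGD
with Nesterov momentum; global gradient-norm clipping at 5 as a stability
guard. Gradient correctness is pinned by a central finite-difference test.
Any other classifier can be plugged into the same generics
(`modelUpdate`, `modelPredict`, `modelActivations`).

## The desk-scale experiment and its expected pattern

`runExperiment()` runs all three regimes on one dataset (10 classes, 60
train / 12 validation / 20 test images per class) with identical
initialization: 5 stages x 4 epochs, 120 steps of batch 16 per epoch,
initial learning rate 0.03. On one CPU this takes roughly 4–5 minutes per
regime. The qualitative pattern it reproduces:

* **full** training saturates on unfiltered images via the texture shortcut
  and performs near chance on `SFL1`, where only the coarse cue survives;
* **mixed** training is forced to master the coarse cue in stage 1 and
  retains it (`SFL1` is 12.5–100% of every batch), ending far above full
  training on `SFL1` while staying close to it on unfiltered images;
* **gradual** training learns the coarse cue in stage 1, then loses `SFL1`
  accuracy after the switch to `SFL2`-only data as the easy mid-band cues
  hijack the optimization, and never recovers.

The stage-switch drop is the most delicate of the three effects at this
scale: it requires stage 1 to have converged (hence the many small-batch
steps per epoch) and is measured at epoch granularity on a 120-image
validation pool, so its size varies across seeds even though the
post-switch *decay* of `SFL1` accuracy is consistent.

## Hybrid stimuli and RSA

Hybrid images superimpose the low-pass band (below 0.17 c/deg, radius 10.2
cycles/image) of one source with the high-pass band of another. The 18-image
set holds the high band fixed across the 9 LSF-delta positions and the low
band fixed across the 9 HSF-delta positions. The two binary conceptual RDMs
assign dissimilarity 0 to pairs sharing the relevant band source and 1
otherwise; cross-subset pairs share neither source under this layout and
score 1 in both models (the rule is applied uniformly; users can mask those
entries out).

RDMs are $1 - \rho_s$ (Spearman, average-rank ties) between activation
patterns; constant patterns are an error, not a silent NA. RDM comparison
uses the strictly-upper triangle. The permutation test relabels stimuli
simultaneously in rows and columns of the model RDM and reports the
strict-inequality count $p = \#\{\rho_{perm} > \rho_{obs}\}/n_{perm}$ — this
estimator can return exactly 0, so the conventional add-one estimate is
reported alongside. The bootstrap resamples stimuli (not RDM cells) with
replacement, excludes self-pair duplicates from the compared triangle, and
redraws degenerate replicates (fewer than 3 distinct stimuli, or no rank
variance left), counting them.

As a training-free sanity check, a *pixel observer* that sees only the
low-pass (or high-pass) band of the 18 hybrids produces an RDM that
correlates strongly with the LSF (respectively HSF) conceptual model and
weakly with the other — this is deterministic and requires no classifier.

## Numerical and design choices, in brief

* Argmax ties in accuracy break deterministically to the lowest class index.
* Binomial confidence intervals use the Wilson score interval (equal to the
  inversion of the score test, `prop.test` without continuity correction).
* The "within 15% of average performance" category-selection rule is read
  as an absolute band of ±0.15 around the mean accuracy, supported by the
  phrasing "15% above or below"; with more than `k` qualifiers the `k`
  closest to the mean are kept, ties by class index.
* The RSA layer tags `final_fc` and `mid_conv` map to the reference model's
  hidden dense layer and middle convolution block.
* All randomness flows from explicit integer seeds through a private RNG
  stream that restores the caller's RNG state.

## Known limitations

The reference network is small and CPU-bound; it is a vehicle for the
curriculum mechanism, not a substitute for a production-scale network. The synthetic cue
geometry makes band membership unusually clean — real images leak category
information across bands, so effect sizes here should not be read as
predictions for natural data. At 64 px the `SFL4` filter is a near-identity,
so the top two curriculum levels are nearly equivalent; the mechanism lives
in `SFL1`–`SFL3`. Finally, the stage-switch drop (gradual regime) is
epoch-granular and seed-sensitive in magnitude, as discussed above.
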