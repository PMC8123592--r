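---
title: "Identifying bloodstains in VNIR hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying bloodstains in VNIR hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemospec)
```

## The problem

Dried bloodstains must often be distinguished from visually similar red
substances (ketchup, red and rust paints, nail polish, fake blood, red
ink) without destroying DNA evidence. A visible/near-infrared (VNIR)
hyperspectral camera records a full reflectance spectrum per pixel, and
dried blood carries a distinctive hemoglobin signature: the intense Soret
absorption near 415 nm, the oxyhemoglobin β and α bands appearing as
reflectance dips at 540 and 577 nm, and a steep positive reflectance
slope over 600–650 nm produced by methemoglobin and hemichrome. As stains
age over days, the α/β dips flatten and the slope relaxes, which is what
makes naive raw-reflectance matching fragile.

`hemospec` implements the identification pipeline end to end:

1. empirical-line calibration of encoded radiance to reflectance,
2. region-of-interest (ROI) extraction at 540 nm,
3. spectral pre-treatments (SNV, MSC, Savitzky–Golay smoothing),
4. the Savitzky–Golay **second derivative** (13-point window, order-3
   polynomial) that converts weak, aging-sensitive dips into robust
   curvature features,
5. band selection to 470–770 nm,
6. classification (three SVM kernels, k-NN, a small dense network, a
   decision tree, a random forest), and
7. evaluation (confusion matrix; overall accuracy, Cohen's κ, precision,
   sensitivity, specificity, F1) under two splitting disciplines.

Because casework hypercubes are rarely shareable, the package ships a
synthetic hypercube generator that reproduces the spectral physics above;
every stage is tested against it.

## The synthetic spectral model

Each substance is a sum of Gaussian absorbance bands converted to
reflectance through a Beer–Lambert-style relation,

$$R(\lambda) \;=\; B(\lambda)\,10^{-A(\lambda)},\qquad
A(\lambda)=\sum_i m_i d_i\,
\exp\!\left(-\frac{(\lambda-c_i)^2}{2w_i^2}\right),$$

where $B$ is the substrate baseline (white cotton fabric ≈ 0.52–0.58,
the most absorbing; white tile ≈ 0.90–0.92; PVC wall sheet ≈ 0.81–0.85,
each with a gentle tilt), $c_i, w_i, d_i$ are band centre, width, and
depth, and $m_i$ is a per-day aging multiplier. Gaussian absorbance bands
are the standard chemometric stand-in when a study reports band positions
and qualitative shapes rather than coefficients.

Blood is modelled with:

| band | centre/width (nm) | depth | aging multipliers (day 1–3) |
|---|---|---|---|
| Soret | 415 / 20 | 1.00 | fixed |
| β oxyhemoglobin | 540 / 12 | 0.45 | 1.0, 0.7, 0.45 |
| α oxyhemoglobin | 577 / 10 | 0.40 | 1.0, 0.7, 0.45 |
| broad oxy envelope | 560 / 40 | 0.60 | fixed |
| methemoglobin/hemichrome | 630 / 40 | 0.10 | 1.0, 1.3, 1.6 |
| oxidative browning | 450 / 80 | 0.30 | 0.0, 0.5, 1.0 |

Three structural choices matter and were genuinely open:

* **The broad 560 nm envelope does not age.** If it decayed at the α/β
  rate, the background under the dips would brighten faster than the dips
  shrink and the *absolute* dip depths would grow with age — the opposite
  of what aged stains show. Keeping it fixed makes α/β dip depths and the
  600–650 nm slope strictly decreasing in day (the slope decay is driven
  by methemoglobin growth filling in the 630 nm region).
* **Aging carries a broad browning component** (450/80 nm, growing from
  zero). Day-1 and day-3 spectra then differ mostly by smooth, wide
  structure in raw reflectance, while their second derivatives — which
  suppress anything much wider than the filter window — remain close.
  This reproduces the observed homogenization: after the derivative
  transform, aged and fresh blood are more alike (standardized L2 over
  470–770 nm) than their raw spectra are.
* **Donor variation is a scalar baseline factor** in [0.9, 1.1] drawn per
  donor (band centres never move), matching the observation of level
  shifts with stable dip positions. Setting the shift to 0 is an
  ablation switch: donor classes then collapse to chance in the
  multi-class experiment, which the tests assert.

Confusers are red-hued (strong absorption below ~600 nm) with broad bands
only: rust acrylic paint carries two flanking bands (470/25, 555/30) that
produce the characteristic reflectance hump near 510 nm, and both nail
polishes carry faint NIR troughs near 925 nm. None has the narrow 540/577
pair — that, plus band *sharpness*, is what the second derivative
exploits.

**Pixel noise.** Each stain pixel is
`mult × R(λ) + offset + ε(λ)` with `mult ~ N(1, 0.03²)`,
`offset ~ N(0, 0.01²)` (constant per pixel), and heteroscedastic
`ε(λ) ~ N(0, (0.01·R(λ))²)`; values are clipped to (0, 1.2]. Noise
magnitudes are implementer choices; these levels produce visibly noisy single-pixel
spectra with stable stain means and are deliberately conservative. A
single `scale` knob exists only for ablation (tests verify accuracy
degrades monotonically as noise grows 20-fold).

**Design layout.** `generate_full_design()` emits the full sampling
frame: 3 substrates × 3 days × (9 blood stains = 3 donors × 3 replicates,
plus 16 non-blood = 8 substances × 2 replicates) = 225 stain cubes, 81
blood and 144 non-blood. Stain discs have diameters drawn from 14–19.5 px
so pixel counts vary (~150–300, about 200 on average) — the desk-scale
stand-in for the 100 × 100 × 224 per-stain cubes of a real campaign.
`generate_blind_scene()` renders full 410 × 512 × 224 frames holding two
stains from a *fourth, never-trained* donor (days 1 and 3) and four
confusers.

What the generator does **not** emulate: spatial texture within stains
(pixels are exchangeable), substrate weave patterns, specular effects,
wavelength-dependent focus, or sensor smile/keystone. Perfect scores on
synthetic data therefore demonstrate the pipeline's correctness and the
sufficiency of the derivative criteria for the modelled physics — not
performance on any real camera.

## Calibration

A pushbroom scanner records one line (columns × bands) per frame; dark
and white references are captured as 100 such line-frames and averaged.
The empirical-line method computes, per pixel and band,

$$\mathrm{Reflectance}
  = \frac{R_\mathrm{specimen}-D_\mathrm{ref}}{W_\mathrm{ref}-D_\mathrm{ref}},$$

with the averaged reference lines broadcast along the scan axis (standard
pushbroom practice; the mapping is not otherwise specified by line-scan
conventions). The ratio is invariant to any common affine re-encoding of
the three signals. Real denominators can be tiny at band edges, so output
is clipped to a configurable [−0.05, 1.5] with the clipped count recorded
in metadata rather than silently discarded. ENVI I/O emits `data type =
4` (float32), little-endian, any of BIL/BIP/BSQ, wavelengths in nm.

## Savitzky–Golay filtering

`sg_coefficients()` solves the windowed least-squares system directly
(Vandermonde on offsets −h…h), so the classical tables fall out as
checks: window 5 / order 2 / smoothing gives (−3, 12, 17, 12, −3)/35.
Derivatives are scaled by `spacing^(−deriv)`; with the default grid the
units are reflectance · nm⁻². Edges are handled by evaluating the
first/last window's fitted polynomial at the edge offsets — no shrinkage,
and the whole map is a band-limited `224 × 224` matrix so a pixel table
filters in one BLAS product. Tests pin every output point to an explicit
per-window `lm()` refit oracle (≤ 1e−9 relative) and cross-check the
interior against `signal::sgolayfilt`.

The identification setting is window 13, order 3, derivative 2. On the
~2.7 nm grid a 13-point window spans ~33 nm: wide enough to suppress
pixel noise and the browning-scale structure, narrow enough that the
10–12 nm α/β bands survive as strong curvature features bracketing 540
and 577 nm with sign changes. Whether a separate smoothing pass preceded
the derivative in the original workflow is unstated; the default here is
the single derivative pass (one filter already implies its own
smoothing), with smoothing available as `sg_spec(13, 3, 0)`.

## Features and splitting discipline

Filtering is applied to the full 224-band spectrum *before* band
selection so the 470–770 nm window never sees filter edge artefacts. The
default window keeps 111 bands on the uniform grid (the printed feature
count of 110 depends on the camera's true band-centre list, which is not
published; the selector reports its own count). Features are min–max
normalized to [0, 1] using **training-row statistics only** — held-out
rows may leave [0, 1]; fitting normalization on all rows would leak the
test distribution and is refused by construction. The PCA baseline (3
components) is likewise fitted on training rows only.

Two splitting schemes mirror the two reporting tables:

* **sample-based** — stains are atomic; within each (class, day,
  substrate) stratum, 70% of stains form the training pool and 30% the
  external test, then 20% of pool stains become internal validation;
* **pixel-based** — every stain is cut 56/14/30 (train / internal
  validation / external test, floors with remainders to training).

Internal validation is exposed for monitoring and is used for exactly one
decision: choosing k for k-NN over 1–20. Nothing else is fitted on it.

## Classifiers

SVMs (linear, RBF, cubic polynomial) come from `e1071`, the decision
tree from `rpart` (entropy splitting, depth ≤ 10), the random forest
from `randomForest` (500 trees). k-NN is implemented in-package with a
blocked BLAS distance computation and a neighbour table shared across all
candidate k (tuning with a reference implementation would recompute all
distances 20 times); tests verify agreement with `class::knn` on
tie-free queries. The dense network (three hidden layers of 30
rectified-linear units, softmax output, cross-entropy loss,
adaptive-moment updates, batch 128, 50 epochs) is implemented in-package
as plain matrix code; any standard initialization reproduces the
separability results, and all stochastic families are seeded so one
master seed fixes the entire experiment byte-for-byte.

## Metrics

From the confusion matrix (rows = truth): OA = trace/N; per-class
precision, sensitivity, specificity one-vs-rest, macro-averaged; F1 as
the harmonic mean of macro precision and macro recall; AA = macro recall;
κ = (P₀ − Pₑ)/(1 − Pₑ) with Pₑ = Σᵢ rowᵢ·colᵢ/N². Two printed formula
variants in the source material — an overall accuracy written as
(1/C)ΣTPᵢ, and a chance term squaring the truth marginal — are not
proportions and would deny κ = 1 to perfect binary agreement; the
standard forms are implemented and the variants documented here.
Degenerate denominators yield `NA`, never a silent 0.

## Problem sizes and reproduction

The shipped experiments run at the generator's default desk scale
(~200 px/stain ⇒ ~50 000 labelled pixels; blind scenes at full
410 × 512). `scripts/acceptance.R` regenerates the design from a seed,
runs the binary experiment per substrate for all seven families
(sample-based splitting), reports the **minimum** external-test OA over
all 21 substrate × family cells, then trains a linear SVM on the full
design and reports the stain-level blood extraction rate over three blind
scenes (six unseen-donor blood stains). Unit tests exercise the same
machinery on 5–9 px discs, which preserves every structural property at a
fraction of the cost.

## Known limitations

* The spectral model is phenomenological: Gaussian bands on absorbance,
  no radiative transfer, no substrate–stain interaction beyond a
  multiplicative baseline.
* Aging magnitudes (multipliers, browning depth) are calibrated to the
  *qualitative* published claims (dip decay, slope decay, derivative
  homogenization), not to measured kinetics.
* Donor differences are scalar level shifts; real inter-donor variation
  has spectral shape components, so the synthetic multi-class donor task
  is *harder* than the real one reported (donor recall near chance under
  ablation, ~0.4–0.7 at the default ±10% shift).
* Temperature/humidity effects and chemical enhancement workflows are out
  of scope.
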