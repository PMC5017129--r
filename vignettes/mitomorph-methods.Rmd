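---
title: "Quantifying whole-cell mitochondrial morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-cell mitochondrial morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A cell's mitochondrial phenotype — the proportions of small ovoid
(*punctate*), short rod-like (*intermediate*) and long, branched
(*filamentous*) mitochondria, together with total mitochondrial area and its
density relative to cell area — is informative about metabolic state and
drug response, but it has to be read out of fluorescence Z-stacks in which
any single focal plane shows only part of the organelle population in
focus. `mitomorph` implements the full measurement chain:

1. **All-in-focus fusion** of the Z-stack into one 2-D image,
2. **Segmentation** of individual mitochondria from that image,
3. **Shape-descriptor extraction** and **three-class classification**,
4. **Population statistics** over cells and samples,

plus a **synthetic-image simulator** whose generative ground truth lets
every stage be validated end to end without any external data.

# All-in-focus fusion

Each pixel of the fused image is taken from the slice in which the local
neighbourhood is sharpest. Sharpness is the local variance (window
`window = 9` px, reflected borders) of the 4-neighbour Laplacian of the
slice. Two numerical details matter in practice:

* **Shot-noise suppression** (`preSigma = 1` px). Photon noise contributes
  variance to the Laplacian in proportion to local intensity, so a bright
  but defocused structure can out-score its own in-focus rendition. A light
  Gaussian pre-smoothing before scoring (the fused image still samples the
  *original* intensities) removes this failure mode; in simulations it
  reduces the fraction of object pixels assigned to a far-off slice from
  about 6% to zero.
* **Majority smoothing** (`smoothRadius = 5` px). The per-pixel arg-max map
  is modal-filtered so selection does not flicker between slices inside one
  object; ties go to the lower slice index, making fusion fully
  deterministic.

On single-slice input, fusion is the identity.

# Segmentation

The fused image passes through the classical chain: rolling-ball background
subtraction, FFT band-pass, adaptive local-mean thresholding, binary
open–close cleanup, 8-connected labelling, restricted to a per-cell polygon
ROI.

* **Rolling ball** (`ballRadius = 50` px): background is the grayscale
  opening with a flat disc, clipped at image borders; subtraction is exact
  morphology (verified against brute-force evaluation to 1e-9), so it
  commutes with additive constants and never produces negative pixels.
* **Band-pass** (`bandpassLow = 0.2`, `bandpassHigh = 4` µm): a radially
  symmetric transfer function, flat at 1 inside the passband with Gaussian
  skirts (sigma = cutoff/3) outside and DC forced to zero. The Gaussian
  skirts avoid the ringing of an ideal annulus; the passband spans
  mitochondrial widths up to cluster scale. Narrower high cutoffs (≤ 2 µm)
  were rejected because they attenuate the along-axis spectrum of long
  filaments and fragment them.
* **Adaptive threshold** (`window = 51` px): foreground iff intensity
  exceeds the local mean plus an offset. The automatic offset is
  `max(2·σ̂, 0.1·q99.9)`, where σ̂ is a robust noise scale from median
  absolute horizontal pixel differences. First differences see only
  pixel-scale noise, so σ̂ does not inflate when much of a dense cell is
  covered by object halos (a plain MAD of intensities does, by ~3×, and
  then fragments dim filaments); the small signal-quantile term keeps the
  cut meaningful on essentially noise-free images, where a pure noise
  threshold collapses to zero and the mask balloons.
* **Cleanup** (`openingRadius = 1`, `closingRadius = 1` px,
  `minObjectArea = 0.2` µm²): open–close with flat discs, then 8-connected
  labelling with an area floor. The floor sits below the image-domain
  footprint of the smallest resolvable object (measured punctate areas are
  ≥ ~0.3 µm² at the default optics) but above residual threshold specks
  (≤ ~0.15 µm²).

# Shape descriptors and classification

Ten descriptors per object, all calibrated to micrometres: area, perimeter,
ellipse-equivalent major/minor axis and eccentricity (second-order
moments), solidity (area over convex-hull area, clamped at 1), form factor
(4πA/P², clamped at 1), skeleton length, skeleton branch-point count, and
aspect ratio.

The skeleton is computed by Zhang–Suen thinning with three corrections that
make its statistics usable as classification features:

* **Spur pruning**: thinning turns mask boundary roughness into sub-width
  side twigs; terminal spurs shorter than 0.35 µm (about one tube radius)
  that end at a junction are removed.
* **Crossing-number junctions**: a branch point is where the circular
  crossing number is ≥ 3. Plain neighbour counting misfires on staircase
  double pixels of diagonal skeletons.
* **Tip extension**: thinning erodes each end of an elongated object by
  roughly its local half-width (at 45° nearly the full width), so the
  Euclidean distance-map value at each skeleton leaf is added to the
  minimum-spanning-tree length over the skeleton adjacency graph. Without
  this, a 2.5 µm rod at 45° can measure under 1 µm.

Classification is a random forest (200 trees, √p features per split, fixed
seed; out-of-bag confusion and an MD5 hash of the training table are stored
in the model for reproducibility). A transparent threshold rule — branch
point or skeleton length > 4 µm ⇒ filamentous; < 1 µm ⇒ punctate;
otherwise intermediate — serves as a cross-check and fallback. Prediction
ties go to the less elongated class, and are logged.

# The simulator

`renderStack()` draws object classes from a mixture, generates geometry
from per-class archetypes, places the objects in the cell polygon, and
images them through a Gaussian PSF with linear defocus growth plus the
standard camera model (Poisson shot noise, additive Gaussian read noise).
Defaults are one fixed set of study conditions:

| parameter | default | rationale |
|---|---|---|
| pixel size | 0.1 µm/px | high-NA oil objective with a modern sCMOS |
| Z-step | 0.5 µm | typical acquisition spacing |
| PSF sigma (in focus) | 0.15 µm | diffraction-limited visible-light imaging |
| defocus gain | 0.4 µm blur / µm defocus | linear surrogate for the defocus cone |
| photon scale | 200 photons at unit intensity | moderate-SNR fixed-cell staining |
| read noise | 2 counts | sCMOS-like |
| objects per cell | 30 | resolvable density at desk scale |
| cell polygon | 19 µm-radius circle in a 41.6 µm frame | adherent cancer-cell footprint that fits 30 objects at any mixture |
| archetypes | punctate 0.3–0.8 µm ovoids (aspect < 2); intermediate 1–3 µm rods; filamentous 4–12 µm curves, 0–3 branches | the field's verbal descriptions of the three classes |

Placement is hard-core: each object lies entirely inside the cell polygon
with at least 1.2 µm between true footprints (about the optical footprint
of the blur). Fixed-cell mitochondria occupy disjoint 2-D footprints, and
the segmentation stage deliberately does not watershed-split touching
objects, so the generator keeps objects resolvable by construction; the
count of unavoidable best-effort placements is reported as
`placementFailures`.

The **in-silico validation condition** (`insilicoSpec()`) is distinct from
the acquisition-like defaults: widened-margin archetypes (0.4–0.6 /
1.8–2.8 / 6–10 µm), no noise, a minimal 0.08 µm PSF and no defocus. It
emulates feeding ideal artificial shapes to the classifier, where both the
forest and the threshold rule are expected to be perfect.

What the simulator does **not** model: fission/fusion dynamics over time,
3-D volumetric structure (objects live at a single depth), fixation
artifacts, spatially varying background, and optical aberrations beyond
isotropic Gaussian blur. Passing tests therefore demonstrate correctness of
the measurement chain under a controlled optical model, not performance on
any particular microscope's data.

# Population statistics

Per cell: class counts and fractions (count-weighted by default;
area-weighted mode available, since either convention is defensible for
published per-cell percentages), total mitochondrial area, and density =
mitochondrial area / polygon area. Per sample: means and dispersions over
cells. The **total morphology change** between two populations is the sum
over the three classes of the absolute change in mean class percentage
(range 0–200 points); a relative-change mode is provided. Pearson
correlation (via the standard product-moment test) connects phenotype to
external per-sample measurements such as oxygen consumption and
extracellular acidification rates. Friedman's rank sums test compares
related condition distributions; for ≤ 10 blocks an exact/permutation
p-value is computed (full enumeration when the number of within-block
orderings is ≤ 1e5, otherwise a seeded Monte Carlo sample). The
longitudinal stability report applies Friedman's test per class across
timepoints, pairing cells by acquisition index (cells are exchangeable
draws from the population, so the null is exact even though cells are not
physically tracked week to week) and Bonferroni-combining the three
per-class p-values.

Classifier confusion measured on a labelled benchmark can be inverted out
of measured population fractions with `correctClassFractions()` (linear
unmixing, clamped to the simplex).

# Validation design and problem sizes

The test suite validates each filter against brute-force oracles on small
instances (exact for binary morphology, 1e-6 for float operations), and the
pipeline end to end at these scales, chosen to keep a desk-scale run within
minutes while leaving binomial confidence intervals tight enough to be
meaningful:

* classifier benchmark: 1000 objects, balanced mixture, 800/200 train/test
  split; held-out error is required to stay below 4%;
* in-silico archetype check: 50 objects per class at the validation optics,
  100% required of both classifiers;
* mixture recovery: mixtures (0.8, 0.1, 0.1), (⅓, ⅓, ⅓), (0.1, 0.1, 0.8) at
  100 cells × 30 objects, recovered within 95% binomial intervals after
  confusion correction;
* dose-response: punctate weight 0.1 → 0.9 across five levels at 25 cells
  per level, requiring strictly increasing measured punctate fraction and
  total-change metric.

# Known limitations

* **Area inflation at acquisition optics.** Sub-resolution objects
  (punctate, and the width of all objects) are measured through the PSF:
  at the default blur, measured areas run ~2–3.5× ground truth for
  punctate and ~1.1–1.7× for filaments. This is diffraction, not a bug;
  classification is trained on the measured representation and is
  unaffected. Area fidelity (within 25%) is therefore asserted at the
  crisp in-silico optics, and absolute areas from real data should be
  interpreted as image-domain areas.
* **No splitting of touching mitochondria**: objects that overlap in
  projection merge into one component.
* **Skeleton length** is a geodesic estimate; for highly curved, branched
  objects the tip extension slightly overestimates total length (each leaf
  regains its cap).
* The Friedman blocking convention for longitudinal data (index pairing) is
  one defensible choice among several; with ~100 cells per timepoint the
  test's behaviour is indistinguishable from condition-wise resampling.
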