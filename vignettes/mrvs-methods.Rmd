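---
title: "Multi-branch OCTA vessel segmentation: models, parameters and design notes"
author: "mrvs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-branch OCTA vessel segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrvs)
```

## The problem

En-face optical coherence tomography angiography (OCTA) renders retinal
blood flow as bright, elongated structures on a speckled background. On a
3 mm x 3 mm macular scan of the superficial capillary plexus, two caliber
classes coexist: a handful of large arteriolar/venular trunks entering
from the field borders, and a dense capillary meshwork that surrounds a
capillary-free region at the fovea (the foveal avascular zone, FAZ).
Quantitative biomarkers -- vessel density, skeleton density, caliber and
complexity indices, fractal dimension, FAZ morphometry, non-perfusion
area -- all start from a binary vessel segmentation, so the segmentation
has to handle both caliber classes at once.

`mrvs` implements a two-branch segmentation: a large-vessel branch tuned
to trunks, a capillary branch tuned to the meshwork, and a fusion step
that takes the union of the two foregrounds. Everything downstream (24
metrics, FAZ/non-perfusion detection, evaluation and repeatability
statistics) is built on that fused mask.

## The segmentation model

### Oriented line strength

Both branches rest on the basic line detector. For a pixel $p$, a window
size $W$ (odd), and orientations $\theta \in \{0^\circ, 15^\circ, \dots,
165^\circ\}$ (12 directions, $15^\circ$ apart), let $\bar\ell_\theta(p)$
be the mean gray level along the digital line of length $W$ through $p$
at angle $\theta$ (Bresenham rasterization, clipped at the image
border), and $\bar w(p)$ the mean of the $W \times W$ window centred on
$p$ (also border-clipped). The line strength is

$$S(p) \;=\; \max_\theta \bar\ell_\theta(p) \;-\; \bar w(p).$$

$S$ is large on elongated bright structures, zero on flat regions, and
negative in dark gaps. Subtracting the window mean is the classical
formulation of this detector; it also makes $S$ invariant to adding a
constant to the image, which the test suite checks exactly. A defensible
alternative would be the raw maximum line average without subtraction;
we implement the subtraction variant because without it the later
vessel/background separation is ill-posed on bright backgrounds.

Two properties drive the scale choice: a straight bright line scores the
full contrast at any window size, while a *tortuous* thin vessel scores
less at large windows (the straight probe line leaves the vessel within
the window). A 25-px window therefore favours smooth large trunks; a
7-px window follows capillaries.

### Large-vessel branch

1. $S_{25}$ = line strength at the 25 x 25 px window.
2. Combined map $C = w_s\,\mathrm{norm}(S_{25}) + w_i\,\mathrm{norm}(I)$
   with $w_s = 1/3$, $w_i = 2/3$ and min--max normalization to $[0,1]$.
3. Rough binarization: Otsu threshold on $C$ (parameter-free; a constant
   map yields an all-background mask with a warning).
4. Background attenuation: pixels outside the rough mask are multiplied
   by $0.5$ and rounded half-up; rough-foreground pixels pass unchanged.
5. Gray-level K-means ($k = 2$) on the attenuated image; the vessel mask
   is the cluster with the higher centroid.
6. Speckle suppression: 4-connected components smaller than
   $7^2 = 49$ px are removed.

The K-means initialization is deterministic (centroids at the 25th and
75th percentile gray values; Lloyd iterations until both centroids move
less than $10^{-6}$ or 100 iterations), so repeated runs are bit-identical.
Assignment ties at the midpoint go to the lower cluster.

### Capillary branch

Detected large-vessel pixels are first overwritten with the flat gray 45
(0--255 scale) so their strong gradients do not leak into the capillary
scale. The image is then enhanced by the top--bottom hat transform with a
disk structuring element of radius 8 px,

$$E = \mathrm{clip}\big(I + (I - I \circ b) - ((I \bullet b) - I)\big),$$

which lifts capillary-scale bright detail and suppresses dark pits, and
the same five-stage chain runs at the 7 x 7 px window on $E$. The final
capillary mask excludes large-vessel pixels, so the two branch masks are
disjoint and the per-caliber densities add up exactly.

One deliberate deviation from a literal per-branch reading: speckle
suppression in the capillary branch judges component size on the union
of the capillary K-means mask and the large-vessel mask *before*
excluding large-vessel pixels. Capillaries physically branch off larger
vessels, so a capillary fragment that touches the large-vessel network
is anatomy, not noise; judging it in isolation would delete exactly the
perivascular capillaries the branch exists to recover (we observed the
capillary branch degenerating to an empty mask under the literal order).

### Fusion

The fused segmentation is the logical OR of the two branch masks -- an
exact union, tested as such.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `win_large_px` | 25 | px | line-detector window, large branch |
| `win_cap_px` | 7 | px | line-detector window, capillary branch |
| `n_orientations` / `angle_step_deg` | 12 / 15 | -- / deg | orientation sampling (product fixed at 180) |
| `w_struct` / `w_intensity` | 1/3 / 2/3 | -- | combination weights (sum to 1) |
| `background_atten` | 0.5 | -- | background attenuation factor |
| `large_vessel_fill_gray` | 45 | gray | fill value before capillary enhancement |
| `tophat_se_radius_px` | 8 | px | disk radius of the hat transform (~75 um at 320 px / 3 mm: larger than any capillary, smaller than background undulation) |
| `faz_close_radius_px`, `npa_close_radius_px` | 10 | px | closing radius sealing intercapillary gaps before avascular-region labeling |
| `npa_min_area_mm2` | 0.015 | mm^2 | minimum reportable non-perfusion region |

Window sizes, weights, the attenuation factor, the fill gray and the
orientation sampling are the method's published operating point; the
closing radii and area floor parameterize the FAZ/non-perfusion
replacement procedure described below and scale with resolution through
the configuration.

## FAZ and non-perfusion detection

The upstream FAZ/non-perfusion literature is cited without algorithmic
detail, so `mrvs` adopts a transparent morphological procedure with all
radii and thresholds exposed in the configuration:

1. Close the fused vessel mask with a disk (radius 10 px) to seal
   intercapillary gaps.
2. Label the remaining background with 4-connected components.
3. FAZ = the component containing the image center, or failing that the
   component whose centroid lies nearest the center; no avascular
   component within 0.5 mm of center raises a FAZ-not-found error.
   Interior holes are filled before morphometry.
4. Non-perfusion regions = the remaining components, excluding any that
   touch the outer border margin (one closing-radius wide -- border
   background is a field-of-view artifact, not dropout) and any smaller
   than `npa_min_area_mm2`.

FAZ morphometry reports area (pixel count times $\mathrm{mm}^2$/px),
perimeter, circularity $4\pi A/P^2$, ellipse axes, orientation and
eccentricity from second-order central moments (with the $1/12$ pixel
footprint correction), and the horizontal/vertical extents through the
centroid. Orientation is measured counter-clockwise in display
orientation from the horizontal axis, in $(-90^\circ, 90^\circ]$.

**Perimeter convention.** Counting boundary pixels overestimates a
digital circle's perimeter by roughly 25%, which would cap a perfect
disk's circularity at about 0.63. FAZ perimeter therefore uses a
4-direction Crofton intercept estimate (error below 1% on digital
disks), restoring circularity $\approx 1$ for circular FAZs. The vessel
*perimeter index*, by contrast, is a boundary-pixel density over the
field and keeps the plain count: it is a per-area index, not a length
estimate, and the two conventions are documented separately.

## The 24 metrics

Densities are foreground fractions of the field (or of a circular ROI);
the skeleton is a Zhang--Suen thinning of the mask; the perimeter mask
contains foreground pixels 8-adjacent to in-image background. On top of
these: vessel diameter index (mask area / skeleton length -- mean
caliber in px), vessel complexity index ($P^2 / 4\pi A$), and the
box-counting fractal dimension of the skeleton (box sizes 2--64 px on a
grid anchored at the origin; least-squares slope of $\log N(s)$ against
$\log s$, negated). Big/small metrics come from the two branch masks;
the 1-mm and 2-mm circle densities use disks of the stated *diameter*
centred on the FAZ centroid (image center when no FAZ is found). Box
origins are fixed rather than averaged, for determinism. Undefined
metrics (empty skeleton, FAZ not found) are reported as NaN sentinels,
never as zero, so downstream statistics can exclude them.

## Evaluation and repeatability

Against a ground-truth mask: sensitivity, specificity, accuracy, Dice
coefficient, Matthews correlation (zero when any confusion marginal is
empty), and the vessel volume difference
$|{(tp{+}fp) - (tp{+}fn)}| / (tp{+}fn)$, i.e. relative to ground-truth
volume -- the "absolute" in its name refers to the absolute value, and
the convention is stated explicitly because the phrase is ambiguous.

For test--retest tables (subjects x repeats): the within-subject SD
$S_w$ is the root of the mean per-subject sample variance (identical to
the one-way ANOVA within mean square for balanced tables), the
coefficient of variation is $100 \cdot S_w / \bar x$, and reliability is
the one-way random-effects single-measurement ICC(1,1),
$(\mathrm{MSB} - \mathrm{MSW}) / (\mathrm{MSB} + (k-1)\mathrm{MSW})$.
ICC(1,1) is the standard choice when the same device re-scans the same
eye and no rater/session structure exists; which ICC variant the
original analysis used cannot be determined from the text, so the
estimator is documented and swappable. It may be slightly negative when
within-variance dominates; an all-equal table returns NaN with a
warning. A simulation test verifies the estimator recovers a true
reliability $\rho = \sigma_b^2/(\sigma_b^2 + \sigma_w^2)$ within 0.05.

## The synthetic phantom

No clinical images ship with the package; every pipeline stage is tested
against a generated angiogram with pixel-exact ground truth. The phantom
emulates, on a 320-px / 3-mm field by default:

- **Large trunks** (2--4, widths 5--9 px): correlated random walks
  growing inward from the borders, heading mean-reverting to the launch
  direction so trunks cross the field with gentle curvature, stamped as
  overlapping disks, steered around the FAZ.
- **Capillary branches** (widths 1--2 px): spawned from trunk steps with
  probability 0.08 per step, more tortuous, terminating at the FAZ
  boundary; branches can branch once more.
- **A perifoveal arcade and a space-filling mesh**: a capillary ring
  just outside the FAZ boundary, and a jittered quadrilateral lattice
  (~0.12 mm pitch) of thin wiggly segments. Real superficial-plexus
  capillaries are space-filling with bounded intercapillary spacing;
  without the mesh, walk-based coverage leaves incidental avascular
  pockets large enough to masquerade as non-perfusion. Both are drawn
  only when `branching_prob > 0`, so a zero-branching phantom contains
  exactly its trunks.
- **FAZ**: an ellipse (semi-axes 0.25 x 0.20 mm) with low-frequency
  sinusoidal boundary jitter, keeping the analytic area $\pi a b$
  approximately valid (the jitter perturbs area by $O(j^2)$).
- **Dropout pockets**: optional stamped avascular ellipses
  (~0.08--0.12 mm^2, at 0.8--1.15 mm eccentricity), the ground truth for
  non-perfusion detection.
- **Intensity**: per-pixel uniform draws (large vessels 180--255,
  capillaries 90--160, background 40) multiplied by unit-mean gamma
  speckle -- the standard multiplicative OCT speckle surrogate -- and
  clipped to [0, 255]. Anatomy grays are drawn once per geometry;
  repeated "acquisitions" share them and differ only in speckle, with
  per-repeat seeds derived deterministically from the master seed.

Reproducibility properties are engineered, not incidental: the same spec
and seed give bit-identical bundles, and raising `branching_prob` only
*adds* capillaries (spawn decisions consume pre-drawn per-site uniforms;
each branch grows from its own derived seed), which makes the
vessel-mask monotonicity property exact.

**What the phantom does not emulate** -- and hence what passing tests do
not establish about clinical data: projection and motion artifacts,
depth-dependent signal loss, flow-dependent contrast, vessel-coherent
intensity (real vessels vary smoothly along their length; the phantom
draws per-pixel), and real FAZ shape diversity. Phantom scores should be
read as verification of the algorithmic chain, not as expected clinical
accuracy.

## Numerical choices and degenerate inputs

- Coordinates are (row, col), origin at the top-left pixel; the image
  center of an even-sized image falls between pixels and is rounded for
  the center-containment test.
- Background attenuation rounds half-up (22.5 -> 23), stated explicitly
  for bit-reproducibility.
- Min--max normalization maps a constant input to all zeros; Otsu on a
  constant map warns and returns all-background; K-means on a constant
  image returns an empty vessel mask; empty skeletons/masks yield NaN
  metrics.
- Maxima over orientations need no tie-breaking (the maximum of means is
  orientation-agnostic).
- Line/window means at the border average in-bounds pixels only -- no
  padding, so the 3-mm field edge is artifact-free.

## Known limitations

- **Caliber separation depends on capillary brightness.** With the
  phantom's default bright capillaries (90--160 on a background of 40),
  the large-branch K-means absorbs much of the capillary network, so
  big/small metrics under-separate even though the *fused* mask is
  accurate; with near-background capillaries the same code separates
  branches cleanly. Real OCTA sits between these regimes. The per-branch
  agreement on the reference phantom is pinned as a regression value in
  the tests rather than asserted as a quality bar.
- **Two-class clustering hallucinates on vessel-free fields.** On a
  phantom with no capillaries at all, the capillary branch's K-means
  necessarily bisects the background speckle and leaves a substantial
  residue; this degenerate case is likewise pinned, not hidden.
- Circularity from any discrete perimeter estimate can slightly exceed 1
  on near-circular shapes.
- Resolution is a free parameter (the instrument's export size is not
  fixed); all physical metrics scale through `mm_per_px`, which the
  tests check on analytic shapes at 160 and 320 px.

## Problem sizes used by the test-suite and acceptance script

Phantom-based checks run at the default 320 px on 10 seeds (recovery,
degradation at three speckle levels, FAZ morphometry), 192 px for the
40-acquisition repeatability experiment, and 96--160 px for contract and
CLI tests; oracle-equivalence checks use 20 random 32 x 32 images for
the line detector and 20 random 64 x 64 mask pairs for the evaluation
metrics. These sizes are the package's chosen verification conditions
and are stated here so they can be scaled up by anyone wanting tighter
Monte-Carlo confirmation.
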