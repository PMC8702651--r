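# mrvs — multi-branch retinal vessel segmentation for OCTA angiograms

`mrvs` segments retinal vessels on en-face optical coherence tomography
angiography (OCTA) images and quantifies the standard vascular and
foveal-avascular-zone (FAZ) biomarkers built on that segmentation. It is
aimed at ophthalmic-imaging researchers who export 3 mm × 3 mm
superficial-plexus en-face scans (TIFF) and need reproducible,
parameter-transparent quantification — plus a synthetic phantom
generator so the whole chain can be validated without clinical data.

## The method

Segmentation runs in two branches fused by union:

- **Large-vessel branch** — oriented line strength at a 25 × 25 px
  window, `S(p) = max_θ ℓ̄_θ(p) − w̄(p)` over 12 directions 15° apart
  (mean gray along a digital line through `p`, minus the window mean);
  combined with intensity as `C = (1/3)·norm(S) + (2/3)·norm(I)`; rough
  Otsu binarization; detected background halved; gray-level 2-means
  (deterministic percentile initialization) takes the brighter cluster;
  components < 49 px removed.
- **Capillary branch** — large vessels filled with gray 45, top–bottom
  hat enhancement (`I + tophat − bottomhat`, disk radius 8 px), then the
  same chain at a 7 × 7 px window; large-vessel pixels excluded so the
  branch masks are disjoint.

From the fused mask: skeleton (Zhang–Suen), perimeter map, FAZ and
non-perfusion regions (morphological closing + 4-connected avascular
components), and 24 metrics — vessel/skeleton/perimeter densities,
vessel diameter index (area/skeleton length), complexity index
(P²/4πA), box-counting fractal dimension, big/small branch densities,
non-perfusion area, nine FAZ shape descriptors, and 1-mm / 2-mm circle
densities centred on the FAZ. Segmentation accuracy metrics (SE, SP,
ACC, DSC, MCC, VVD) and test–retest statistics (Sw, CoV = 100·Sw/mean,
one-way ICC(1,1)) complete the toolbox.

See `vignettes/mrvs-methods.Rmd` for the full model description,
parameter rationale and design notes.

## Worked example

```r
library(mrvs)

# a synthetic 3-mm angiogram with pixel-exact ground truth
bundle <- generate_phantom(phantom_spec(seed = 42, speckle_shape = 50))

fit <- mrvsm(bundle$image)   # full pipeline: both branches + metrics
fit
#> MRVS segmentation of a 320 x 320 angiogram (3 mm field)
#>   vessel density 0.3712 (big 0.3390, small 0.0321)
#>   FAZ area 0.1566 mm2, circularity 0.966

eval_masks(fit$fused, bundle$gt_vessel)
#> Segmentation evaluation (tp 38006, fp 0, tn 61924, fn 2470):
#>   SE 0.9390  SP 1.0000  ACC 0.9759  DSC 0.9685  MCC 0.9502  VVD 0.0610
```

Reading the numbers: 37.1% of the field is segmented as vessel, close
to the stamped ground-truth density; the fused mask agrees with the
ground truth at Dice 0.97 with no false-positive pixels at this low
noise level; the recovered FAZ area (0.157 mm²) matches the stamped
ellipse (π·0.25·0.20 ≈ 0.157 mm²) and its circularity 0.97 reflects the
mild boundary jitter. `fit$metrics` holds the full 24-column record
(e.g. skeleton fractal dimension 1.699, vessel diameter index 2.27 px,
perimeter index 0.268 for this phantom).

Real images enter through `read_angiogram("scan.tif", field_size_mm = 3)`.
A command-line wrapper (`exec/mrvs`) exposes `segment`, `metrics`,
`faz`, `eval`, `repeat`, `phantom` and `debug-strength` subcommands;
every run writes a JSON manifest with the configuration snapshot and
input hashes.

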