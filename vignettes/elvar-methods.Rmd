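---
title: "Quantifying interstitial lung disease on CT: the ELVAR method"
author: "elvarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interstitial lung disease on CT: the ELVAR method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elvarkit)
```

## The index

Interstitial lung disease (ILD) replaces aerated lung with dense tissue:
reticulation and septal thickening form sheet-like structures, ground-glass
opacity raises attenuation diffusely, and consolidation fills airspaces
entirely. All of these are visible in Hounsfield units (HU) on thin-slice
chest CT. The Effective Lung Ventilation Area Ratio condenses their extent
into one number:

$$\mathrm{ELVAR} = \frac{L - I}{L},$$

where $L$ is the total number of lung voxels and $I$ the number of voxels
occupied by interstitial structure (including, by default, the pulmonary
vessels that the interstitium accompanies). ELVAR is a purely geometric
fraction in $[0, 1]$: it carries no airflow model, and a low value means a
large interstitial compartment and correspondingly little effectively
ventilated lung. Both counts are taken over the whole volume — the ratio is
computed from global counts, not averaged over per-slice ratios — and the
result is reported to 4 decimal places.

Computing ELVAR needs two masks, and the two stages of the method produce
them: an ILD-robust lung segmentation (for $L$) and a curvature-based
interstitial enhancement inside that lung (for $I$).

## Lung segmentation in four stages

Segmenting ILD lungs by plain thresholding fails in exactly the cases that
matter: dense disease does not threshold as lung, and organs indenting the
lung base punch "holes" into naive masks. The pipeline therefore runs four
stages, each per axial slice with 3-D component analysis where connectivity
matters; every intermediate mask is kept for audit.

1. **Coarse air segmentation** (`coarseSegment`). Voxels below
   `airThresholdHU` (default −500 HU, the conventional aerated/soft-tissue
   divide) are air candidates; air connected to the in-plane image border is
   exterior and removed; optionally the tracheal air column is removed (the
   air component whose in-plane centroid lies in the central third of the
   field of view on the topmost 10% of slices); components smaller than
   `minLungComponentMM3` (default 10000 mm³, appropriate for an adult
   thorax at full field of view — reduce it for small-FOV or pediatric data)
   are discarded.
2. **Contour detection** (`detectContours`). The binary indicator is
   smoothed per slice with a Gaussian of `gaussianSigmaMM` (default 1 mm,
   converted to voxels through the spacing, truncated at 4σ), and its
   Laplacian is scanned for zero crossings. A voxel is marked when its
   Laplacian differs in sign from at least one in-plane face neighbor and
   its magnitude does not exceed that neighbor's — the side closest to zero
   wins, equal magnitudes mark both, and an exactly zero Laplacian flanked
   by both signs is marked too. This yields a deterministic,
   single-voxel-thick crossing set. Crossings on the dense side of the
   smoothed transition (indicator < 0.5) form the **outer** boundary — the
   candidate lung edge, which keeps all irregular fragments near the
   boundary — and those on the aerated side the **inner** boundary.
3. **Filling and hole elimination** (`fillContours`, `eliminateHoles`).
   The exterior is flood-filled from the slice border (4-connectivity, the
   crossing set as barrier); everything unreachable is interior and is
   filled, the contour voxels are retained, and the coarse air region is
   superimposed so the filled contour always covers the binary lung region
   it came from. Dense structure inside the filled contour
   (`filled \ coarse`) is then classified: a component is a **mask hole**
   — an adjacent organ (heart, liver dome, stomach) indenting the lung —
   when it is larger than `holeMinVolumeMM3` (default 500 mm³) *and* its
   dense tissue is reached by region growing from the image border, i.e. it
   is connected to the body. Blood vessels are too small to qualify, and
   dense disease, although possibly large, is enclosed by aerated lung
   rather than connected to the body; both are preserved. This
   connectivity condition is what makes the segmentation ILD-robust: a
   size-only rule would carve out large consolidation.
4. **Contour shrinkage** (`shrinkContour`). The quasi-lung mask is eroded
   one boundary layer at a time until every boundary location lies on the
   accurate lung edge. Because the filled contour's own boundary *is* the
   outer crossing, stopping at any crossing would stop immediately; the
   stage therefore stops on the crossing's aerated (inner) side, bounded
   additionally by the smoothed indicator's 0.5 level set wherever the
   discrete crossing set has gaps. The mask never grows, the iteration is
   capped at `shrinkMaxIters` (default 50), and non-convergence — or an
   empty stopping set — leaves the current mask with a diagnostic flag
   rather than failing.

$L$ is the voxel count of the final mask. The containment chain
`lung_final ⊆ contour_filled \ hole` and `coarse_air ⊆ contour_filled`
holds voxelwise by construction, and the whole pipeline is deterministic.

Left and right lungs are never separated: the index is whole-lung.

## Interstitial enhancement

Thresholding density alone misses the point of the enhancement step:
sub-solid reticulation sits well below soft-tissue attenuation, while its
*shape* is highly characteristic. Interstitial sheets and the vessels they
accompany differ from aerated parenchyma in the directional profile of the
local second derivatives, so the enhancement is a multi-scale Hessian
eigenvalue analysis (`curvatureFeatures`). For each in-lung voxel and each
scale in `scalesMM` (default 0.7, 1.4, 2.8 mm, spanning septal thickness to
small vessels), the Hessian of the scale-smoothed HU field is diagonalized
and its eigenvalues sorted by magnitude, $|\lambda_1| \le |\lambda_2| \le
|\lambda_3|$. Bright sheets have one dominant negative eigenvalue, bright
tubes two:

* sheet response: $|\lambda_3|\,\exp(-(\lambda_2/\lambda_3)^2/2\alpha^2)$
  for $\lambda_3 < 0$, with $\alpha = 0.25$;
* tube response (enabled when vessels count toward $I$):
  $\sqrt{|\lambda_2\lambda_3|}\,\exp(-\lambda_1^2/2\beta^2|\lambda_2\lambda_3|)
  \,(1 - \exp(-(\lambda_2/\lambda_3)^2/2\alpha^2))$ for
  $\lambda_2, \lambda_3 < 0$, with $\beta = 0.5$.

The per-voxel score is the maximum over scales, normalized by the volume
maximum to $[0, 1]$ so that `sheetnessThreshold` (default 0.35) transfers
across volumes. Hessian magnitudes scale with the structure's HU contrast
(hundreds of HU for disease against −850 HU parenchyma) while smoothed
noise contributes an order of magnitude less, which is what lets the score
flag low-contrast structure that direct inspection misses.

Curvature alone cannot see the *interior* of consolidation or ground glass
— a flat dense region has zero Hessian inside — so a density fallback
marks any in-lung voxel at or above `densityFloorHU` (default −700 HU,
below ground-glass attenuation but far above parenchyma). The interstitium
mask is the union of both criteria, cleaned of components smaller than
`minComponentVoxels` (default 3), and $I$ is its voxel count. Two
consequences are worth stating plainly:

* Vessels count toward $I$ by default (`includeVesselsInI`). Healthy lungs
  then score ELVAR below 1 by roughly their vascular volume fraction,
  which is what makes healthy and diseased values comparable on one scale.
  Switching the tubular branch off removes vessels from the curvature
  channel only; vessels dense enough to pass the density floor still
  enter $I$.
* No attempt is made to classify patterns (reticulation vs ground glass vs
  consolidation); everything aggregates into the single compartment $I$.

## The digital phantom

No clinical data ship with the package; every claim is validated on a
digital thoracic phantom (`generatePhantom`) with voxel-exact ground truth.
The default specification — these defaults *are* the study conditions of
the validation suite — is a 40 × 128 × 128 grid at 1 mm isotropic spacing:
an elliptical soft-tissue body (+40 HU) in exterior air (−1000 HU), two
ellipsoidal lungs (−850 HU), a procedurally branching intrapulmonary
vessel tree (+50 HU, ~3–4% of lung volume, matching pulmonary vascular
volume fractions), and Gaussian HU noise (σ = 20) added last, after truth
masks are recorded; HU are rounded to integers as calibrated CT data are.
Optional components: a diaphragm-level spherical organ indentation
(default 2000 mm³) reproducing the mask-hole geometry, and a central
tracheal air column for the airway-exclusion rule.

Disease is painted lesion by lesion from a mix of septal sheets (1-voxel
planes, −300 HU), ground-glass blobs (−600 HU) and consolidation blobs
(+20 HU) — conventional radiological HU, since sub-voxel texture is not
modeled — with centers biased toward the outer lung, until the achieved
fraction of lung volume matches `targetFraction` to within one voxel (the
final lesion is trimmed, nearest-to-center voxels kept). Because lesions
accrue as a deterministic stream under the seed, phantoms sharing a seed
have *nested* disease masks across increasing targets, which is what makes
"ELVAR strictly decreases with burden" testable per seed rather than only
on average. Lesions and vessels are clipped two voxels clear of the pleural
surface so that disease is enclosed by aerated lung — the configuration the
hole-elimination rule is designed around; true subpleural disease
(honeycombing abutting the pleura) is outside what the phantom emulates.
Ground truth counts disease plus (configurably) vessels, mirroring the
analysis configuration, and `true_elvar` follows the same formula as the
measurement.

What passing the phantom suite does **not** show: performance on real HRCT
with partial-volume edges, reconstruction-kernel texture, motion, attached
subpleural disease, or vendor-specific calibration. The phantom validates
the *algorithmic* chain — thresholds, contours, hole logic, curvature
scoring, the formula — not clinical accuracy.

The generator draws from R's Mersenne-Twister with inversion normals and
rejection sampling, fully specified at each call, so identical
specifications are bit-identical across platforms and sessions.

## Cohort statistics

The package reproduces the two cohort-level analyses that give ELVAR its
clinical reading, on synthetic cohorts (`generateCohort`): group-wise
ELVAR values drawn from logit-normal distributions matched to a stated
median and IQR (the defaults mirror a published two-group structure:
0.7973 [0.7458–0.8338] for early death vs 0.8685 [0.8155–0.8956] for
early survival, 16 vs 39 subjects, 12 months follow-up), with
piecewise-constant hazards per group.

* `rocAnalysis` builds the empirical ROC with candidate cutoffs at
  midpoints between consecutive distinct scores (plus sentinels), AUC by
  the trapezoid rule (ties contribute half), and the best cutoff by
  Youden's $J$; ties break toward higher specificity, then the lower
  cutoff. For ELVAR the positive (death) class sits at *low* scores, so
  `direction = "low-positive"`. The implementation is checked in the test
  suite against an exhaustive brute-force scan and against an independent
  AUC implementation.
* `kmStratify` splits at a cutoff and fits the product-limit estimator per
  stratum via the survival package, reporting the step curves and survival
  at 3 and 12 months; "mortality within 3 months" uses the closed boundary
  (event time ≤ 3.0). No confidence bands are drawn by default; log-log
  bands sit behind a flag.

## Numerical and interface choices

* **Axis convention**: arrays are (slice, row, col), slice axis
  caudo-cranial, 0-based voxel coordinates in physical computations; masks
  live on the exact source lattice, and nothing resamples implicitly.
* **HU is the only intensity unit** inside the pipeline. Lung-window
  settings affect PNG rendering only — windowing destroys densitometric
  information and is never applied to data.
* **DICOM**: loading applies `stored × slope + intercept` exactly once per
  file, sorts by physical slice position (so on-disk order is irrelevant),
  rejects mixed series, non-uniform in-plane spacing, duplicate positions,
  and gaps exceeding twice the modal spacing (non-contiguous series are
  rejected rather than interpolated). Only standard rescale tags are
  honored; vendor private tags are ignored. The bundled reader/writer
  speaks explicit-VR little-endian single-frame CT.
* **Degenerate inputs**: an empty lung mask yields $L = 0$ and an ELVAR
  result carrying an explicit undefined marker — never NaN; slices with no
  lung are marked undefined in the per-slice table but contribute nothing
  to the global ratio; $I > L$ is an upstream invariant violation and an
  error.
* **Fingerprints**: every result records a canonical hash of all
  parameters used, so reports are traceable to their settings.

## Problem sizes in the validation suite

The test suite validates segmentation accuracy and ELVAR recovery on
full-size default phantoms (40 × 128 × 128): twenty phantom/pipeline runs
spanning burdens 0–30% and organ indentation on/off, five seeds per burden
for recovery and ordering, plus consolidation-only high-burden phantoms.
Unit tests use a compact 24 × 80 × 80 phantom with proportionally reduced
component-size thresholds. The acceptance script repeats the study at four
burdens under a caller-supplied seed and adds the synthetic-cohort ROC and
Kaplan-Meier quantities.

## Known limitations

* ELVAR is a geometric voxel fraction; it does not model DLCO, FVC or any
  ventilation physiology, and "ventilation" in its name is interpretive.
* The density floor counts every dense in-lung voxel toward $I$,
  deliberately including vessels; cohorts where vascular volume varies
  independently of ILD would see that variation in ELVAR.
* The per-volume score normalization assumes at least one strong
  structure per volume (vessels guarantee this in practice); a volume with
  no structure at all normalizes trivially and scores zero everywhere.
* Multi-frame enhanced-CT DICOM, PACS networking, DICOM-SEG/RTSTRUCT
  output, lobe separation and airway-tree extraction beyond trachea
  exclusion are out of scope, as are learned segmentation models.
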