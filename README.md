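# elvarkit

Computer-aided quantification of interstitial lung disease (ILD) extent on
chest CT. The package implements the **Effective Lung Ventilation Area
Ratio**,

```
ELVAR = (L − I) / L
```

where `L` is the number of lung voxels and `I` the number of voxels
occupied by lung interstitium (septal thickening, reticulation,
ground-glass opacity, consolidation, and — by default — the pulmonary
vessels that accompany the interstitium). ELVAR lies in [0, 1]; low values
mean extensive interstitial involvement. The index was introduced for risk
stratification of rapidly progressive ILD (anti-MDA5 dermatomyositis),
where low ELVAR marks patients at high risk of early death.

The analysis chain is:

1. **ILD-robust lung segmentation** — four stages: coarse air thresholding
   with 3-D component analysis; per-slice Gaussian smoothing and Laplacian
   zero-crossing contour detection; contour filling plus "mask hole"
   elimination (organ indentations at the lung base are removed while
   vessels and dense disease are preserved); contour shrinkage onto the
   accurate lung edge. Produces `L`.
2. **Lung interstitial enhancement** — multi-scale Hessian curvature
   analysis distinguishes sheet-like interstitium and tubular vessels from
   parenchyma, with a density fallback for curvature-free dense disease
   interiors. Produces `I`.
3. **ELVAR computation and reporting**, per volume and per slice.
4. **Cohort statistics** — empirical ROC with Youden-optimal cutoff
   (low-positive direction) and Kaplan-Meier stratification at a cutoff.

Because no clinical data ship with the package, a **digital thoracic
phantom** generator provides CT volumes with voxel-exact ground-truth lung
and interstitium masks, configurable disease burden, organ indentation and
trachea; all validation runs against it. Audience: researchers in
quantitative CT / radiology informatics who want a tested, scriptable
reference implementation of the index.

## Worked example

Generate a phantom with 20% disease burden and run the full pipeline:

```r
library(elvarkit)

spec <- phantomSpec(seed = 11L, disease = list(targetFraction = 0.2))
ph   <- generatePhantom(spec)
ph$truth
#> PhantomTruth: true ELVAR = 0.7673
#>   lung voxels: 117712 ; interstitial: 27388

run <- elvarPipeline(ph$volume)
run$result
#> ElvarResult: L = 117712 , I = 27570
#>   ELVAR = (L - I)/L = 0.7658

diceCoefficient(lungMask(run$segmentation), ph$truth@lungMaskTrue)
#> [1] 1
```

The segmentation recovers the true lung essentially voxel-exactly on this
phantom, and the measured ELVAR (0.7658) reproduces the ground truth
(0.7673) to within 0.002: the small excess in `I` is the curvature halo
around lesions and vessels. `elvarReport(run$result, "report.csv")` writes
a CSV/JSON report; `renderEnhancement()` writes per-slice overlays and a
score projection.

Cohort-level stratification on a synthetic two-group cohort:

```r
tab <- generateCohort(cohortSpec(seed = 2L))
roc <- rocAnalysis(tab$elvar, tab$event_flag & tab$event_time_months <= 3,
                   direction = "low-positive")
roc
#> RocResult: AUC = 0.725 ; best cutoff = 0.809 (Youden J = 0.467 )
ks <- kmStratify(tab, roc@bestCutoff)
ks$survivalAtHorizons
#>              m3       m12
#> below 0.4444444 0.4444444
#> above 0.8648649 0.8108108
```

Subjects below the ELVAR cutoff show 44% survival at 3 months against 86%
above it — the direction the index is designed to capture.

A thin command-line front end over the same functions is installed at
`inst/cli/elvarkit.R` (subcommands `segment`, `enhance`, `elvar`,
`phantom`, `cohort`, `stratify`).

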