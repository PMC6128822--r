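---
title: "Methods: hotspot topography and TMS coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot topography and TMS coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuetopo)
```

`cuetopo` characterizes where in frontal cortex individual people show
their strongest cue-evoked BOLD response, and how well fixed scalp
locations would cover those per-person peaks for TMS delivery. This
vignette is the package's account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The block paradigm and the first-level model

The cue-exposure task is a block design: epochs of fixed length containing
alternating blocks of four conditions — Drug, Neutral, Blur (a visual
control) and Rest. The defaults encode six 120-second epochs of 24-second
blocks, a 12-minute task, with five images of 4.8 s per block. A 120-s
epoch holds five 24-s block slots but only four conditions;
`build_paradigm(epoch_fill =)` decides the fifth slot: `"repeat_rest"`
(default) pads each epoch with a second Rest block, `"cycle"` keeps
rotating the condition order across slots. Both satisfy the same
arithmetic; the choice only shifts how much implicit baseline the design
has.

The first-level model is ordinary least squares per voxel. Drug, Neutral
and Blur boxcars are convolved with the canonical double-gamma HRF
(response gamma peaking at 6 s, 1/6-amplitude undershoot peaking at 16 s,
unit dispersions, rescaled to unit peak) on a microtime grid of 16 samples
per TR, then sampled at acquisition times $i \cdot \mathrm{TR}$
($\mathrm{TR} = 2.2$ s by default). Rest is the implicit baseline, so the
Drug > Neutral comparison uses contrast weights $(+1, -1, 0)$ over the
three condition regressors. Six motion covariates and an intercept
complete the design; all-zero motion columns are dropped (and recorded) so
synthetic motion-free designs stay full rank. Two deliberate
simplifications, both documented rather than hidden: no temporal
autocorrelation model (plain OLS, where SPM-style pipelines prewhiten) and
no slice-timing model (volumes are treated as instantaneous at
$i \cdot \mathrm{TR}$). Both affect efficiency, not unbiasedness, and the
package's calibration tests confirm the voxelwise type-I error is nominal
under its own noise model.

Degenerate voxels — zero residual variance with a nonzero effect, which
noiseless synthetic data produce — would give infinite t; they are guarded
at a large finite sentinel ($10^6$) and flagged, never silently passed on.

## Cluster-extent correction

Suprathreshold voxels (one-sided, positive t, default voxel p < 0.005)
inside the analysis mask are partitioned into connected components;
face-connectivity (6 neighbours) is the default, with 18 and 26
configurable. The minimum cluster size is derived by Monte-Carlo
simulation: each null iteration smooths white Gaussian noise to the target
FWHM, re-standardizes, thresholds, labels, and records the maximum cluster
size; the extent threshold is the smallest $k$ with
$\hat{P}(\max \ge k) \le \alpha$ (default $\alpha = 0.05$, 1000
iterations). Design choices worth knowing:

* **Gaussian autocorrelation only.** The null fields have a Gaussian
  spatial ACF. Mixed/heavy-tailed ACF models used by recent AFNI versions
  are out of scope; with real data whose smoothness is estimated from
  residuals, Gaussian-ACF thresholds are known to be somewhat liberal.
* **Circular smoothing with exact re-standardization.** Null fields use
  periodic-boundary separable Gaussian convolution and are rescaled by the
  exact theoretical standard deviation of circularly smoothed white noise,
  so the null field is stationary and marginally N(0,1). This keeps the
  family-wise error calibration testable against its own definition; the
  suite verifies FWE within Monte-Carlo confidence limits of $\alpha$.
* **One-sided thresholding.** Hotspots are defined as cue-evoked
  *elevations*, so only the positive tail is clustered.
* **Mask dilation is 3D.** Atlas GUIs sometimes call the analogous setting
  a "2D" dilation; here masks are 3D volumes and `dilate_mask()` applies
  iterative 3D binary dilation with the chosen structuring element.
* The often-quoted 48-voxel extent for a full-brain 3 mm acquisition
  depends on the smoothness of that study's residuals, which cannot be
  re-derived from a desk simulation; the package treats any such number as
  a worked-example constant, and its own thresholds are always computed
  from the configured geometry.

## Hotspots

Surviving clusters are ranked by ascending empirical cluster-level p
(equivalently, descending extent under an extent-based correction), with
descending peak t and then lexicographic peak index as tie-breaks; a
peak-t ranking is available as a config alternative. Each cluster
contributes its local-maximum voxel, converted to MNI mm — the subject's
hotspot(s). Cohort point sets come in two modes: the *full complement*
(every corrected cluster from every subject) and *one per individual*
(rank-1 clusters only). Subjects with no surviving cluster are
non-responders; the assembled set records the responder count and
fraction. `max_per_subject` is unlimited by default, since multi-cluster
subjects are common and there is no principled cap.

## k-means++ topography

The clustering engine is written in the package and follows the two-phase
scheme of the classical k-means++ implementations: D²-weighted seeding,
batch Lloyd iterations to convergence (stop when assignments are stable or
the objective improves by less than $10^{-10}$ mm²), then an online phase
that moves one point per sweep whenever the exact
$\frac{n_a}{n_a-1} / \frac{n_b}{n_b+1}$-corrected change lowers the
within-cluster sum of squares, capped at 100 sweeps. Empty clusters are
repaired by re-seeding at the farthest point. The objective is asserted
non-increasing at every step. Distances are unweighted Euclidean over the
three MNI coordinates in millimetres. Each fit is restarted 1000 times
with random seeding and the lowest-wcss restart wins, ties going to the
earliest restart so results are reproducible given a seed. On separated
data the fit agrees with `stats::kmeans` (used in the tests only, as an
independent cross-check) and with exhaustive enumeration on tiny inputs.

Model selection scans k = 2–10 and maximizes the *mean per-point
silhouette* $s(i) = (b_i - a_i)/\max(a_i, b_i)$; ties go to the smaller k.
"Silhouette-based selection" underdetermines the summary statistic; the
mean over points is the common default and the per-cluster-mean
alternative changes nothing on well-separated data. Two conventions:
singleton-cluster members score 0, and coincident points ($a = b = 0$)
score 0. When even the best mean silhouette is below 0.25 the selection is
flagged `weak_structure` — a documented convention, not a test: a forced
2-split of a single isotropic Gaussian cloud scores around 0.35, so weak
but nonzero apparent structure is expected even from unclustered data, and
the flag threshold is deliberately conservative.

Cluster-composition questions (is drug group, or gender, distributed
independently of cluster membership?) use the Pearson chi-square without
continuity correction, with a warning when any expected cell count falls
below 5.

## TMS coverage

Distances from hotspots to scalp electrodes are straight-line 3D
Euclidean millimetres, not along-scalp geodesics — the quantity relevant
to field penetration depth. Coverage at radius r is the percentage of
hotspots within r of the electrode, evaluated at 20/30/40/50 mm by
default (the 2–5 cm range of rTMS effective depth across coil sizes);
"best" electrodes per radius are ties after rounding percentages to
integers, reported jointly (e.g. `FPz/FP2`), with the rounding precision
configurable. Counting is per-electrode (how many hotspots are within r of
*this* electrode); nearest-electrode attribution would partition hotspots
instead and is a different question.

The default electrode table is the standard 10-05 position set
(Oostenveld's extension of the 10-10 system) digitized on the colin27
scalp in MNI millimetres, shipped as package data with its provenance
recorded; it includes the extended 10-5 midpoint labels (AF5 and friends)
so all labels commonly reported in targeting work resolve. Label matching
is case-insensitive. Any user table with `label,x,y,z` columns can be
substituted, and reports carry the table's provenance string.

## The synthetic cohort

The generator defines the package's study conditions:

* **Coordinate level.** Hotspots are drawn from a 3-component isotropic
  Gaussian mixture at MNI (7, 50, 4), (−40, 24, 25), (30, 18, 41) with
  mixing proportions 0.40/0.32/0.28 — medial prefrontal/ACC, left lateral
  prefrontal, right lateral prefrontal. The within-component dispersion is
  not something a results table reports; the default of 12 mm (isotropic
  SD) makes components overlapping but silhouette-separable, which is the
  qualitative regime the analysis is designed for. It is config, not a
  claim about real dispersion.
* **Cohort structure.** Group sizes default to 55/53/48
  (cocaine/alcohol/nicotine) and the responder rate to 103/156 ≈ 66%, the
  bookkeeping regime the pipeline must handle. Non-responders are explicit
  records with amplitude 0. In the coordinate-level pipeline each
  responder contributes 1 + Poisson(1.53) hotspots, so the expected
  points-per-responder matches the ~2.5 clusters-per-responder regime of
  multi-cluster cohorts; again a structural choice, not an empirical
  claim.
* **Image level.** Each subject's 4D series is baseline 100 plus a
  Gaussian blob (12 mm FWHM) at the subject's true locus, scaled by
  amplitude (percent signal change) and the HRF-convolved Drug regressor,
  in spatially smoothed (8 mm FWHM, matching the common preprocessing
  kernel) temporally white Gaussian noise. Defaults: 3 mm isotropic
  voxels, TR 2.2 s, amplitude 1%, noise SD 0.5% — a single-subject peak t
  around 10, typical of a 12-minute block design after smoothing. Planted
  loci are truncated to lie a margin inside the simulated grid. The
  simulator deliberately omits scanner drift, motion, physiological noise
  and temporal autocorrelation; passing recovery tests therefore
  demonstrates the pipeline's correctness under its stated model, not
  robustness to every real-data artifact.

## Problem sizes and determinism

The package's own verification runs at desk scale: the clustering
acceptance checks use the full 261-point, 1000-restart, k = 2–10 protocol
(about 40 s); extent-threshold calibration uses 20³ grids with 1000 null
iterations; the image-level end-to-end check uses 12 subjects on a
31×26×24-voxel frontal grid with 327 volumes each. Every randomized
operation takes an explicit seed and touches no hidden global state
(`withr::with_seed` underneath); `run_pipeline()` reruns to byte-identical
reports given the same config.

## Known limitations

OLS without prewhitening; Gaussian-ACF-only extent thresholds; no
anatomical labelling of hotspots; straight-line (not scalp-geodesic)
electrode distances; the synthetic generator's simplifications listed
above. The empirical constants quoted in examples (group sizes, responder
fractions, centroid locations, coverage percentages from published
targeting tables) depend on raw clinical data no desk simulation can
reproduce; the package treats them as structural anchors for its synthetic
conditions and report formats.
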