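---
title: "Microglia morphometry and cohort statistics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microglia morphometry and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgliaMorph)
```

## The scientific problem

Chronic elevation of intraocular pressure (IOP) — ocular hypertension, the
main modifiable risk factor in glaucoma — degrades retinal ganglion cell
projections to the dorsolateral geniculate nucleus (dLGN). Microglia, the
resident immune cells, respond by changing shape: surveillant cells are
intricately ramified with many fine processes, while reactive cells retract
processes (deramify) or adopt elongated, bipolar "rod" morphologies.
This package implements the full quantitative chain used to characterise
that response from fluorescence imaging:

1. **Global skeleton analysis** of the Iba1 (microglial) channel:
   projection, contrast operators, thresholding, topology-preserving
   skeletonization, and per-cell branch-length / endpoint counts.
2. **Single-cell fractal and hull morphometry**: box-counting fractal
   dimension $D_f$ of the cell outline, and convex-hull span ratio and
   circularity.
3. **Puncta and intensity quantification**: vGluT2-style synaptic puncta
   detection and density, C1q-style peak-plane intensity, and
   count-to-density scaling.
4. **Cohort statistics**: trapezoidal AUC of longitudinal IOP (mmHg·days),
   simple regressions with slope comparison between strains, two-way and
   nested ANOVA with Šídák/Tukey pairwise tests, and fold-change/FDR
   filtering of differential-expression tables.

Because single-cell ground truth cannot be obtained from real tissue
without a human tracer, a synthetic-data module generates image fields,
pressure trajectories, cohorts and gene tables with *known* truth, so every
stage is testable end to end.

## Image operators and their parameters

All operators take calibrated containers (`ImageStack`, `Image2D`,
`BinaryMask2D`; micrometre pixel sizes). Defaults are the protocol values
used throughout:

| operator | default | role |
|---|---|---|
| `unsharpMask` | sigma 0.5 px, weight 0.6 | sharpen fine processes |
| `despeckle` | 3×3 median | impulse-noise removal |
| `thresholdGlobal` | IsoData, 22 % floor | foreground segmentation |
| `morphologicalClose` | 3×3 element | bridge eroded process gaps |
| `removeOutliers` | radius 7 px, threshold 50, dark | smooth mask noise |
| `rollingBallSubtract` | radius 10 px (puncta) / 50 px (intensity) | background estimation |
| `detectPuncta` gates | 100–7500 px, 6–100 µm², circularity 0–1 | particle filtering |

Numerical conventions, chosen once and used everywhere:

* **Edge handling** is replicate padding for every neighbourhood filter.
* **8-bit conversion** is min–max rescaling with half-up rounding; a
  constant image maps to zero (nothing to stretch).
* **"Modified IsoData, 22 %"** is ambiguous in its original tooling; here
  the classic IsoData fixed-point iteration runs on the 256-bin histogram
  and the result is floored at the 22nd intensity percentile. Both raw and
  modified thresholds are attached to the returned mask so the choice is
  auditable.
* **Rolling ball** is grayscale opening with a non-flat spherical-cap
  element. On an isolated one-pixel spike the cap rides up by
  $r-\sqrt{r^2-1}$ — a real property of the rolling ball, covered in the
  tests. The legacy shrink/enlarge approximation is not reproduced.
* **Remove Outliers** replaces a pixel only when it deviates from the disc
  median *strictly* more than the threshold; the default polarity is dark
  (the skeleton pipeline applies it to the 0/255 mask after thresholding,
  where residual noise is dark).
* `detectPuncta` uses the maximum filter (radius 2 px) only to consolidate
  fragmented puncta for detection; particle areas are measured on the
  un-dilated pixels above the same threshold, otherwise every area would
  be inflated by about two pixels of radius. At the default pixel size
  (0.3613 µm) the 100 px pixel gate corresponds to ≈13 µm², so it — not
  the 6 µm² area gate — sets the effective lower size limit.

## Skeleton morphometry

`skeletonizeMask` uses two-subiteration (Zhang–Suen) thinning plus a
staircase cleanup pass; the 8-connected component count of the input is
preserved. Thinning can leave 2×2 *junction clusters* where four branches
meet — exactly the structures ImageJ's skeleton analyser also tolerates —
so `buildSkeletonGraph` clusters adjacent junction pixels into one node and
rejects only genuinely thick input (a 3×3 solid block, or a 2×2 block
containing non-junction pixels).

Branch lengths use the 1 / $\sqrt 2$ step metric (one pixel per axial step,
$\sqrt 2$ per diagonal), the convention of the skeleton plugin this
reimplements, not sub-pixel spline length. On oblique straight lines that
metric over-measures Euclidean length by up to ~8 %, which is the dominant
term in the ~7 % aggregate branch-length error of the recovery battery.

`pruneAndSummarize` applies the two published trim rules — terminal
branches shorter than 1 µm, and connected components with fewer than two
endpoints (isolated pixels, closed loops) — evaluated jointly on the branch
table, which makes the operation independent of rule order. Only terminal
branches are length-trimmed; short internal edges are kept so trimming can
never disconnect a graph. The cell count used for per-cell averages is an
*input* (in the emulated protocol cells were counted manually through the
stack); it is never auto-detected.

## Fractal and hull morphometry

`boxCountDimension` counts occupied boxes over a geometric series of box
sizes (powers of two, from 45 % of the longest bounding-box side down to
1 px) for four grid origins at fractional offsets
$\{(0,0),(\tfrac12,0),(0,\tfrac12),(\tfrac12,\tfrac12)\}$ of the largest
box, applied as the same absolute grid translation at every scale. Per
origin, $D$ is minus the slope of $\ln N$ on $\ln \varepsilon$; the
reported $D_f$ is the mean over origins, with per-origin fits retained as
diagnostics. Two fit filters control discretization bias: the largest box
(deep in the finite-size regime) and any scale covered by fewer than eight
boxes are excluded whenever at least five scales remain. With these
choices the estimator reproduces the analytic dimensions of a straight
line (1), a filled square (2, counted as a region via the filled-mask
mode) and a depth-7 Sierpinski prefractal ($\log 3/\log 2 \approx 1.585$)
to well within ±0.05.

One honest limitation: on thin-branched cell outlines the estimator
carries 2–4 % of orientation dependence (rasterization anisotropy — a
diagonal stroke has ~$\sqrt2$ more outline pixels than an axial one). The
effect persists at 2–3× finer sampling and with a denser scale series, so
the tests assert rotation stability of $D_f$ at 5 %, while the hull
metrics below are rotation-stable to better than 2 %.

`hullMetrics` builds the convex hull of foreground pixel centres. Span
ratio is the longest hull chord divided by the extent measured orthogonal
to it (a calipers construction, not an ellipse fit, matching the verbal
definition of the source metric); circularity is the isoperimetric ratio
$4\pi A/P^2$ of the hull, 1 for a circle. Collinear input yields an `Inf`
span-ratio sentinel with a warning. Both the hull perimeter and the
outline pixel count are emitted, since published "perimeter" figures can
refer to either.

## The synthetic-data generator

The generator's job is to produce data *with the statistical structure the
analysis assumes*, under the study conditions being emulated:

* **Fields**: 370 × 370 µm at 1024 × 1024 px (0.3613 µm/px), 1 µm plane
  spacing, 40 µm z-span; ~23 cells per field, which converts to
  4200 cells/mm³ at two significant figures.
* **Cells** (`makeCell`): a stochastic process tree grown from the soma —
  trunks at jittered-regular angles (ramified microglia radiate their
  primary processes), segments of shifted-exponential length (4 µm floor
  plus an exponential tail, preserving the requested mean; arbitrarily
  short terminal segments are not biologically plausible and would sit
  below the 1 µm trim rule by construction), binary branching with the
  given probability, and growth that is *self-avoiding* at a 2.6 µm
  clearance so that dilated silhouettes of distinct processes do not fuse.
  Trunks are long enough to clear the soma. Elongation applies an
  anisotropic stretch along the cell's principal axis (rod microglia
  elongate along their existing orientation), so measured span ratio
  rises monotonically with the parameter.
  Truth polylines are rooted at the soma centre, so the recorded
  process length includes the intra-soma centerline the skeleton
  necessarily traces.
* **Rendering** (`renderField`): collision-free placement, per-cell
  contiguous z-extent, Gaussian PSF per plane, Poisson photon noise plus
  Gaussian read noise; bit-for-bit deterministic given the seed.
* **Pressure series** (`makeIOPSeries`): monthly visits from 3 months of
  age; control animals flat near 12 mmHg, hypertensive animals rising
  after ~6 months to means near 19–20 mmHg; the two eyes share the
  animal-level trajectory and visit deviations with small independent eye
  noise, so bilateral cumulative exposure (AUC) is correlated with
  $R^2 > 0.9$.
* **Cohorts** (`makeCohort`): per-animal metrics are
  `intercept + slope[strain] × AUC + noise`; zero slopes give null
  cohorts with nominal type-I behaviour downstream.
* **Gene tables** (`makeDEGTable`): exactly the requested numbers of true
  up-/down-regulated genes at the 1.5-fold / q < 0.05 criteria, with the
  remainder failing at least one criterion by construction.

What the generator does **not** emulate: process motility or any temporal
dynamics, phagocytic morphology, true 3-D branching (cells are stacked 2-D
occupancy), anisotropic PSFs, tissue autofluorescence, or the intensity
statistics of any particular microscope (per-cell signal-to-noise was
chosen for pipeline robustness, not realism — no published value
constrains it). Passing tests therefore demonstrate that the *algorithms*
recover known structure under controlled conditions, not that any
biological claim holds in real tissue.

## Statistical layer

* `aucTrapezoid` integrates pressure against actual measurement days with
  no interpolation and no baseline anchoring, starting at each animal's
  first recorded visit — the simplest faithful reading of "area under the
  curve in mmHg·days".
* `fitRegression` reports slope with 95 % CI, $R^2$, and $F$ on
  $(1, n-2)$ df; `compareSlopes` tests a common slope against separate
  slopes, $F$ on $(1, n_a+n_b-4)$ df, with the conventions $F=0, p=1$ for
  identical or exactly parallel noiseless groups.
* `twoWayAnova` fits the cell-means model with interaction; unbalanced
  designs use marginal (Type III) tests under sum-to-zero contrasts, with
  sequential SS available behind a flag. Pairwise comparisons are Šídák
  ($p_{adj} = 1-(1-p)^m$) on estimated marginal means within each level of
  the other factor; $m$ is the number of contrasts in the family and is
  carried in the result.
* `nestedAnova` treats animals as random and cells as replicates; the
  group effect is tested against the animal-within-group mean square (the
  `Error()` stratum of the underlying fit). Pairwise tests on group means
  use that same stratum, with Tukey HSD by default and Šídák as an
  alternative, since the emulated protocol cites both in different
  places; every result names the method used.
* `degFilter` applies fold-change ≥ 1.5 (inclusive) and q < 0.05
  (strict), both directions.

Degenerate inputs follow documented conventions rather than erroring where
a value is meaningful: zero residual variance gives $F=0, p=1$ for
constant data and $F=\infty, p=0$ for a perfect non-trivial fit; a t-test
on two identical constant samples returns $t=0, p=1$.

## Problem sizes and runtime

The test-suite and acceptance batteries use sizes chosen to exercise every
code path at full fidelity while staying small: 100-cell skeleton
batteries at the native pixel scale, 185 µm puncta fields, 2000-replicate
null simulations for type-I error, and 500 replicate cohorts at 40
animals per strain for slope recovery. Demonstration fields render at
reduced extent (120–185 µm) — the operators are scale-free, so nothing
but memory changes at 370 µm / 1024 px.

## Known limitations

* 2-D only: skeletonization and fractal analysis run on projections and
  traced silhouettes, as in the emulated protocol; no 3-D skeletons.
* The box-count estimator's orientation dependence on thin outlines
  (above).
* The rolling ball is exact grayscale opening; its cost grows with the
  square of the radius, so very large radii on full-resolution stacks are
  slow. Use trimmed fields or smaller radii where throughput matters.
* The nested-ANOVA pairwise comparisons assume a roughly balanced number
  of cells per animal when converting the animal-stratum mean square to
  the animal-mean scale.
* TIFF calibration metadata travels in a JSON sidecar (`<path>.json`)
  because the available TIFF writer cannot set the ImageDescription tag.
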