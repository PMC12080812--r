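# microgliaMorph

Quantitative microglia morphometry and cohort statistics for ocular
hypertension imaging studies, in R.

Chronically elevated intraocular pressure (IOP) reshapes microglia in the
visual thalamus: ramified, surveillant cells lose fine processes and can
adopt elongated, rod-like forms. This package implements the complete
measurement chain used to quantify that response and relate it to
cumulative pressure exposure:

* **Global skeleton analysis** — maximum-intensity projection, 8-bit
  conversion, unsharp masking (σ 0.5 px, weight 0.6), despeckling,
  IsoData thresholding (22 % floor), morphological closing, outlier
  removal (7 px / 50), topology-preserving skeletonization, and
  skeleton-graph extraction of per-cell branch length (µm, 1/√2 step
  metric) and endpoint counts, with the published trim rules (terminal
  branches < 1 µm; components with < 2 endpoints).
* **Single-cell fractal/hull morphometry** — box-counting fractal
  dimension *D*<sub>f</sub> (4 grid origins, largest box at 45 % of the
  silhouette side, geometric scale series), convex-hull span ratio
  (longest chord / orthogonal extent) and circularity (4πA/P²).
* **Puncta & intensity** — synaptic-puncta detection (rolling ball 10 px,
  max filter 2 px, Otsu, size gates 100–7500 px then 6–100 µm²), puncta
  density per mm², peak-plane mean intensity (rolling ball 50 px), and
  count→density scaling (cells/mm³).
* **Cohort statistics** — trapezoidal AUC(IOP) in mmHg·days, simple
  regression with full F/df/p/CI reporting, between-strain slope
  comparison, two-way (age × strain) ANOVA with Šídák pairwise tests,
  nested one-way ANOVA (cells within animals) with Tukey/Šídák, unpaired
  t-tests, and DEG filtering at fold-change ≥ 1.5, q < 0.05.
* **Synthetic data with known truth** — parametric microglia (branching
  trees, elongation, deramification), rendered noisy image stacks with
  label images, punctate terminal fields, longitudinal control vs
  hypertensive IOP trajectories with correlated eyes, cohorts with
  imposed metric–AUC slopes, and DEG tables with exact truth counts.

## Worked example

Grow a synthetic microglia, render a field, and run the skeleton pipeline:

```r
library(microgliaMorph)

cells <- lapply(1:5, function(i)
  makeCell(cellSpec(nPrimaryProcesses = 6, branchProbability = 0,
                    seed = 500 + i), labelId = i))
fs  <- fieldSpec(fieldSizeUm = c(150, 150, 12), nCells = 5,
                 backgroundLevel = 2, amplitude = 200, photonScale = 0,
                 readNoiseSd = 0, psfSigmaUm = 0.2, cellZSpanUm = 8,
                 seed = 77)
fld <- renderField(fs, cells)
runGlobalSkeletonPipeline(fld$stack, nCells = 5)
#>   n_cells total_branch_length_um n_endpoints branch_length_per_cell_um
#> 1       5               394.7508          30                  78.95016
#>   endpoints_per_cell
#> 1                  6
```

Each cell was grown with six unbranched primary processes, so six
endpoints per cell is exact recovery; the ~79 µm of centerline per cell is
the summed process length the skeleton traced. Shape metrics on one cell:

```r
tr <- makeCell(cellSpec(elongation = 3, seed = 9))
hullMetrics(tr$silhouette)[c("span_ratio", "circularity")]
#> $span_ratio
#> [1] 5.434356
#> $circularity
#> [1] 0.33826
```

An elongation-3 cell shows the rod-like signature: a high span ratio and a
hull far from circular. Cohort-level inference on synthetic animals:

```r
co <- makeCohort(cohortSpec(14, effectMap = list(
  endpoints_per_cell = list(intercept = 20,
                            slope = c(D2 = -0.003, D2control = 0),
                            noiseSd = 1.2)), seed = 21))
d2  <- co[co$strain == "D2", ]
ctl <- co[co$strain == "D2control", ]
compareSlopes(d2$auc_iop, d2$endpoints_per_cell,
              ctl$auc_iop, ctl$endpoints_per_cell)[c("f", "df2", "p")]
#> $f
#> [1] 272.1386
#> $df2
#> [1] 80
#> $p
#> [1] 1.81346e-27
```

The hypertensive strain was simulated with endpoints falling by 0.003 per
mmHg·day of cumulative exposure while controls are flat; the slope
comparison recovers that difference decisively.

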