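Package: microgliaMorph
Title: Microglia Morphometry and Cohort Statistics for Ocular Hypertension Imaging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of microglial morphology from fluorescence image
    stacks and cohort-level statistics linking morphology to cumulative
    intraocular pressure. Implements the global skeleton analysis
    (projection, sharpening, despeckling, IsoData/Otsu thresholding,
    morphological cleanup, topology-preserving skeletonization, skeleton-graph
    branch and endpoint extraction with spur trimming), single-cell fractal
    and convex-hull morphometry (box-counting fractal dimension with multiple
    grid origins, hull span ratio and circularity), synaptic-puncta detection
    and density, peak-plane intensity measurement, count-to-density scaling,
    and the statistical layer (trapezoidal AUC of longitudinal pressure
    series, simple regression with slope comparison, two-way and nested
    ANOVA with Sidak/Tukey pairwise tests, differential-expression
    filtering). A synthetic-data module generates image fields, pressure
    trajectories, cohorts and gene tables with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    igraph,
    pracma,
    car,
    emmeans,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
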