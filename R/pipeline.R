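#' Default run configuration
#'
#' One flat configuration with per-stage sections; every operator parameter
#' defaults to the established protocol value (0.5 px / 0.6 unsharp mask,
#' 22 percent IsoData floor, 7 px / 50 outlier removal, rolling-ball radii
#' 10 and 50 px, 6-100 um^2 particle gate, 1.5-fold / q < 0.05 DEG
#' criteria, 4 box-count grid origins at 45 percent largest grid size).
#'
#' @param seed master RNG seed for the run.
#' @return a nested list of class `RunConfig`.
#' @export
defaultConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = c("simulate", "stats", "deg"),
    simulate = list(
      n_per_group = 6L,
      strains = c("D2", "D2control"),
      ages = c(4, 9, 12),
      effect_map = list(
        endpoints_per_cell = list(intercept = 20, slope = list(D2 = -0.0015, D2control = 0), noiseSd = 1.5),
        branch_length_per_cell = list(intercept = 90, slope = list(D2 = -0.006, D2control = 0), noiseSd = 6),
        vglut2_density = list(intercept = 9000, slope = list(D2 = -0.6, D2control = 0), noiseSd = 450)),
      render_fields = 0L,
      cells_per_field = 5L,
      field_um = c(120, 120, 40)),
    skeleton = list(isodata_percent = 22, unsharp_sigma = 0.5,
                    unsharp_weight = 0.6, outlier_radius = 7,
                    outlier_threshold = 50),
    puncta = list(ball_radius = 10, max_filter = 2,
                  size_px = c(100, 7500), size_um2 = c(6, 100)),
    fractal = list(n_origins = 4L, max_box_fraction = 0.45),
    deg = list(n_genes = 15000L, n_up = 77L, n_down = 7L,
               fc_threshold = 1.5, q_threshold = 0.05),
    stats = list(alpha = 0.05)), class = "RunConfig")
}

#' Save / load a run configuration as YAML
#' @param config a `RunConfig` list.
#' @param path file path.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  structure(yaml::read_yaml(path), class = "RunConfig")
}

writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes the selected stages in dependency order: `simulate` builds a
#' synthetic cohort (and optionally renders image fields and runs the
#' skeleton stage on them), `stats` fits per-strain regressions of every
#' cohort metric against AUC(IOP) with follow-up slope comparisons and a
#' two-way (age x strain) ANOVA, and `deg` builds and filters a synthetic
#' gene table. All outputs are written as CSV under `outDir` together with
#' a JSON manifest (config snapshot, package version, per-file MD5 hashes,
#' accumulated warnings). Identical config + seed reproduce identical
#' outputs.
#'
#' @param config a `RunConfig` from [defaultConfig()].
#' @param outDir output directory (created if missing).
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = tempfile("run")) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  warningsSeen <- character(0)
  results <- list()
  files <- character(0)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warningsSeen <<- c(warningsSeen,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  if ("simulate" %in% config$stages) {
    results$cohort <- stage("simulate", {
      em <- lapply(config$simulate$effect_map, function(e) {
        if (is.list(e$slope)) e$slope <- unlist(e$slope)
        e
      })
      makeCohort(cohortSpec(config$simulate$n_per_group,
                            config$simulate$strains, config$simulate$ages,
                            em, seed = config$seed))
    })
    files <- c(files, writeCsv(results$cohort, file.path(outDir, "cohort.csv")))
    if (config$simulate$render_fields > 0) {
      results$fields <- stage("skeleton", {
        rows <- lapply(seq_len(config$simulate$render_fields), function(f) {
          ncell <- config$simulate$cells_per_field
          cells <- lapply(seq_len(ncell), function(i)
            makeCell(cellSpec(seed = config$seed * 1000L + f * 100L + i),
                     labelId = i))
          fs <- fieldSpec(fieldSizeUm = config$simulate$field_um,
                          nCells = ncell, seed = config$seed * 1000L + f)
          fld <- renderField(fs, cells)
          sm <- runGlobalSkeletonPipeline(fld$stack, ncell,
                                          isodataPercent = config$skeleton$isodata_percent)
          cbind(field = f, sm,
                true_endpoints_per_cell = mean(vapply(cells, `[[`, 0, "n_tips")))
        })
        do.call(rbind, rows)
      })
      files <- c(files, writeCsv(results$fields, file.path(outDir, "fields.csv")))
    }
  }

  if ("stats" %in% config$stages && !is.null(results$cohort)) {
    st <- stage("stats", {
      cohort <- results$cohort
      metrics <- intersect(names(cohort), cohortMetricNames)
      reg <- list(); slp <- list(); anv <- list()
      for (m in metrics) {
        for (s in unique(cohort$strain)) {
          sub <- cohort[cohort$strain == s, ]
          r <- fitRegression(sub$auc_iop, sub[[m]])
          reg[[paste(m, s)]] <- data.frame(metric = m, strain = s,
                                           slope = r$slope, r_squared = r$r_squared,
                                           f = r$f, df1 = r$df1, df2 = r$df2,
                                           p = r$p, n = r$n)
        }
        if (length(unique(cohort$strain)) == 2L) {
          s12 <- unique(cohort$strain)
          a <- cohort[cohort$strain == s12[1], ]
          b <- cohort[cohort$strain == s12[2], ]
          cs <- compareSlopes(a$auc_iop, a[[m]], b$auc_iop, b[[m]])
          slp[[m]] <- data.frame(metric = m, f = cs$f, df1 = cs$df1,
                                 df2 = cs$df2, p = cs$p)
        }
        aw <- twoWayAnova(cohort, m, "age", "strain")
        anv[[m]] <- cbind(metric = m, aw$effects)
      }
      list(regressions = do.call(rbind, reg),
           slope_comparisons = do.call(rbind, slp),
           anova = do.call(rbind, anv))
    })
    results <- c(results, st)
    files <- c(files,
               writeCsv(st$regressions, file.path(outDir, "regressions.csv")),
               writeCsv(st$slope_comparisons, file.path(outDir, "slope_comparisons.csv")),
               writeCsv(st$anova, file.path(outDir, "anova.csv")))
  }

  if ("deg" %in% config$stages) {
    results$deg <- stage("deg", {
      tab <- makeDEGTable(config$deg$n_genes, config$deg$n_up,
                          config$deg$n_down, seed = config$seed)
      flt <- degFilter(tab, config$deg$fc_threshold, config$deg$q_threshold)
      list(table = tab, n_up = flt$n_up, n_down = flt$n_down)
    })
    files <- c(files, writeCsv(results$deg$table, file.path(outDir, "deg.csv")),
               writeCsv(data.frame(n_up = results$deg$n_up,
                                   n_down = results$deg$n_down),
                        file.path(outDir, "deg_summary.csv")))
  }

  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("microgliaMorph")),
                   hashes = as.list(tools::md5sum(files)),
                   warnings = warningsSeen)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest, out_dir = outDir))
}
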