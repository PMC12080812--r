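#' @importFrom pracma trapz
#' @importFrom car Anova
#' @importFrom emmeans emmeans contrast
#' @importFrom stats lm aov anova coef confint pf pt ptukey qt t.test
#'   rnorm rexp rpois runif quantile setNames aggregate
NULL

#' Trapezoidal area under a longitudinal pressure series
#'
#' Integrates pressure against time (days) with the trapezoid rule; no
#' baseline subtraction, no interpolation onto a common grid. The result is
#' in mmHg*days, a summary of cumulative pressure exposure.
#'
#' @param times days of age, strictly increasing, length >= 2.
#' @param values pressures in mmHg.
#' @return AUC in mmHg*days.
#' @export
aucTrapezoid <- function(times, values) {
  if (length(times) < 2L) stop("need at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(values) != length(times)) stop("times and values differ in length")
  pracma::trapz(times, values)
}

#' Simple linear regression with full reporting
#'
#' Ordinary least squares of `y` on `x` with the F statistic on (1, n-2)
#' degrees of freedom, two-sided p, R-squared, and a 95 percent confidence
#' interval on the slope.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @param conf confidence level for the slope interval.
#' @return a list of class `RegressionResult`: `slope`, `slope_ci`,
#'   `intercept`, `r_squared`, `f`, `df1`, `df2`, `p`, `n`.
#' @export
fitRegression <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (length(y) != n) stop("x and y differ in length")
  if (stats::var(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  ssRes <- sum(stats::resid(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  if (ssRes < 1e-12 * max(ssTot, 1)) {       # exact fit: F unbounded
    f <- Inf; p <- 0
    if (ssTot < 1e-24) { f <- 0; p <- 1 }    # y constant as well
  } else {
    f <- sm$fstatistic[1]
    p <- stats::pf(f, 1, n - 2L, lower.tail = FALSE)
  }
  ci <- tryCatch(suppressWarnings(stats::confint(fit, "x", level = conf)),
                 error = function(e) c(NA, NA))
  out <- list(slope = unname(stats::coef(fit)[2]),
              slope_ci = as.numeric(ci),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              f = unname(f), df1 = 1L, df2 = n - 2L,
              p = unname(p), n = n)
  class(out) <- "RegressionResult"
  out
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("slope = %.4g [%.4g, %.4g], R^2 = %.3f, F(%d,%d) = %.4g, p = %.4g (n = %d)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$r_squared,
              x$df1, x$df2, x$f, x$p, x$n))
  invisible(x)
}

#' Compare the slopes of two simple regressions
#'
#' Tests whether two groups share a common slope by comparing the full
#' model (separate slopes and intercepts) with the reduced model (common
#' slope, separate intercepts): `F = (delta SS / 1) / MS_full` on
#' `(1, n_a + n_b - 4)` degrees of freedom, two-sided. Identical or exactly
#' parallel noiseless groups give F = 0, p = 1.
#'
#' @param xa,ya first group.
#' @param xb,yb second group.
#' @return a list with `f`, `df1`, `df2`, `p`, and the two fitted slopes.
#' @export
compareSlopes <- function(xa, ya, xb, yb) {
  fa <- fitRegression(xa, ya); fb <- fitRegression(xb, yb)
  x <- c(xa, xb); y <- c(ya, yb)
  g <- factor(rep(c("a", "b"), c(length(xa), length(xb))))
  full <- stats::lm(y ~ x * g)
  red <- stats::lm(y ~ x + g)
  ssFull <- sum(stats::resid(full)^2)
  ssRed <- sum(stats::resid(red)^2)
  df2 <- length(x) - 4L
  dSS <- ssRed - ssFull
  scale <- max(sum(y^2), 1)
  if (dSS <= 1e-12 * scale) {
    f <- 0; p <- 1
  } else if (ssFull < 1e-12 * scale) {
    f <- Inf; p <- 0
  } else {
    f <- dSS / (ssFull / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  list(f = unname(f), df1 = 1L, df2 = df2, p = unname(p),
       slope_a = fa$slope, slope_b = fb$slope)
}

#' Sidak multiple-comparison adjustment
#'
#' @param p raw p-value(s).
#' @param m number of comparisons.
#' @return adjusted p, `1 - (1 - p)^m`, capped at 1.
#' @export
sidakAdjust <- function(p, m) pmin(1 - (1 - p)^m, 1)

#' Two-way ANOVA with Sidak pairwise comparisons
#'
#' Cell-means linear model with both main effects and their interaction.
#' Unbalanced designs are handled with marginal (Type III) tests under
#' sum-to-zero contrasts (`sequential = TRUE` switches to sequential Type I
#' sums of squares). Pairwise comparisons are computed on the estimated
#' marginal means of `factorA` within each level of `factorB` (the
#' strain-within-age / age-within-strain layout of cohort figures), Sidak
#' adjusted with `m` = number of contrasts per family.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factorA,factorB factor column names (e.g. `"age"`, `"strain"`).
#' @param sequential use sequential (Type I) sums of squares instead.
#' @return a list of class `AnovaResult`: `effects` (term, F, df1, df2, p),
#'   `pairwise` (contrast, estimate, t, df, p_raw, p_adj, m), `method`.
#' @export
twoWayAnova <- function(data, response, factorA = "age", factorB = "strain",
                        sequential = FALSE) {
  df <- data.frame(y = data[[response]],
                   A = factor(data[[factorA]]), B = factor(data[[factorB]]))
  if (nlevels(df$A) < 2L || nlevels(df$B) < 2L)
    stop("each factor needs at least 2 levels")
  tabn <- table(df$A, df$B)
  if (any(tabn == 0))
    stop(sprintf("empty design cells: %s",
                 paste(apply(which(tabn == 0, arr.ind = TRUE), 1, function(i)
                   paste(rownames(tabn)[i[1]], colnames(tabn)[i[2]], sep = ":")),
                   collapse = ", ")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(y ~ A * B, data = df)
  dfRes <- fit$df.residual
  ssRes <- sum(stats::resid(fit)^2)
  degenerate <- ssRes < 1e-12 * max(sum(df$y^2), 1)
  if (degenerate) {
    # zero residual variance: constant data gives F = 0, otherwise the
    # perfect-fit convention F = Inf for terms with non-zero SS
    tab <- suppressWarnings(stats::anova(fit))
    ss <- tab$`Sum Sq`[1:3]
    eff <- data.frame(term = c(factorA, factorB, "interaction"),
                      F = ifelse(ss > 1e-12, Inf, 0), df1 = tab$Df[1:3],
                      df2 = dfRes, p = ifelse(ss > 1e-12, 0, 1))
  } else if (sequential) {
    tab <- stats::anova(fit)
    terms <- rownames(tab)[1:3]
    eff <- data.frame(term = c(factorA, factorB, "interaction"),
                      F = tab$`F value`[1:3], df1 = tab$Df[1:3],
                      df2 = dfRes, p = tab$`Pr(>F)`[1:3])
  } else {
    tab <- car::Anova(fit, type = 3)
    idx <- match(c("A", "B", "A:B"), rownames(tab))
    eff <- data.frame(term = c(factorA, factorB, "interaction"),
                      F = tab$`F value`[idx], df1 = tab$Df[idx],
                      df2 = dfRes, p = tab$`Pr(>F)`[idx])
  }
  em1 <- suppressWarnings(emmeans::emmeans(fit, "A", by = "B"))
  em2 <- suppressWarnings(emmeans::emmeans(fit, "B", by = "A"))
  mkTab <- function(em, byCol) {
    pw <- suppressWarnings(
      as.data.frame(emmeans::contrast(em, "pairwise", adjust = "sidak")))
    data.frame(contrast = paste(pw$contrast, "|", pw[[byCol]]),
               estimate = pw$estimate, t = pw$t.ratio,
               df = pw$df, p_adj = pw$p.value)
  }
  pairwise <- rbind(mkTab(em1, "B"), mkTab(em2, "A"))
  out <- list(effects = eff, pairwise = pairwise,
              method = list(ss = if (sequential) "sequential" else "type3",
                            pairwise = "sidak"))
  class(out) <- "AnovaResult"
  out
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat("ANOVA (", x$method$ss, " SS), pairwise: ", x$method$pairwise, "\n", sep = "")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Nested one-way ANOVA (cells within animals)
#'
#' One-way design with animals nested in groups and cells as replicates:
#' the group effect is tested against the animal-within-group mean square
#' (animals treated as random). Pairwise comparisons on group means use
#' that same error stratum, with Tukey HSD (default) or Sidak adjustment.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param group grouping column name.
#' @param animal animal id column name.
#' @param pairwise `"tukey"` or `"sidak"`.
#' @return a list of class `AnovaResult` with the group effect and the
#'   pairwise table.
#' @export
nestedAnova <- function(data, response, group, animal, pairwise = c("tukey", "sidak")) {
  pairwise <- match.arg(pairwise)
  df <- data.frame(y = data[[response]], g = factor(data[[group]]),
                   a = factor(paste(data[[group]], data[[animal]], sep = "/")))
  if (nlevels(df$g) < 2L) stop("need at least 2 groups")
  perGroup <- rowSums(table(df$g, df$a) > 0)
  if (any(perGroup < 2L))
    stop("need at least 2 animals per group (no denominator df otherwise)")
  fit <- stats::aov(y ~ g + Error(a), data = df)
  st <- summary(fit)[[1]][[1]]            # animal stratum: g vs animal resid
  Fg <- st["g", "F value"]
  df1 <- st["g", "Df"]; df2 <- st["Residuals", "Df"]
  msA <- st["Residuals", "Mean Sq"]
  p <- st["g", "Pr(>F)"]
  if (!("Residuals" %in% rownames(st)) || is.na(msA))
    stop("nested design is degenerate: no animal-level residual stratum")
  if (isTRUE(msA < 1e-12 * max(mean(df$y^2), 1)) &&
      isTRUE(st["g", "Mean Sq"] < 1e-12 * max(mean(df$y^2), 1))) {
    Fg <- 0; p <- 1
  }
  # pairwise on animal means with the animal-stratum error
  am <- stats::aggregate(y ~ g + a, df, mean)
  gm <- tapply(am$y, am$g, mean)
  ng <- tapply(am$y, am$g, length)
  cellsPerAnimal <- nrow(df) / nlevels(df$a)   # harmonic layout assumption
  msMeans <- msA / cellsPerAnimal              # error MS on the animal-mean scale
  lev <- names(gm)
  combs <- utils::combn(lev, 2)
  m <- ncol(combs)
  rows <- apply(combs, 2, function(pr) {
    d <- gm[pr[1]] - gm[pr[2]]
    se <- sqrt(msMeans * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
    tstat <- d / se
    praw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
    padj <- if (pairwise == "tukey")
      stats::ptukey(abs(tstat) * sqrt(2), nlevels(df$g), df2, lower.tail = FALSE)
    else sidakAdjust(praw, m)
    data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = unname(d),
               t = unname(tstat), df = df2, p_raw = unname(praw),
               p_adj = unname(padj))
  })
  out <- list(effects = data.frame(term = group, F = unname(Fg), df1 = df1,
                                   df2 = df2, p = unname(p)),
              pairwise = do.call(rbind, rows),
              method = list(ss = "nested", pairwise = pairwise, m = m))
  class(out) <- "AnovaResult"
  out
}

#' Unpaired two-sample t-test
#'
#' Two-sided pooled-variance t-test by default (`welch = TRUE` for unequal
#' variances). Degenerate input with zero variance in both groups and equal
#' means returns t = 0, p = 1 by convention.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param welch use the Welch correction.
#' @return a list with `t`, `df`, `p`, and the group means.
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  res <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("degenerate samples with unequal means")
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Differential-expression filter
#'
#' Applies the fold-change and FDR criteria: upregulated if
#' `fold_change >= fcThreshold` and `q < qThreshold`; downregulated if
#' `fold_change <= 1 / fcThreshold` and `q < qThreshold`. The fold-change
#' bound is inclusive, the q bound strict.
#'
#' @param table data.frame with columns `gene`, `fold_change`, `q`.
#' @param fcThreshold fold-change threshold (ratio, treated/control).
#' @param qThreshold FDR-adjusted significance threshold.
#' @return a list with `n_up`, `n_down`, `up_genes`, `down_genes`.
#' @export
degFilter <- function(table, fcThreshold = 1.5, qThreshold = 0.05) {
  need <- c("gene", "fold_change", "q")
  if (!all(need %in% names(table)))
    stop("table must have columns gene, fold_change, q")
  up <- table$fold_change >= fcThreshold & table$q < qThreshold
  down <- table$fold_change <= 1 / fcThreshold & table$q < qThreshold
  list(n_up = sum(up), n_down = sum(down),
       up_genes = table$gene[up], down_genes = table$gene[down])
}
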