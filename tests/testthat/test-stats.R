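test_that("aucTrapezoid integrates pressure series in mmHg*days", {
  expect_equal(aucTrapezoid(c(0, 100), c(10, 10)), 1000)
  expect_equal(aucTrapezoid(c(0, 100), c(10, 20)), 1500)
  set.seed(1)
  t <- sort(sample(1:400, 12)); v <- runif(12, 8, 25)
  brute <- sum((v[-1] + v[-12]) / 2 * diff(t))
  expect_equal(aucTrapezoid(t, v), brute)
  # additivity over a split at an interior point
  expect_equal(aucTrapezoid(t[1:6], v[1:6]) + aucTrapezoid(t[6:12], v[6:12]),
               aucTrapezoid(t, v))
  expect_error(aucTrapezoid(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(aucTrapezoid(100, 10), "2 time points")
})

test_that("fitRegression reproduces closed-form least squares", {
  r <- fitRegression(1:10, 2 * (1:10) + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  expect_equal(r$f, Inf)

  # closed-form oracle on a small fixed dataset
  x <- c(1, 2, 4, 5, 7); y <- c(2.1, 3.9, 8.3, 9.8, 14.2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  ssRes <- sum((y - a - b * x)^2)
  ssTot <- sum((y - mean(y))^2)
  fOracle <- (ssTot - ssRes) / (ssRes / 3)
  r2 <- fitRegression(x, y)
  expect_equal(r2$slope, b)
  expect_equal(r2$intercept, a)
  expect_equal(r2$r_squared, 1 - ssRes / ssTot)
  expect_equal(r2$f, fOracle)
  expect_equal(r2$df2, 3L)
  expect_equal(r2$p, pf(fOracle, 1, 3, lower.tail = FALSE))

  expect_error(fitRegression(rep(3, 5), 1:5), "constant")
  expect_error(fitRegression(1:2, 1:2), "n >= 3")
})

test_that("fitRegression holds its nominal type-I error under the null", {
  set.seed(10)
  rej <- mean(replicate(600, {
    fitRegression(runif(20), rnorm(20))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("compareSlopes tests slope equality via full/reduced models", {
  x <- 1:12; y <- 3 * x + rnorm(12, 0, 0.5)
  same <- compareSlopes(x, y, x, y)
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)

  par <- compareSlopes(x, 2 * x + 1, x, 2 * x + 9)
  expect_equal(par$f, 0)

  # brute-force residual-sum decomposition on noisy groups
  set.seed(3)
  xa <- runif(15, 0, 10); ya <- 1.5 * xa + rnorm(15)
  xb <- runif(18, 0, 10); yb <- 0.8 * xb + 2 + rnorm(18)
  got <- compareSlopes(xa, ya, xb, yb)
  rss <- function(x, y) sum(resid(lm(y ~ x))^2)
  ssFull <- rss(xa, ya) + rss(xb, yb)
  g <- c(rep(0, 15), rep(1, 18))
  ssRed <- sum(resid(lm(c(ya, yb) ~ c(xa, xb) + g))^2)
  fOracle <- (ssRed - ssFull) / (ssFull / (33 - 4))
  expect_equal(got$f, fOracle)
  expect_equal(got$df2, 29L)
  # exchanging the groups leaves the p-value unchanged
  rev <- compareSlopes(xb, yb, xa, ya)
  expect_equal(rev$p, got$p)
})

test_that("sidakAdjust applies 1 - (1 - p)^m", {
  expect_equal(sidakAdjust(0.05, 3), 0.142625)
  expect_equal(sidakAdjust(0, 5), 0)
  expect_equal(sidakAdjust(0.9, 10), 1)
})

test_that("twoWayAnova decomposes balanced designs exactly", {
  d0 <- expand.grid(age = c(4, 9, 12), strain = c("D2", "ctl"), rep = 1:4)
  d0$y <- 7
  aw0 <- twoWayAnova(d0, "y")
  expect_true(all(aw0$effects$F == 0))
  expect_true(all(aw0$effects$p == 1))

  set.seed(4)
  d <- expand.grid(age = c(4, 9, 12), strain = c("D2", "ctl"), rep = 1:5)
  d$y <- 10 + 2 * (d$age == 12) - 1.5 * (d$strain == "D2") + rnorm(nrow(d))
  aw <- twoWayAnova(d, "y")

  # brute-force SS from cell and marginal means (balanced: type III == I)
  grand <- mean(d$y)
  mAge <- tapply(d$y, d$age, mean); mStr <- tapply(d$y, d$strain, mean)
  mCell <- tapply(d$y, interaction(d$age, d$strain), mean)
  nAge <- 10; nStr <- 15; nCell <- 5
  ssA <- nAge * sum((mAge - grand)^2)
  ssB <- nStr * sum((mStr - grand)^2)
  ssCell <- nCell * sum((mCell - grand)^2)
  ssAB <- ssCell - ssA - ssB
  ssTot <- sum((d$y - grand)^2)
  ssRes <- ssTot - ssCell
  dfRes <- nrow(d) - 6
  expect_equal(aw$effects$F[aw$effects$term == "age"],
               (ssA / 2) / (ssRes / dfRes))
  expect_equal(aw$effects$F[aw$effects$term == "strain"],
               (ssB / 1) / (ssRes / dfRes))
  expect_equal(aw$effects$F[aw$effects$term == "interaction"],
               (ssAB / 2) / (ssRes / dfRes))
  # conservation of total SS in the balanced decomposition
  expect_equal(ssA + ssB + ssAB + ssRes, ssTot)

  expect_error(twoWayAnova(d[d$age != 4 | d$strain != "D2", ], "y"),
               "empty design cells")
})

test_that("nestedAnova tests groups against between-animal variation", {
  # collapse property: cells identical within animal, balanced design
  d <- expand.grid(g = c("a", "b"), an = 1:4, cell = 1:5)
  animalMeans <- c(a1 = 3.1, a2 = 4.5, a3 = 2.8, a4 = 3.9,
                   b1 = 5.0, b2 = 6.2, b3 = 5.8, b4 = 4.9)
  d$y <- animalMeans[paste0(d$g, d$an)]
  na <- nestedAnova(d, "y", "g", "an")
  am <- aggregate(y ~ g + an, d, mean)
  ow <- summary(aov(y ~ g, am))[[1]]
  expect_equal(na$effects$F, ow["g", "F value"])
  expect_equal(na$effects$df2, ow["Residuals", "Df"])

  # worked 2 x 3 x 4 design against the textbook nested SS oracle
  set.seed(6)
  d2 <- expand.grid(g = c("lo", "hi"), an = 1:3, cell = 1:4)
  d2$y <- 10 + 3 * (d2$g == "hi") + rnorm(nrow(d2), 0,
                                          0.8)[as.integer(interaction(d2$g, d2$an))] +
    rnorm(nrow(d2), 0, 0.4)
  na2 <- nestedAnova(d2, "y", "g", "an")
  oracle <- bruteNestedF(d2$y, d2$g, d2$an)
  expect_equal(na2$effects$F, oracle$F)
  expect_equal(na2$effects$df1, oracle$df1)
  expect_equal(na2$effects$df2, oracle$df2)
  expect_equal(na2$effects$p, oracle$p)

  # Tukey and Sidak pairwise tables carry adjusted p >= raw p
  naT <- nestedAnova(d2, "y", "g", "an", pairwise = "tukey")
  naS <- nestedAnova(d2, "y", "g", "an", pairwise = "sidak")
  expect_true(all(naS$pairwise$p_adj >= naS$pairwise$p_raw - 1e-12))
  expect_true(all(naT$pairwise$p_adj >= 0 & naT$pairwise$p_adj <= 1))

  expect_error(nestedAnova(d2[d2$an == 1 | d2$g == "hi", ], "y", "g", "an"),
               "2 animals")
})

test_that("nestedAnova holds its type-I error under label permutation", {
  set.seed(11)
  d <- expand.grid(g = c("a", "b", "c"), an = 1:3, cell = 1:4)
  rej <- mean(replicate(400, {
    d$y <- rnorm(9, sd = 1)[as.integer(interaction(d$g, d$an))] +
      rnorm(nrow(d), 0, 0.5)
    nestedAnova(d, "y", "g", "an")$effects$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("unpairedTTest matches the closed-form pooled t", {
  a <- c(5, 5); b <- c(5, 5)
  same <- unpairedTTest(a, b)
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  a <- c(30.2, 28.9, 31.4, 29.8, 30.6); b <- c(32.0, 33.1, 31.2, 32.8)
  got <- unpairedTTest(a, b)
  sp2 <- ((4 * var(a)) + (3 * var(b))) / 7
  tOracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(got$t, tOracle)
  expect_equal(got$df, 7)
  expect_equal(got$p, 2 * pt(abs(tOracle), 7, lower.tail = FALSE))

  set.seed(12)
  rej <- mean(replicate(600, unpairedTTest(rnorm(8), rnorm(8))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("degFilter applies the inclusive-FC, strict-q criteria", {
  tab <- makeDEGTable(2000, 77, 7, seed = 9)
  got <- degFilter(tab)
  expect_equal(got$n_up, 77)
  expect_equal(got$n_down, 7)
  # one-line brute-force scan agrees
  expect_equal(got$n_up, sum(tab$fold_change >= 1.5 & tab$q < 0.05))
  expect_equal(got$n_down, sum(tab$fold_change <= 1 / 1.5 & tab$q < 0.05))

  empty <- data.frame(gene = character(), fold_change = numeric(), q = numeric())
  expect_equal(degFilter(empty)$n_up, 0)

  edge <- data.frame(gene = c("a", "b", "c"),
                     fold_change = c(1.5, 1.5, 1 / 1.5),
                     q = c(0.049, 0.05, 0.0499))
  ge <- degFilter(edge)
  expect_equal(ge$up_genes, "a")      # fc = 1.5 inclusive, q = 0.05 excluded
  expect_equal(ge$down_genes, "c")
  expect_error(degFilter(data.frame(gene = "x")), "columns")
})
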