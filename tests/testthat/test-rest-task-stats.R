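test_that("percent change follows the printed formula", {
  expect_identical(percentChange(2, 3), 50)
  expect_identical(percentChange(2, 2), 0)
  expect_identical(percentChange(4, 3), -25)
  expect_warning(out <- percentChange(c(1, 0, -1), c(2, 2, 2)), "<= 0")
  expect_identical(is.na(out), c(FALSE, TRUE, TRUE))
  # algebraic identity pc(r, t) + 100 = 100 t / r
  withr::with_seed(60, {
    r <- runif(200, 0.1, 5); t <- runif(200, 0.1, 5)
    expect_equal(percentChange(r, t) + 100, 100 * t / r)
  })
})

test_that("variability-change correlation handles monotone identities", {
  s <- data.frame(rest_sd = 1:10, pct_change = (1:10)^2)
  expect_equal(variabilityChangeCorrelation(s)$rho, 1)
  s$pct_change <- -s$pct_change
  out <- variabilityChangeCorrelation(s)
  expect_equal(out$rho, -1)
  expect_identical(out$df, 8)
  expect_error(spearmanCor(rep(1, 5), rep(2, 5)), "all-tied")
})

test_that("spearman p matches the reference t-approximation", {
  withr::with_seed(61, {
    x <- rnorm(40); y <- x + rnorm(40, sd = 2)
    mine <- spearmanCor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  })
})

test_that("group comparison matches the reference Wilcoxon and bounds effects", {
  withr::with_seed(62, {
    a <- rnorm(60, 1); b <- rnorm(50)
    mine <- compareGroups(a, b)
    ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

    ap <- rnorm(40, 0.5); bp <- rnorm(40)
    minep <- compareGroups(ap, bp, paired = TRUE)
    refp <- wilcox.test(ap, bp, paired = TRUE, correct = TRUE, exact = FALSE)
    expect_equal(minep$p, refp$p.value, tolerance = 1e-10)
  })
})

test_that("group comparison effect sizes behave as designed", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  same <- compareGroups(x, x, paired = TRUE)
  expect_identical(same$z, 0)
  expect_identical(same$effect_r, 0)
  expect_identical(same$p, 1)

  # complete separation: rank-biserial = 1
  sep <- suppressWarnings(compareGroups(11:18, 1:8))
  expect_identical(sep$effect_r, 1)

  withr::with_seed(63, {
    a <- rnorm(200, 2); b <- rnorm(200)
    big <- compareGroups(a, b)
    expect_lt(big$p, 0.001)
    expect_gt(big$effect_r, 0.5)
    # antisymmetry
    rev <- compareGroups(b, a)
    expect_equal(rev$z, -big$z)
    expect_equal(rev$effect_r, -big$effect_r)
    # z-normalized variant is bounded differently but shares sign
    zv <- compareGroups(a, b, effect = "z-normalized")
    expect_gt(zv$effect_r, 0)
  })
  expect_error(compareGroups(numeric(), 1:5), "empty")
})

test_that("MAD screening removes gross outliers and degrades gracefully", {
  out <- removeOutliersMAD(c(1, 2, 3, 4, 100))
  expect_identical(out$values, c(1, 2, 3, 4))
  expect_identical(out$mask, c(rep(TRUE, 4), FALSE))

  withr::with_seed(64, {
    clean <- rnorm(50)
    expect_true(all(removeOutliersMAD(clean, k = 5)$mask))
  })
  expect_warning(deg <- removeOutliersMAD(rep(7, 10)), "zero")
  expect_identical(deg$values, rep(7, 10))
  expect_error(removeOutliersMAD(c(1, 2)), "at least 3")
})

test_that("Holm correction steps down and never decreases p", {
  expect_identical(holmCorrect(0.03), 0.03)
  expect_equal(holmCorrect(c(0.01, 0.04)), c(0.02, 0.04))
  expect_identical(holmCorrect(rep(1, 4)), rep(1, 4))
  withr::with_seed(65, {
    p <- runif(30)
    expect_true(all(holmCorrect(p) >= p))
  })
  expect_error(holmCorrect(c(0.1, 1.2)), "0, 1")
})

test_that("Clogg comparison is calibrated for nested regressions", {
  eq <- cloggCompare(0.8, 0.1, 0.8, 0.12)
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)

  one <- cloggCompare(0.5, 0.1, 0.5 - sqrt(0.12^2 - 0.1^2), 0.12)
  expect_equal(one$z, 1)
  expect_equal(one$p, 2 * pnorm(-1), tolerance = 1e-12)
  expect_error(cloggCompare(0.5, 0.2, 0.4, 0.1), "non-positive")

  # null simulation: an added covariate independent of predictor and
  # outcome rarely shifts the coefficient
  withr::with_seed(66, {
    hits <- 0L
    for (i in 1:10) {
      n <- 2000
      x <- rnorm(n)
      ylat <- plogis(0.8 * x)
      y <- rbinom(n, 1, ylat)
      z <- rnorm(n)
      f1 <- summary(glm(y ~ x, family = binomial))$coefficients
      f2 <- summary(glm(y ~ x + z, family = binomial))$coefficients
      res <- tryCatch(cloggCompare(f1["x", 1], f1["x", 2],
                                   f2["x", 1], f2["x", 2]),
                      error = function(e) list(p = 0))
      if (res$p > 0.05) hits <- hits + 1L
    }
    expect_gte(hits, 8L)
  })
})

test_that("full pipeline recovers positive change and negative modulation", {
  ens <- genRestTaskEnsemble(nChannels = 40, restDur = 300, taskDur = 300,
                             seed = 67)
  tab <- windowedINT(ens$recording)
  smry <- restTaskSummary(tab)
  expect_gt(mean(smry$pct_change > 0), 0.95)
  ok <- tab$converged
  cmp <- compareGroups(tab$tau_s[ok & tab$state == "task"],
                       tab$tau_s[ok & tab$state == "rest"])
  expect_lt(cmp$p, 0.001)
  vc <- variabilityChangeCorrelation(smry)
  expect_lt(vc$rho, 0)
  expect_lt(vc$p, 0.01)
})
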