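test_that("ACF normalization gives r0 = 1 and bounded values", {
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rnorm(100) + sin(seq_len(100) / runif(1, 2, 20))
      a <- computeACF(x, maxLag = 50)
      expect_identical(acfValues(a)[1], 1)
      expect_true(all(abs(acfValues(a)) <= 1 + 1e-12))
    }
  })
  expect_error(computeACF(rep(2, 50), maxLag = 10), "constant")
  expect_error(computeACF(rnorm(10), maxLag = 10), "maxLag")
})

test_that("FFT and direct-summation ACF agree to 1e-10", {
  withr::with_seed(12, {
    for (i in 1:25) {
      n <- sample(50:400, 1)
      x <- as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.9)), n))
      mf <- acfValues(computeACF(x, maxLag = floor(n / 2), method = "fft"))
      md <- acfValues(computeACF(x, maxLag = floor(n / 2), method = "direct"))
      expect_lt(max(abs(mf - md)), 1e-10)
    }
  })
})

test_that("ACF of a long AR(1) with phi = 0.9 has r1 near 0.9", {
  x <- genOUSeries(tau = -1 / log(0.9), fs = 1, duration = 10000, seed = 13)
  a <- computeACF(x, maxLag = 10, fs = 1, method = "direct")
  expect_equal(acfValues(a)[2], 0.9, tolerance = 0.02)
})

test_that("a perfect exponential ACF is recovered exactly", {
  lags <- 0:100
  a <- new("ACFEstimate", lags = as.integer(lags),
           acf = exp(-lags / 10), fs = 20)
  fit <- fitTau(a)
  expect_true(fit$converged)
  expect_equal(fit$tauSamples, 10, tolerance = 1e-3)
  expect_equal(fit$tau, 10 / 20, tolerance = 1e-3)
  # the lag at which the fitted curve reaches 1/e equals tau
  expect_equal(exp(-fit$tauSamples / 10), 1 / exp(1), tolerance = 1e-3)
})

test_that("tau recovery is accurate and rank-monotone on OU ground truth", {
  taus <- c(0.1, 0.2, 0.4, 0.8)
  med <- vapply(seq_along(taus), function(i) {
    median(ouTauEstimates(taus[i], nwin = 60, seed = 20 + i), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(med) > 0))
  expect_lt(abs(med[2] / 0.2 - 1), 0.25)
})

test_that("tau and ACW-0 rank together on OU ensembles", {
  withr::with_seed(30, {
    taus <- runif(25, 0.1, 0.8)
    est <- t(vapply(taus, function(tt) {
      x <- genOUSeries(tt, fs = 20, duration = 200, seed = NULL)
      a <- computeACF(x, fs = 20)
      c(fitTau(a)$tau, computeACW0(a))
    }, c(0, 0)))
    ok <- complete.cases(est)
    expect_gt(cor(rank(est[ok, 1]), rank(est[ok, 2])), 0.5)
  })
})

test_that("ACW-0 finds the interpolated first zero crossing", {
  fs <- 100; T <- 1                       # 1-s period cosine
  x <- cos(2 * pi * seq(0, 20, by = 1 / fs))
  a <- computeACF(x, maxLag = 200, fs = fs)
  expect_equal(computeACW0(a), T / 4, tolerance = 0.02)

  # strictly positive ACF: undefined
  mono <- new("ACFEstimate", lags = 0:10, acf = exp(-(0:10) / 50), fs = 1)
  expect_true(is.na(computeACW0(mono)))

  # white noise decorrelates within ~2 samples
  withr::with_seed(31, {
    w <- vapply(1:20, function(i)
      computeACW0(computeACF(rnorm(500), maxLag = 250, fs = 20)), 0)
    expect_lt(median(w, na.rm = TRUE), 2 / 20)
  })
})

test_that("windowed estimation yields one row per channel per full window", {
  rec <- genStateRecording(data.frame(state = "rest", duration = 470),
                           list(rest = 0.05), nChannels = 1, fs = 500,
                           seed = 40)
  tab <- windowedINT(rec)
  expect_identical(nrow(tab), 47L)
  expect_identical(unique(diff(tab$start_s)), 10)

  short <- Recording(matrix(rnorm(198 * 2), ncol = 2), fs = 20)
  expect_identical(nrow(windowedINT(short)), 0L)   # 9.9 s: dropped
  exact <- Recording(matrix(rnorm(200 * 2), ncol = 2), fs = 20)
  expect_identical(nrow(windowedINT(exact)), 2L)   # 1 window x 2 channels
})

test_that("windowed estimation respects segment tables and labels", {
  sched <- data.frame(state = c("rest", "task"), duration = c(15, 15))
  rec <- genStateRecording(sched, list(rest = 0.2, task = 0.4),
                           nChannels = 2, fs = 20, seed = 41)
  tab <- windowedINT(rec)
  expect_setequal(unique(tab$state), c("rest", "mixed", "task"))
  segs <- data.frame(state = c("a", "b"), start_s = c(0, 16), end_s = c(10, 26))
  tseg <- windowedINT(rec, segments = segs)
  expect_identical(nrow(tseg), 4L)
  expect_setequal(unique(tseg$state), c("a", "b"))
})

test_that("band power matches Parseval on a pure sine and is additive", {
  fs <- 500
  x <- 2 * sin(2 * pi * 10 * seq(0, 20, by = 1 / fs))
  bp <- bandPower(x, fs)
  expect_equal(unname(bp["alpha"]), 2^2 / 2, tolerance = 0.01)
  expect_equal(unname(bp["broadband"]), 2^2 / 2, tolerance = 0.01)
  expect_lt(bp["beta"], 0.01)

  withr::with_seed(50, {
    w <- rnorm(5000)
    bw <- bandPower(w, fs)
    subsum <- sum(bw[c("theta", "delta", "alpha", "beta", "gamma")])
    expect_lte(subsum, bw[["broadband"]] * 1.02)  # gaps at 7-8, 12-13 Hz
    expect_gt(subsum, bw[["broadband"]] * 0.8)
    expect_true(all(bw[["broadband"]] >= bw[names(bw) != "broadband"]))
  })

  expect_identical(unname(bandPower(rep(0, 100), fs = 100)), rep(0, 6))
  expect_error(bandPower(rnorm(100), fs = 60), "Nyquist")
})
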