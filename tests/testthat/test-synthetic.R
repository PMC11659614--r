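test_that("OU generator has the exact AR(1) autocorrelation and SD", {
  fs <- 20
  x <- genOUSeries(tau = 0.5, sigma = 1, fs = fs, duration = 10000, seed = 1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, exp(-1 / (fs * 0.5)), tolerance = 0.01)
  expect_equal(sd(x), 1, tolerance = 0.02)

  # convergence of the AR(1) coefficient for other timescales
  for (tt in c(0.1, 0.8)) {
    y <- genOUSeries(tt, fs = fs, duration = 10000, seed = 2)
    expect_equal(cor(y[-1], y[-length(y)]), exp(-1 / (fs * tt)),
                 tolerance = 0.01)
  }
})

test_that("OU generator is deterministic under a seed and validates input", {
  expect_identical(genOUSeries(0.3, fs = 20, duration = 5, seed = 9),
                   genOUSeries(0.3, fs = 20, duration = 5, seed = 9))
  expect_error(genOUSeries(-1, fs = 20, duration = 5), "tau")
  expect_error(genOUSeries(0.3, fs = 0, duration = 5), "fs")
  expect_error(genOUSeries(0.3, fs = 20, duration = 0), "duration")
})

test_that("state recordings switch timescale with state and label exactly", {
  sched <- data.frame(state = c("rest", "task"), duration = c(100, 100))
  rec <- genStateRecording(sched, list(rest = 0.3, task = 0.6),
                           nChannels = 50, fs = 20, seed = 3)
  labs <- stateLabels(rec)
  expect_length(labs, nSamples(rec))
  expect_identical(unname(table(labs)["rest"]), 100L * 20L)
  expect_identical(labs[1:2000], rep("rest", 2000))

  tab <- windowedINT(rec)
  ok <- tab$converged
  cmp <- compareGroups(tab$tau_s[ok & tab$state == "task"],
                       tab$tau_s[ok & tab$state == "rest"])
  expect_gt(cmp$z, 3)
  expect_lt(cmp$p, 0.001)
})

test_that("state recording rejects degenerate requests", {
  sched <- data.frame(state = "rest", duration = 10)
  one <- genStateRecording(sched, list(rest = 0.3), nChannels = 2, seed = 1)
  expect_identical(unique(stateLabels(one)), "rest")
  expect_error(genStateRecording(sched, list(run = 0.3), nChannels = 2),
               "without a timescale")
  expect_error(genStateRecording(sched, list(rest = 0.3), nChannels = 0),
               "nChannels")
})

test_that("wheel-velocity traces have the requested bout structure", {
  fs <- 20
  v <- canonicalBoutTrace(fs)
  expect_length(v, 170 * fs)
  expect_equal(mean(abs(v[(70 * fs + 1):(100 * fs)])), 3)
  expect_true(all(v[1:(70 * fs)] == 0))

  # zero run duration: all rest, no locomotion-class segments
  v0 <- genWheelVelocity(data.frame(preRest = 30, runDuration = 0,
                                    postRest = 30, runSpeed = 3,
                                    noiseSd = 0), fs = fs)
  expect_identical(nrow(segmentBehavior(v0, fs)), 0L)

  # two qualifying bouts separated by long rest: two locomotion windows
  b <- data.frame(preRest = c(70, 30), runDuration = 30, postRest = c(70, 70),
                  runSpeed = 3, noiseSd = 0)
  segs <- segmentBehavior(genWheelVelocity(b, fs = fs), fs)
  expect_identical(sum(segs$state == "locomotion"), 2L)
})

test_that("synthetic connectomes are nonnegative, zero-diagonal, heavy-tailed", {
  con <- genConnectome(40, density = 1, seed = 4)
  W <- couplingMatrix(con)
  expect_identical(dim(W), c(40L, 40L))
  expect_true(all(diag(W) == 0))
  off <- W[row(W) != col(W)]
  expect_true(all(off > 0))
  expect_identical(W, t(W))
  # lognormal weights are right-skewed
  skew <- mean((off - mean(off))^3) / sd(off)^3
  expect_gt(skew, 0)

  sp <- genConnectome(40, density = 0.3, symmetric = FALSE, seed = 5)
  offs <- couplingMatrix(sp)[row(couplingMatrix(sp)) != col(couplingMatrix(sp))]
  expect_equal(mean(offs > 0), 0.3, tolerance = 0.05)
  expect_error(genConnectome(40, density = 0), "density")
  expect_error(genConnectome(1), "nRegions")
})

test_that("connectome weight distribution is stable across seeds", {
  s1 <- couplingMatrix(genConnectome(60, seed = 1))
  s2 <- couplingMatrix(genConnectome(60, seed = 2))
  o1 <- s1[row(s1) != col(s1)]; o2 <- s2[row(s2) != col(s2)]
  expect_equal(mean(o1), mean(o2), tolerance = 0.1)
  expect_equal(median(o1), median(o2), tolerance = 0.1)
})

test_that("rest-task ensemble couples variability negatively to change", {
  ens <- genRestTaskEnsemble(nChannels = 30, restDur = 100, taskDur = 100,
                             seed = 6)
  expect_true(all(ens$truePct > 0))
  expect_lt(cor(rank(ens$tauRest), rank(ens$truePct)), 0)
  expect_identical(nChannels(ens$recording), 30L)
})
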