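# Shared fixture builders; everything is generated in code.

# one qualifying bout: 70 s rest, 30 s run, 70 s rest, noiseless
canonicalBoutTrace <- function(fs = 20, runSpeed = 3) {
  genWheelVelocity(data.frame(preRest = 70, runDuration = 30, postRest = 70,
                              runSpeed = runSpeed, noiseSd = 0), fs = fs)
}

# windowed tau estimates over nwin non-overlapping 10-s windows of an OU
# process with known timescale
ouTauEstimates <- function(tau, nwin, fs = 20, seed = 1) {
  x <- genOUSeries(tau, fs = fs, duration = nwin * 10, seed = seed)
  wlen <- 10 * fs
  vapply(seq_len(nwin), function(w) {
    seg <- x[((w - 1) * wlen + 1):(w * wlen)]
    fitTau(computeACF(seg, fs = fs))$tau
  }, 0)
}

# two well-separated Gaussian classes in d dimensions
separableClasses <- function(n, d = 10, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n / 2 * d), ncol = d),
               matrix(rnorm(n / 2 * d, mean = gap), ncol = d))
    list(x = x, y = factor(rep(c("a", "b"), each = n / 2)))
  })
}

smallScaledConnectome <- function(n = 30, wii = 1, seed = 7) {
  setRecurrent(scaleOffdiagonal(genConnectome(n, seed = seed)), wii)
}
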