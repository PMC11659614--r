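#' Generate an Ornstein-Uhlenbeck time series
#'
#' Discrete-time OU process sampled at `fs` Hz using the exact AR(1)
#' update `x[t+1] = phi * x[t] + eps`, with `phi = exp(-1/(fs*tau))` and
#' innovation variance `sigma^2 * (1 - phi^2)`, so the autocorrelation at
#' lag `l` samples is exactly `exp(-l/(fs*tau))` and the stationary SD is
#' `sigma`. This is the ground-truth process for timescale-recovery tests:
#' its intrinsic timescale is `tau` by construction.
#'
#' @param tau decay timescale in seconds (> 0).
#' @param sigma stationary standard deviation.
#' @param fs sampling rate in Hz.
#' @param duration length in seconds; `duration * fs` must round to a
#'   positive integer sample count.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return numeric vector of `duration * fs` samples.
#' @examples
#' x <- genOUSeries(tau = 0.5, fs = 20, duration = 60, seed = 1)
#' @export
genOUSeries <- function(tau, sigma = 1, fs = 20, duration = 60, seed = NULL) {
  stopifnot_scalar_pos(tau, "tau")
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(duration, "duration")
  n <- round(duration * fs)
  if (n < 1) stop("'duration * fs' must be a positive sample count")
  phi <- exp(-1 / (fs * tau))
  withSeed(seed, {
    x0 <- rnorm(1L, 0, sigma)
    e <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
  })
}

# continue an OU stream from a given state (internal; keeps channels
# continuous across state switches in genStateRecording)
ouSegment <- function(n, phi, sigma, init) {
  e <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive", init = init))
}

#' Generate a state-dependent multichannel OU recording
#'
#' Each channel is an OU process whose decay timescale switches with the
#' behavioral state according to `schedule`; per-sample labels align
#' sample-exactly with the schedule. This emulates recordings in which
#' neural timescales are longer during behavioral states than at rest,
#' with the state-wise timescales known exactly.
#'
#' @param schedule data.frame with columns `state` and `duration`
#'   (seconds), or a list of `(state, duration)` pairs.
#' @param tauByState named list/vector mapping each state to its timescale
#'   in seconds; an entry may be a scalar (shared by all channels) or a
#'   vector of length `nChannels` (per-channel ground truth).
#' @param nChannels number of channels (>= 1).
#' @param fs sampling rate in Hz.
#' @param sigma stationary SD of every channel.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A [Recording-class] with per-sample state labels.
#' @examples
#' sched <- data.frame(state = c("rest", "task"), duration = c(100, 100))
#' rec <- genStateRecording(sched, list(rest = 0.3, task = 0.6),
#'                          nChannels = 4, fs = 20, seed = 1)
#' @export
genStateRecording <- function(schedule, tauByState, nChannels = 10,
                              fs = 20, sigma = 1, seed = NULL) {
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- data.frame(
      state = vapply(schedule, function(s) as.character(s[[1]]), ""),
      duration = vapply(schedule, function(s) as.numeric(s[[2]]), 0))
  if (nChannels < 1) stop("'nChannels' must be >= 1")
  missing <- setdiff(schedule$state, names(tauByState))
  if (length(missing))
    stop("states in schedule without a timescale: ",
         paste(missing, collapse = ", "))
  taus <- lapply(tauByState, function(tv) {
    tv <- as.numeric(tv)
    if (any(tv <= 0)) stop("all timescales must be > 0")
    rep_len(tv, nChannels)
  })
  nseg <- round(schedule$duration * fs)
  if (any(nseg < 1)) stop("every schedule entry must span >= 1 sample")
  labels <- rep(schedule$state, nseg)
  ntot <- sum(nseg)
  withSeed(seed, {
    sig <- matrix(0, ntot, nChannels)
    for (ch in seq_len(nChannels)) {
      xlast <- rnorm(1L, 0, sigma)
      pos <- 0L
      for (k in seq_len(nrow(schedule))) {
        phi <- exp(-1 / (fs * taus[[schedule$state[k]]][ch]))
        seg <- ouSegment(nseg[k], phi, sigma, xlast)
        sig[pos + seq_len(nseg[k]), ch] <- seg
        xlast <- seg[nseg[k]]
        pos <- pos + nseg[k]
      }
    }
    Recording(sig, fs = fs, labels = labels)
  })
}

#' Generate a rest/task recording with built-in variability--change coupling
#'
#' Convenience ensemble mirroring the empirical rest-task design: channels
#' get heterogeneous resting timescales (log-uniform on
#' `[tauRange[1], tauRange[2]]`) and each channel's task timescale is
#' `tauRest * (1 + pc/100)` with percent change
#' `pc = changeBase * median(tauRest) / tauRest`. Because the
#' across-window variability of the windowed tau estimator grows with the
#' underlying timescale, this construction yields a positive rest-to-task
#' change in every channel together with a negative correlation between
#' resting-state tau variability and percent change -- the rest-task
#' modulation structure the statistics module is designed to detect.
#'
#' @param nChannels number of channels.
#' @param restDur,taskDur rest and task durations in seconds.
#' @param tauRange range of resting timescales in seconds.
#' @param changeBase percent change assigned to the channel whose resting
#'   timescale equals the ensemble median.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return list with `recording` (a [Recording-class]), `tauRest`,
#'   `tauTask`, and `truePct` (per-channel ground truth).
#' @export
genRestTaskEnsemble <- function(nChannels = 50, restDur = 400, taskDur = 400,
                                tauRange = c(0.15, 0.6), changeBase = 60,
                                fs = 20, seed = NULL) {
  withSeed(seed, {
    tauRest <- exp(runif(nChannels, log(tauRange[1]), log(tauRange[2])))
    pc <- changeBase * median(tauRest) / tauRest
    tauTask <- tauRest * (1 + pc / 100)
    sched <- data.frame(state = c("rest", "task"),
                        duration = c(restDur, taskDur))
    rec <- genStateRecording(sched, list(rest = tauRest, task = tauTask),
                             nChannels = nChannels, fs = fs, seed = NULL)
    list(recording = rec, tauRest = tauRest, tauTask = tauTask, truePct = pc)
  })
}

#' Generate a bout-structured wheel-velocity trace
#'
#' Concatenates, for each bout, a pre-rest epoch (zero mean), a running
#' epoch (mean absolute velocity `runSpeed`) and a post-rest epoch, all
#' with additive Gaussian noise of SD `noiseSd`. A bout is a list or
#' one-row data.frame with fields `preRest`, `runDuration`, `postRest`
#' (seconds), `runSpeed`, `noiseSd`.
#'
#' @param bouts data.frame (one row per bout) or list of lists with the
#'   fields above.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return numeric velocity vector.
#' @examples
#' v <- genWheelVelocity(data.frame(preRest = 70, runDuration = 30,
#'                                  postRest = 70, runSpeed = 3,
#'                                  noiseSd = 0), fs = 20)
#' @export
genWheelVelocity <- function(bouts, fs = 20, seed = NULL) {
  if (is.list(bouts) && !is.data.frame(bouts))
    bouts <- do.call(rbind, lapply(bouts, as.data.frame))
  if (nrow(bouts) == 0) stop("'bouts' must be non-empty")
  need <- c("preRest", "runDuration", "postRest", "runSpeed", "noiseSd")
  if (!all(need %in% names(bouts)))
    stop("bouts need fields: ", paste(need, collapse = ", "))
  if (any(bouts$preRest < 0 | bouts$runDuration < 0 | bouts$postRest < 0))
    stop("durations must be >= 0")
  withSeed(seed, {
    segs <- lapply(seq_len(nrow(bouts)), function(k) {
      b <- bouts[k, ]
      npre <- round(b$preRest * fs)
      nrun <- round(b$runDuration * fs)
      npost <- round(b$postRest * fs)
      c(rnorm(npre, 0, b$noiseSd),
        b$runSpeed + rnorm(nrun, 0, b$noiseSd),
        rnorm(npost, 0, b$noiseSd))
    })
    unlist(segs)
  })
}

#' Generate a synthetic structural connectome
#'
#' Random nonnegative, zero-diagonal coupling matrix standing in for an
#' averaged DTI connectivity matrix: heavy-tailed (lognormal by default)
#' off-diagonal weights at a given density, optionally symmetric. The
#' recurrent (diagonal) strength is set separately with [setRecurrent()]
#' and the off-diagonal scale with [scaleOffdiagonal()].
#'
#' @param nRegions number of regions (>= 2).
#' @param density fraction of nonzero off-diagonal entries, in (0, 1].
#' @param weightLaw `"lognormal"` (meanlog `mu`, sdlog `sigma`) or
#'   `"exponential"` (rate `1/mu`).
#' @param mu,sigma weight-law scale parameters.
#' @param symmetric if `TRUE`, return a symmetric matrix.
#' @param seed integer seed.
#' @return A [Connectome-class] with zero diagonal.
#' @examples
#' con <- genConnectome(60, seed = 1)
#' @export
genConnectome <- function(nRegions = 360, density = 1,
                          weightLaw = c("lognormal", "exponential"),
                          mu = 0, sigma = 1, symmetric = TRUE, seed = NULL) {
  weightLaw <- match.arg(weightLaw)
  if (nRegions < 2) stop("'nRegions' must be >= 2")
  if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
  withSeed(seed, {
    W <- matrix(0, nRegions, nRegions)
    if (symmetric) {
      ut <- which(upper.tri(W))
      keep <- ut[runif(length(ut)) < density | density >= 1]
      W[keep] <- drawWeights(length(keep), weightLaw, mu, sigma)
      W <- W + t(W)
    } else {
      off <- which(row(W) != col(W))
      keep <- off[runif(length(off)) < density | density >= 1]
      W[keep] <- drawWeights(length(keep), weightLaw, mu, sigma)
    }
    diag(W) <- 0
    Connectome(W)
  })
}

drawWeights <- function(n, law, mu, sigma) {
  switch(law,
    lognormal = rlnorm(n, meanlog = mu, sdlog = sigma),
    exponential = {
      if (mu <= 0) stop("'mu' must be > 0 (mean weight) for the ",
                        "exponential law")
      stats::rexp(n, rate = 1 / mu)
    })
}
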