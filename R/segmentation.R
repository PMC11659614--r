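#' Binarize a wheel-velocity trace into run/rest
#'
#' Per-sample run flag `|v| > threshold`, followed by morphological
#' cleaning: rest gaps shorter than `minGapS` between two run bouts are
#' merged into the surrounding run, then run bouts shorter than
#' `minBoutS` are suppressed.
#'
#' @param velocity numeric velocity trace.
#' @param fs sampling rate in Hz.
#' @param threshold locomotion threshold in velocity units (default 0.25).
#' @param minBoutS minimum run-bout duration in seconds.
#' @param minGapS minimum rest-gap duration in seconds.
#' @return logical vector, `TRUE` for run samples.
#' @export
binarizeLocomotion <- function(velocity, fs, threshold = 0.25,
                               minBoutS = 1, minGapS = 1) {
  run <- abs(as.numeric(velocity)) > threshold
  if (!length(run)) return(logical())
  r <- rle(run)
  # close short rest gaps between runs
  if (length(r$lengths) > 2) {
    interior <- 2:(length(r$lengths) - 1L)
    gap <- interior[!r$values[interior] &
                      r$lengths[interior] < round(minGapS * fs)]
    r$values[gap] <- TRUE
  }
  run <- inverse.rle(r)
  r <- rle(run)
  r$values[r$values & r$lengths < round(minBoutS * fs)] <- FALSE
  inverse.rle(r)
}

#' Segment a binarized trace into labeled 10-s behavioral windows
#'
#' Implements the five-state bout heuristic for head-fixed mice on a
#' wheel. For each run bout with pre-rest duration `preR`, bout duration
#' `runD` and post-rest duration `postR` (seconds, on the sample grid):
#' \describe{
#'   \item{onset}{overlapping 5 s rest + 5 s running at bout start;
#'     requires `preR >= 5` and `runD >= 5`.}
#'   \item{locomotion}{the 10 s in the middle of the bout; requires
#'     `runD >= 20` and `preR >= 60`.}
#'   \item{offset}{last 5 s of running + first 5 s of rest; requires
#'     `runD >= 20` and `postR >= 10`.}
#'   \item{initial_rest}{first 10 s of rest after the bout; requires
#'     `runD >= 5` and `postR >= 60`.}
#'   \item{sustained_rest}{10 s of rest starting 40 s after the bout
#'     end, for the same qualifying bouts as initial_rest.}
#' }
#' Every window is exactly 10 s; a bout may emit several states, and the
#' offset and initial-rest windows of the same bout overlap by
#' construction. Rest before the first sample / after the last sample of
#' the trace is not assumed: pre/post-rest are measured inside the trace.
#'
#' @param runFlags logical run/rest trace from [binarizeLocomotion()].
#' @param fs sampling rate in Hz.
#' @param windowS window length in seconds (10).
#' @return data.frame `state`, `start_s`, `end_s`, `bout_id`, ordered by
#'   bout then window start. Empty (with a warning) for traces < 10 s.
#' @export
segmentStates <- function(runFlags, fs, windowS = 10) {
  emptyTab <- data.frame(state = character(), start_s = numeric(),
                         end_s = numeric(), bout_id = integer())
  n <- length(runFlags)
  if (n < round(windowS * fs)) {
    warning("trace shorter than one window; no segments")
    return(emptyTab)
  }
  r <- rle(as.logical(runFlags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(emptyTab)
  T <- n / fs
  snap <- function(x) round(x * fs) / fs
  out <- list()
  for (b in seq_along(runs)) {
    i <- runs[b]
    s0 <- (starts[i] - 1L) / fs     # bout start (s)
    s1 <- ends[i] / fs              # bout end (s)
    runD <- s1 - s0
    preR <- if (i > 1L && !r$values[i - 1L]) r$lengths[i - 1L] / fs else 0
    postR <- if (i < length(r$lengths) && !r$values[i + 1L])
      r$lengths[i + 1L] / fs else 0
    add <- function(state, st) {
      st <- snap(st)
      if (st >= 0 && st + windowS <= T)
        out[[length(out) + 1L]] <<- data.frame(
          state = state, start_s = st, end_s = st + windowS, bout_id = b)
    }
    if (preR >= 5 && runD >= 5) add("onset", s0 - 5)
    if (runD >= 20 && preR >= 60) add("locomotion", (s0 + s1) / 2 - 5)
    if (runD >= 20 && postR >= 10) add("offset", s1 - 5)
    if (runD >= 5 && postR >= 60) {
      add("initial_rest", s1)
      add("sustained_rest", s1 + 40)
    }
  }
  if (!length(out)) return(emptyTab)
  tab <- do.call(rbind, out)
  tab[order(tab$bout_id, tab$start_s), , drop = FALSE]
}

#' Segment a raw velocity trace
#'
#' Convenience wrapper: [binarizeLocomotion()] then [segmentStates()].
#'
#' @inheritParams binarizeLocomotion
#' @inheritParams segmentStates
#' @return segment table as from [segmentStates()].
#' @examples
#' v <- genWheelVelocity(data.frame(preRest = 70, runDuration = 30,
#'                                  postRest = 70, runSpeed = 3,
#'                                  noiseSd = 0), fs = 20)
#' segmentBehavior(v, fs = 20)
#' @export
segmentBehavior <- function(velocity, fs, threshold = 0.25,
                            minBoutS = 1, minGapS = 1, windowS = 10) {
  segmentStates(binarizeLocomotion(velocity, fs, threshold,
                                   minBoutS, minGapS),
                fs = fs, windowS = windowS)
}
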