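#' Windowed intrinsic-timescale estimation
#'
#' Tiles a recording into non-overlapping windows (default 10 s), or uses
#' the windows of a segment table, and estimates `tau` (exponential ACF
#' fit) and ACW-0 for every channel in every complete window. Incomplete
#' trailing windows are dropped. The ACF of each window is computed up to
#' half the window length.
#'
#' @param recording a [Recording-class].
#' @param windowS window length in seconds (default 10).
#' @param segments optional segment table (as returned by
#'   [segmentStates()]): one estimate per segment instead of tiling.
#' @param maxLag largest ACF lag in samples; default half the window.
#' @return long-format data.frame with columns `window`, `start_s`,
#'   `state`, `channel`, `tau_s`, `acw0_s`, `fit_rmse`, `converged`.
#'   The `state` column is `NA` for unlabeled recordings; for tiled
#'   windows it is the label shared by all samples of the window
#'   (`"mixed"` if labels differ within a window).
#' @examples
#' rec <- genStateRecording(data.frame(state = "rest", duration = 60),
#'                          list(rest = 0.3), nChannels = 2, seed = 1)
#' head(windowedINT(rec))
#' @export
windowedINT <- function(recording, windowS = 10, segments = NULL,
                        maxLag = NULL) {
  stopifnot(is(recording, "Recording"))
  fs <- recording@fs
  sig <- recording@signals
  labs <- recording@labels
  if (is.null(segments)) {
    wlen <- round(windowS * fs)
    nwin <- floor(nrow(sig) / wlen)
    if (nwin < 1) {
      return(emptyIntTable())
    }
    starts <- (seq_len(nwin) - 1L) * wlen + 1L
    states <- vapply(starts, function(s) {
      if (!length(labs)) return(NA_character_)
      u <- unique(labs[s:(s + wlen - 1L)])
      if (length(u) == 1L) u else "mixed"
    }, "")
  } else {
    starts <- round(segments$start_s * fs) + 1L
    wlen <- round(windowS * fs)
    ok <- starts >= 1L & (starts + wlen - 1L) <= nrow(sig)
    segments <- segments[ok, , drop = FALSE]
    starts <- starts[ok]
    states <- as.character(segments$state)
    nwin <- length(starts)
    if (nwin < 1) return(emptyIntTable())
  }
  if (is.null(maxLag)) maxLag <- floor(wlen / 2)
  out <- vector("list", nwin * ncol(sig))
  k <- 0L
  for (w in seq_len(nwin)) {
    rows <- starts[w]:(starts[w] + wlen - 1L)
    for (ch in seq_len(ncol(sig))) {
      x <- sig[rows, ch]
      k <- k + 1L
      if (var(x) == 0) {
        out[[k]] <- data.frame(window = w, start_s = (starts[w] - 1L) / fs,
                               state = states[w],
                               channel = colnames(sig)[ch],
                               tau_s = NA_real_, acw0_s = NA_real_,
                               fit_rmse = NA_real_, converged = FALSE)
        next
      }
      a <- computeACF(x, maxLag = maxLag, fs = fs)
      fit <- fitTau(a)
      out[[k]] <- data.frame(window = w, start_s = (starts[w] - 1L) / fs,
                             state = states[w],
                             channel = colnames(sig)[ch],
                             tau_s = fit$tau, acw0_s = computeACW0(a),
                             fit_rmse = fit$rmse, converged = fit$converged)
    }
  }
  do.call(rbind, out)
}

emptyIntTable <- function() {
  data.frame(window = integer(), start_s = numeric(), state = character(),
             channel = character(), tau_s = numeric(), acw0_s = numeric(),
             fit_rmse = numeric(), converged = logical())
}

#' Default frequency bands
#'
#' Band edges in Hz as used throughout the analyses. Note the labels for
#' the two slowest bands are kept exactly as printed in the source
#' analyses (theta: 1-4 Hz, delta: 4-7 Hz); rename via the `bands`
#' argument of [bandPower()] if the conventional naming is wanted.
#'
#' @return named list of `c(lo, hi)` edges in Hz.
#' @export
defaultBands <- function() {
  list(theta = c(1, 4), delta = c(4, 7), alpha = c(8, 12),
       beta = c(13, 30), gamma = c(30, 40), broadband = c(1, 40))
}

#' Band power of a window by periodogram + trapezoid integration
#'
#' One-sided periodogram of the demeaned window, scaled so that its
#' integral over frequency equals the window variance (Parseval), then
#' the area under the spectrum between each pair of band edges by the
#' trapezoid rule (with linear interpolation at the exact edges).
#'
#' @param x numeric vector (one channel, one window).
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param bands named list of `c(lo, hi)` Hz edges; see [defaultBands()].
#' @return named numeric vector of band powers (signal units squared).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1 / 500))
#' bandPower(x, fs = 500)["alpha"]
#' @export
bandPower <- function(x, fs, bands = defaultBands()) {
  x <- as.numeric(x)
  n <- length(x)
  hi <- max(vapply(bands, max, 0))
  if (fs <= 2 * hi)
    stop("band edge above Nyquist: fs must exceed twice the highest edge")
  xd <- x - mean(x)
  if (all(xd == 0)) {
    p <- rep(0, length(bands)); names(p) <- names(bands); return(p)
  }
  nf <- floor(n / 2) + 1L
  P <- (2 / (fs * n)) * Mod(fft(xd)[seq_len(nf)])^2
  P[1L] <- P[1L] / 2
  if (n %% 2 == 0) P[nf] <- P[nf] / 2
  freq <- (seq_len(nf) - 1L) * fs / n
  vapply(bands, function(b) {
    inb <- freq > b[1] & freq < b[2]
    fg <- c(b[1], freq[inb], b[2])
    pg <- c(approx(freq, P, xout = b[1], rule = 2)$y, P[inb],
            approx(freq, P, xout = b[2], rule = 2)$y)
    pracma::trapz(fg, pg)
  }, 0)
}
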