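#' Autocorrelation function of a window
#'
#' Computes the ACF of a single-channel window with the biased
#' normalization
#' \deqn{r_l = \frac{\sum_{t=1}^{N-l} (x_t-\bar x)(x_{t+l}-\bar x)}
#'                  {\sum_{t=1}^{N} (x_t-\bar x)^2},}
#' i.e. the lagged autocovariance of the demeaned window divided by its
#' full-window sum of squares, so \eqn{r_0 = 1} exactly. The default FFT
#' route (Wiener--Khinchin with zero padding) is numerically identical to
#' the direct double summation, which is kept as `method = "direct"` and
#' serves as an independent cross-check.
#'
#' @param x numeric vector (one channel, one window), not constant.
#' @param maxLag largest lag in samples; must satisfy
#'   `1 <= maxLag < length(x)`. Default: half the window length.
#' @param fs sampling rate in Hz (used to express lags in seconds
#'   downstream).
#' @param method `"fft"` (default) or `"direct"`.
#' @return An [ACFEstimate-class] with lags `0..maxLag`.
#' @examples
#' a <- computeACF(genOUSeries(0.5, fs = 20, duration = 10, seed = 1), fs = 20)
#' acfValues(a)[1]  # exactly 1
#' @export
computeACF <- function(x, maxLag = floor(length(x) / 2), fs = 1,
                       method = c("fft", "direct")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (maxLag < 1 || maxLag >= n)
    stop("'maxLag' must satisfy 1 <= maxLag < length(x)")
  xd <- x - mean(x)
  ss <- sum(xd^2)
  if (ss == 0) stop("constant window: autocorrelation undefined")
  if (method == "direct") {
    ac <- vapply(0:maxLag, function(l) {
      sum(xd[seq_len(n - l)] * xd[(1 + l):n]) / ss
    }, 0)
  } else {
    nfft <- stats::nextn(2L * n, 2L)
    f <- fft(c(xd, numeric(nfft - n)))
    acov <- Re(fft(f * Conj(f), inverse = TRUE)) / nfft
    ac <- acov[1:(maxLag + 1L)] / acov[1L]
  }
  new("ACFEstimate", lags = 0:as.integer(maxLag), acf = ac, fs = as.numeric(fs))
}

#' Fit an exponential decay to an ACF and extract the timescale
#'
#' Fits \eqn{e^{-l/\tau}} to the ACF values by least squares. Because the
#' model has a single parameter, the fit is a bounded one-dimensional
#' minimization, bracketed around the empirical 1/e crossing of the ACF
#' (the definitional anchor of the timescale: the lag at which the ACF
#' reaches 1/e equals tau). By default the fit uses lags from 0 up to the
#' first integer lag at which the ACF has decayed to 1/e (minimum 3
#' lags): the single-exponential model describes the initial decay, and
#' in finite windows the ACF tail is dominated by the negative bias of
#' the within-window mean subtraction, which would otherwise drag the
#' estimate down. Windows whose ACF never decays below 1/e within the
#' computed range are marked non-converged.
#'
#' @param acf an [ACFEstimate-class] with at least 3 lags.
#' @param nLags number of leading lags used in the fit; `NULL` (default)
#'   truncates at the first 1/e crossing, `Inf` uses all computed lags.
#' @return list with `tau` (seconds; `NA` if not converged), `tauSamples`,
#'   `rmse` and `converged`.
#' @examples
#' a <- computeACF(genOUSeries(0.5, fs = 20, duration = 10, seed = 1), fs = 20)
#' fitTau(a)$tau
#' @export
fitTau <- function(acf, nLags = NULL) {
  stopifnot(is(acf, "ACFEstimate"))
  l <- as.numeric(acf@lags)
  r <- acf@acf
  if (length(l) < 3) stop("need at least 3 lags to fit")
  cross <- firstCrossing(l, r, 1 / exp(1))
  if (is.na(cross)) {
    return(list(tau = NA_real_, tauSamples = NA_real_, rmse = NA_real_,
                converged = FALSE))
  }
  maxL <- max(l)
  if (is.null(nLags)) nLags <- which(r <= 1 / exp(1))[1]
  keep <- seq_len(min(length(l), max(3L, nLags)))
  l <- l[keep]
  r <- r[keep]
  sse <- function(tau) sum((exp(-l / tau) - r)^2)
  lo <- max(cross / 20, 1e-3)
  hi <- min(cross * 20, 2 * maxL)
  opt <- optimize(sse, interval = c(lo, hi))
  tauS <- opt$minimum
  conv <- tauS > lo * 1.001 && tauS < hi * 0.999
  list(tau = if (conv) tauS / acf@fs else NA_real_,
       tauSamples = if (conv) tauS else NA_real_,
       rmse = sqrt(opt$objective / length(l)),
       converged = conv)
}

#' Zero-crossing autocorrelation window (ACW-0)
#'
#' First lag at which the ACF reaches zero, linearly interpolated between
#' the bracketing integer lags for sub-sample resolution. Undefined (NA)
#' when the ACF stays positive over the whole computed range; such windows
#' are excluded downstream.
#'
#' @param acf an [ACFEstimate-class].
#' @return ACW-0 in seconds, or `NA_real_` if no crossing.
#' @export
computeACW0 <- function(acf) {
  stopifnot(is(acf, "ACFEstimate"))
  cross <- firstCrossing(as.numeric(acf@lags), acf@acf, 0)
  if (is.na(cross)) NA_real_ else cross / acf@fs
}

# first x at which y (piecewise linear over x) descends to `level`
firstCrossing <- function(x, y, level) {
  below <- which(y <= level)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(x[1L])
  x0 <- x[i - 1L]; x1 <- x[i]
  y0 <- y[i - 1L]; y1 <- y[i]
  if (y0 == y1) return(x1)
  x0 + (y0 - level) / (y0 - y1) * (x1 - x0)
}
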