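#' @import methods
#' @importFrom stats approx cor fft filter mad median optimize pnorm pt
#'   quantile rlnorm rnorm runif sd var
NULL

#' Multichannel neural recording
#'
#' Container for a regularly sampled multichannel time series (samples in
#' rows, channels in columns) with its sampling rate and, optionally, a
#' per-sample behavioral state label.
#'
#' @slot signals numeric matrix, samples x channels.
#' @slot fs sampling rate in Hz.
#' @slot labels character vector of per-sample state labels (length 0 if
#'   unlabeled, otherwise one label per sample).
#' @export
setClass("Recording",
  representation(signals = "matrix", fs = "numeric", labels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "'fs' must be a single positive number")
    if (!is.numeric(object@signals))
      msg <- c(msg, "'signals' must be a numeric matrix")
    if (length(object@labels) > 0L &&
        length(object@labels) != nrow(object@signals))
      msg <- c(msg, "'labels' must be empty or have one entry per sample")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a Recording
#'
#' @param signals numeric matrix (samples x channels) or a vector for a
#'   single channel.
#' @param fs sampling rate in Hz.
#' @param labels optional character vector of per-sample state labels.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(200), 100, 2), fs = 20)
#' nSamples(rec)
#' @export
Recording <- function(signals, fs, labels = character()) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1L)
  if (is.null(colnames(signals)))
    colnames(signals) <- sprintf("ch%02d", seq_len(ncol(signals)))
  new("Recording", signals = signals, fs = as.numeric(fs),
      labels = as.character(labels))
}

#' Structural connectome
#'
#' Square nonnegative coupling matrix. Off-diagonal entries are interareal
#' connection weights; the diagonal holds the recurrent (self) connection
#' strength, which the firing-rate model manipulates independently of the
#' interareal weights.
#'
#' @slot W numeric square matrix, nonnegative.
#' @export
setClass("Connectome",
  representation(W = "matrix"),
  validity = function(object) {
    W <- object@W
    msg <- NULL
    if (nrow(W) != ncol(W)) msg <- c(msg, "'W' must be square")
    if (any(!is.finite(W))) msg <- c(msg, "'W' must be finite")
    if (any(W < 0)) msg <- c(msg, "'W' must be nonnegative")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a Connectome
#'
#' @param W square nonnegative numeric matrix.
#' @return A [Connectome-class] object.
#' @export
Connectome <- function(W) new("Connectome", W = as.matrix(W))

#' Firing-rate simulation result
#'
#' Region x time firing-rate trajectories (transient already discarded)
#' together with the applied external input and the parameter snapshot.
#'
#' @slot rates numeric matrix, regions x retained time steps, values in (0,1).
#' @slot input numeric matrix (regions x time) or 1 x time for a shared
#'   scalar input: the external input actually applied at each retained step.
#' @slot fs sampling rate of the trajectories (1/dt) in Hz.
#' @slot params list: parameter snapshot of the run.
#' @slot seed integer seed used (NA if run on ambient RNG state).
#' @export
setClass("SimulationResult",
  representation(rates = "matrix", input = "matrix", fs = "numeric",
                 params = "list", seed = "numeric"),
  validity = function(object) {
    if (length(object@fs) != 1L || object@fs <= 0)
      "'fs' must be a single positive number" else TRUE
  }
)

#' Autocorrelation function estimate
#'
#' ACF of a single demeaned window, computed with the biased normalization
#' (denominator over all N terms) so that the value at lag 0 is exactly 1.
#'
#' @slot lags integer lags in samples, 0..L.
#' @slot acf correlation values at those lags.
#' @slot fs sampling rate in Hz (converts lags to seconds).
#' @export
setClass("ACFEstimate",
  representation(lags = "integer", acf = "numeric", fs = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@lags) != length(object@acf))
      msg <- c(msg, "'lags' and 'acf' must have equal length")
    if (length(object@acf) > 0 && abs(object@acf[1] - 1) > 1e-8)
      msg <- c(msg, "acf at lag 0 must equal 1")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "Recording", function(object) {
  cat("Recording:", nrow(object@signals), "samples x",
      ncol(object@signals), "channels @", object@fs, "Hz (",
      sprintf("%.1f", nrow(object@signals) / object@fs), "s )\n")
  if (length(object@labels))
    cat("  states:", paste(names(table(object@labels)), collapse = ", "), "\n")
})

setMethod("show", "Connectome", function(object) {
  W <- object@W
  d <- diag(W)
  cat("Connectome:", nrow(W), "x", ncol(W), "regions\n")
  cat(sprintf("  recurrent (diagonal): %s\n",
              if (length(unique(d)) == 1L) format(d[1]) else
                sprintf("[%.3g, %.3g]", min(d), max(d))))
  off <- W[row(W) != col(W)]
  cat(sprintf("  off-diagonal: density %.2f, mean row sum %.4g\n",
              mean(off > 0), mean(rowSums(W) - d)))
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", nrow(object@rates), "regions x",
      ncol(object@rates), "steps @ dt =", 1 / object@fs, "s\n")
  cat(sprintf("  mean rate %.4f, range [%.4f, %.4f]\n",
              mean(object@rates), min(object@rates), max(object@rates)))
})

setMethod("show", "ACFEstimate", function(object) {
  cat("ACFEstimate:", length(object@lags), "lags @", object@fs, "Hz\n")
})
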