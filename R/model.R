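#' Firing-rate model parameters
#'
#' Parameter snapshot for the connectome-coupled firing-rate model
#' \deqn{\tau \, dx_i/dt = -x_i + f(\textstyle\sum_j W_{ij} x_j + b + s + I),
#'       \quad f(u) = 1/(1+e^{-ru}).}
#'
#' @param tauNode node time constant in seconds (default 0.05 s, the
#'   typical population time constant of Wilson-Cowan-type firing-rate
#'   units; it sets the scale of the network's intrinsic timescales).
#' @param b bias (-3).
#' @param r sigmoid gain (0.5).
#' @param dt integration step in seconds (0.01).
#' @param duration total simulated time in seconds (300).
#' @param discard initial transient to drop, seconds (100).
#' @param noiseSd SD of the zero-mean Gaussian noise drawn once per step
#'   per region and held across both RK2 stages (1; set 0 for a
#'   noise-free run).
#' @param tauI controller time constant for the clamped-input variant,
#'   seconds (0.05).
#' @return named list of validated parameters.
#' @export
modelParams <- function(tauNode = 0.05, b = -3, r = 0.5, dt = 0.01,
                        duration = 300, discard = 100, noiseSd = 1,
                        tauI = 0.05) {
  stopifnot_scalar_pos(tauNode, "tauNode")
  stopifnot_scalar_pos(r, "r")
  stopifnot_scalar_pos(dt, "dt")
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(tauI, "tauI")
  if (discard < 0 || discard >= duration)
    stop("'discard' must satisfy 0 <= discard < duration")
  list(tauNode = tauNode, b = b, r = r, dt = dt, duration = duration,
       discard = discard, noiseSd = noiseSd, tauI = tauI)
}

#' Scale off-diagonal coupling to a mean row sum of 2
#'
#' Multiplies all off-diagonal entries by a single scalar so that the
#' across-rows mean of the off-diagonal row sums equals 2 (interareal
#' input stronger than the unit default recurrent strength); the
#' diagonal is untouched. Idempotent.
#'
#' @param connectome a [Connectome-class].
#' @param target mean off-diagonal row sum after scaling (2).
#' @return scaled [Connectome-class].
#' @export
scaleOffdiagonal <- function(connectome, target = 2) {
  W <- couplingMatrix(connectome)
  d <- diag(W)
  m <- mean(rowSums(W) - d)
  if (m == 0) stop("all-zero off-diagonal: cannot scale")
  W <- W * (target / m)
  diag(W) <- d
  Connectome(W)
}

#' Set the recurrent (diagonal) connection strength
#'
#' @param connectome a [Connectome-class].
#' @param wii nonnegative recurrent strength applied to every region
#'   (1 is the model's default state).
#' @return [Connectome-class] with the new diagonal; off-diagonal
#'   entries are untouched.
#' @export
setRecurrent <- function(connectome, wii) {
  if (wii < 0) stop("'wii' must be >= 0")
  W <- couplingMatrix(connectome)
  diag(W) <- wii
  Connectome(W)
}

#' Shuffle a fraction of the off-diagonal edges
#'
#' Randomly permutes the chosen fraction of off-diagonal entries among
#' their positions, preserving the multiset of interareal weights and
#' leaving the diagonal (recurrent connections) bit-identical -- the
#' topology null model.
#'
#' @param connectome a [Connectome-class].
#' @param fraction fraction of off-diagonal entries to permute, in (0, 1].
#' @param seed integer seed.
#' @return shuffled [Connectome-class].
#' @export
shuffleEdges <- function(connectome, fraction = 1, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  W <- couplingMatrix(connectome)
  off <- which(row(W) != col(W))
  withSeed(seed, {
    m <- max(2L, round(fraction * length(off)))
    pick <- sample(off, m)
    W[pick] <- W[sample(pick)]
  })
  Connectome(W)
}

#' Simulate the firing-rate model with fixed external input
#'
#' RK2 (explicit midpoint) integration; the noise draw is sampled once
#' per step and held fixed across both stages. The first `discard`
#' seconds are dropped from the returned trajectories.
#'
#' @param connectome a [Connectome-class] (scale with
#'   [scaleOffdiagonal()] and set the diagonal with [setRecurrent()]
#'   first).
#' @param input external input `I`: 0 for the resting state, 1 for the
#'   stimulated state.
#' @param params list from [modelParams()].
#' @param seed integer seed (noise and initial conditions); `NULL` uses
#'   the ambient RNG stream.
#' @param x0 optional initial rates; default Uniform(0,1) per region.
#' @return A [SimulationResult-class].
#' @examples
#' con <- setRecurrent(scaleOffdiagonal(genConnectome(20, seed = 1)), 1)
#' sim <- simulateModel(con, input = 0,
#'                      params = modelParams(duration = 15, discard = 5),
#'                      seed = 1)
#' @export
simulateModel <- function(connectome, input = 0, params = modelParams(),
                          seed = NULL, x0 = NULL) {
  W <- couplingMatrix(connectome)
  nSteps <- round(params$duration / params$dt)
  nDrop <- round(params$discard / params$dt)
  withSeed(seed, {
    if (is.null(x0)) x0 <- runif(nrow(W))
    rates <- sim_rates_cpp(W, params$b, params$r, input, params$tauNode,
                           params$dt, nSteps, params$noiseSd, x0)
    keep <- (nDrop + 1L):nSteps
    new("SimulationResult", rates = rates[, keep, drop = FALSE],
        input = matrix(input, 1L, length(keep)),
        fs = 1 / params$dt,
        params = c(params, list(input = input, mode = "fixed")),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' Steady-state input that clamps a region at a target rate
#'
#' Evaluates
#' \deqn{\tilde I_i = \mathrm{logit}(\bar x)/r - \sum_{j\ne i} W_{ij} x_j
#'       - W_{ii}\bar x - b,}
#' the external input for which the sigmoid steady state of region `i`
#' equals the target rate `xbar` given the current rates `x` of the
#' other regions. Vectorized over regions.
#'
#' @param connectome a [Connectome-class].
#' @param xbar target rate in (0, 1).
#' @param x current rates (length = regions).
#' @param params list from [modelParams()] (uses `b` and `r`).
#' @return numeric vector of inputs, one per region.
#' @export
steadyStateInput <- function(connectome, xbar, x, params = modelParams()) {
  if (xbar <= 0 || xbar >= 1) stop("'xbar' must be in (0, 1) (logit)")
  W <- couplingMatrix(connectome)
  d <- diag(W)
  log(xbar / (1 - xbar)) / params$r -
    (as.numeric(W %*% x) - d * x) - d * xbar - params$b
}

#' Simulate with the firing-rate clamping controller
#'
#' Co-integrates the rate equations with per-region input dynamics
#' \eqn{\tau_I \, dI_i/dt = \tilde I_i(t) - I_i(t)} so the network mean
#' rate (across retained time and regions) settles at the target
#' (0.1 for rest, 0.6 for stimulation), decoupling the mean firing rate
#' from the recurrent strength.
#'
#' @inheritParams simulateModel
#' @param xbar target mean rate in (0, 1).
#' @return A [SimulationResult-class]; `appliedInput()` holds the
#'   per-region input trace.
#' @export
simulateClamped <- function(connectome, xbar = 0.1, params = modelParams(),
                            seed = NULL, x0 = NULL) {
  if (xbar <= 0 || xbar >= 1) stop("'xbar' must be in (0, 1)")
  W <- couplingMatrix(connectome)
  nSteps <- round(params$duration / params$dt)
  nDrop <- round(params$discard / params$dt)
  withSeed(seed, {
    if (is.null(x0)) x0 <- runif(nrow(W))
    res <- sim_clamped_cpp(W, params$b, params$r, xbar, params$tauNode,
                           params$tauI, params$dt, nSteps, params$noiseSd,
                           x0)
    keep <- (nDrop + 1L):nSteps
    new("SimulationResult", rates = res$rates[, keep, drop = FALSE],
        input = res$input[, keep, drop = FALSE],
        fs = 1 / params$dt,
        params = c(params, list(xbar = xbar, mode = "clamped")),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' Windowed timescales of a simulation
#'
#' Delegates to [windowedINT()] on the region x time trajectories
#' (regions become channels). 200 retained seconds give 20 windows per
#' region at the default 10-s window.
#'
#' @param result a [SimulationResult-class].
#' @param windowS window length in seconds.
#' @return long-format timescale table (see [windowedINT()]); channels
#'   are named `r001`, `r002`, ...
#' @export
windowedModelINT <- function(result, windowS = 10) {
  stopifnot(is(result, "SimulationResult"))
  sig <- t(firingRates(result))
  colnames(sig) <- sprintf("r%03d", seq_len(ncol(sig)))
  windowedINT(Recording(sig, fs = result@fs), windowS = windowS)
}
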