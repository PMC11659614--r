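#' Sweep the recurrent-connection strength
#'
#' For each recurrent strength `wii`, simulates the model `nSims` times
#' in the resting and stimulated states, estimates windowed timescales,
#' and summarizes the rest-to-stimulation change: a paired Wilcoxon
#' comparison (units = per-region, per-simulation across-window means;
#' rank-biserial effect size) and the percent change averaged across
#' regions and simulations. In `"fixed"` mode rest/stimulation are
#' `I = 0` / `I = 1`; in `"clamped"` mode the controller targets mean
#' rates 0.1 / 0.6.
#'
#' @param connectome a [Connectome-class], already off-diagonal scaled.
#' @param wiiValues recurrent strengths to sweep (default 0 to 4 by 0.5).
#' @param nSims simulations per state per strength (default 30).
#' @param mode `"fixed"` or `"clamped"`.
#' @param params list from [modelParams()].
#' @param measure `"tau_s"` or `"acw0_s"`.
#' @param windowS window length in seconds.
#' @param seed master seed; per-run child seeds are derived from it.
#' @param targets clamped-mode target rates `c(rest, stim)`.
#' @return list of class `"recurrentSweep"`: `summary` (data.frame per
#'   `wii`: `z`, `p`, `effect_r`, `mean_pct_change`, `n_per_group`,
#'   `mean_rate_rest`, `mean_rate_stim`) and `curve` (the change-vs-wii
#'   relation interpolated on a fine grid).
#' @export
sweepRecurrent <- function(connectome, wiiValues = seq(0, 4, by = 0.5),
                           nSims = 30, mode = c("fixed", "clamped"),
                           params = modelParams(), measure = "tau_s",
                           windowS = 10, seed = NULL,
                           targets = c(0.1, 0.6)) {
  mode <- match.arg(mode)
  rows <- vector("list", length(wiiValues))
  for (iw in seq_along(wiiValues)) {
    wii <- wiiValues[iw]
    con <- setRecurrent(connectome, wii)
    restM <- stimM <- NULL   # per-(region, sim) across-window means
    rateR <- rateS <- 0
    for (s in seq_len(nSims)) {
      sdR <- childSeed(seed, iw * 1000L + 2L * s)
      sdS <- childSeed(seed, iw * 1000L + 2L * s + 1L)
      simR <- if (mode == "fixed")
        simulateModel(con, input = 0, params = params, seed = sdR)
      else simulateClamped(con, xbar = targets[1], params = params,
                           seed = sdR)
      simS <- if (mode == "fixed")
        simulateModel(con, input = 1, params = params, seed = sdS)
      else simulateClamped(con, xbar = targets[2], params = params,
                           seed = sdS)
      rateR <- rateR + mean(firingRates(simR)) / nSims
      rateS <- rateS + mean(firingRates(simS)) / nSims
      restM <- c(restM, regionMeans(windowedModelINT(simR, windowS),
                                    measure))
      stimM <- c(stimM, regionMeans(windowedModelINT(simS, windowS),
                                    measure))
    }
    ok <- !is.na(restM) & !is.na(stimM)
    cmp <- compareGroups(stimM[ok], restM[ok], paired = TRUE)
    rows[[iw]] <- data.frame(
      wii = wii, z = cmp$z, p = cmp$p, effect_r = cmp$effect_r,
      mean_pct_change = mean(percentChange(restM[ok], stimM[ok])),
      n_per_group = sum(ok),
      mean_rate_rest = rateR, mean_rate_stim = rateS)
  }
  summary <- do.call(rbind, rows)
  curve <- if (nrow(summary) >= 3) {
    grid <- seq(min(wiiValues), max(wiiValues), length.out = 101L)
    list(wii = grid,
         pct_change = stats::spline(summary$wii, summary$mean_pct_change,
                                    xout = grid)$y)
  } else NULL
  structure(list(summary = summary, curve = curve, mode = mode,
                 measure = measure, n_sims = nSims),
            class = "recurrentSweep")
}

#' Rest vs stimulated simulation experiment
#'
#' Simulates the model `nSims` times in the resting and stimulated
#' states and returns, per region and simulation, the across-window
#' mean and SD of the resting-state timescale, the stimulated-state
#' mean, and the rest-to-stimulation percent change -- the table behind
#' the model's rest-task modulation analyses (feed it to
#' [spearmanCor()] / [compareGroups()]).
#'
#' @inheritParams sweepRecurrent
#' @return data.frame `sim`, `region`, `rest_mean`, `rest_sd`,
#'   `stim_mean`, `pct_change` (rows with failed fits dropped).
#' @export
restStimExperiment <- function(connectome, nSims = 30,
                               mode = c("fixed", "clamped"),
                               params = modelParams(), measure = "tau_s",
                               windowS = 10, seed = NULL,
                               targets = c(0.1, 0.6)) {
  mode <- match.arg(mode)
  rows <- vector("list", nSims)
  for (s in seq_len(nSims)) {
    sdR <- childSeed(seed, 2L * s)
    sdS <- childSeed(seed, 2L * s + 1L)
    simR <- if (mode == "fixed")
      simulateModel(connectome, 0, params, seed = sdR)
    else simulateClamped(connectome, targets[1], params, seed = sdR)
    simS <- if (mode == "fixed")
      simulateModel(connectome, 1, params, seed = sdS)
    else simulateClamped(connectome, targets[2], params, seed = sdS)
    tR <- windowedModelINT(simR, windowS)
    tS <- windowedModelINT(simS, windowS)
    agg <- function(tab, f) {
      ok <- tab$converged & !is.na(tab[[measure]])
      vapply(split(tab[[measure]][ok], tab$channel[ok]), f, 0)
    }
    rm_ <- agg(tR, mean); rs <- agg(tR, sd); sm <- agg(tS, mean)
    ch <- intersect(names(rm_), names(sm))
    rows[[s]] <- data.frame(sim = s, region = ch, rest_mean = rm_[ch],
                            rest_sd = rs[ch], stim_mean = sm[ch],
                            pct_change = percentChange(rm_[ch], sm[ch]),
                            row.names = NULL)
  }
  do.call(rbind, rows)
}

# across-window mean of the measure for each region of one simulation
regionMeans <- function(intTable, measure) {
  tab <- intTable[intTable$converged & !is.na(intTable[[measure]]), ]
  out <- vapply(split(tab[[measure]], tab$channel), mean, 0)
  all <- sort(unique(intTable$channel))
  out[match(all, names(out))]
}

#' @export
print.recurrentSweep <- function(x, ...) {
  cat("Recurrent-connection sweep (", x$mode, " input, ", x$n_sims,
      " sims/state, measure ", x$measure, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
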