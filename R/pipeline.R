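#' Default pipeline configuration
#'
#' Nested key/value configuration for [runPipeline()]. Every stochastic
#' stage derives its own seed from the single master `seed` via a
#' counter scheme, so a config reruns identically. The config
#' round-trips losslessly through YAML ([writeRunConfig()] /
#' [readRunConfig()]).
#'
#' @param pipeline `"empirical"` or `"model"`.
#' @param seed master seed.
#' @return nested named list.
#' @export
defaultConfig <- function(pipeline = c("empirical", "model"), seed = 1L) {
  pipeline <- match.arg(pipeline)
  if (pipeline == "empirical") {
    list(pipeline = "empirical", seed = as.integer(seed),
         synth = list(n_channels = 20, fs = 20,
                      bout = list(preRest = 70, runDuration = 30,
                                  postRest = 70, runSpeed = 3,
                                  noiseSd = 0.05),
                      n_bouts = 3,
                      tau_rest = 0.3, tau_run = 0.6),
         segment = list(threshold = 0.25, min_bout_s = 1, min_gap_s = 1),
         estimate = list(window_s = 10),
         classify = list(enabled = FALSE, model = "svm", outer = 5,
                         inner = 5, budget = 10),
         stats = list(rest_state = "sustained_rest",
                      task_state = "locomotion"))
  } else {
    list(pipeline = "model", seed = as.integer(seed),
         connectome = list(n_regions = 60, density = 1,
                           weight_law = "lognormal"),
         model = list(wii = 1, duration = 120, discard = 20,
                      n_sims = 2),
         estimate = list(window_s = 10),
         sweep = list(enabled = FALSE, wii_values = c(0, 1, 2),
                      n_sims = 2))
  }
}

#' @rdname defaultConfig
#' @param config nested list as from [defaultConfig()].
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname defaultConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Run an end-to-end pipeline
#'
#' Ties the stages into a reproducible run on synthetic inputs and
#' writes every intermediate table plus a manifest to `outDir`.
#'
#' \describe{
#'   \item{empirical}{generate a state-dependent recording + wheel
#'     velocity, segment the velocity into behavioral windows, estimate
#'     windowed timescales per segment, compare rest vs task states
#'     (Wilcoxon + rank-biserial, variability-change correlation), and
#'     optionally classify states from the per-window timescale
#'     topography.}
#'   \item{model}{generate and scale a synthetic connectome, simulate
#'     resting and stimulated states, estimate windowed timescales,
#'     compare states, and optionally sweep the recurrent strength.}
#' }
#'
#' @param config nested list (see [defaultConfig()]).
#' @param outDir output directory (created if missing).
#' @return list with the key results and the manifest (invisibly the
#'   same content is written under `outDir`).
#' @export
runPipeline <- function(config, outDir = tempfile("intflex_run_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(config$pipeline,
                empirical = runEmpirical(config, outDir),
                model = runModel(config, outDir),
                stop("unknown pipeline: ", config$pipeline))
  manifest <- list(package_version = as.character(utils::packageVersion("intflex")),
                   config = config, outputs = res$outputs,
                   log = res$log)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(c(res, list(manifest = manifest, dir = outDir)))
}

runEmpirical <- function(cfg, outDir) {
  fs <- cfg$synth$fs
  bout <- as.data.frame(cfg$synth$bout)
  bouts <- bout[rep(1L, cfg$synth$n_bouts), , drop = FALSE]
  vel <- genWheelVelocity(bouts, fs = fs, seed = childSeed(cfg$seed, 1L))
  flags <- binarizeLocomotion(vel, fs, cfg$segment$threshold,
                              cfg$segment$min_bout_s, cfg$segment$min_gap_s)
  segs <- segmentStates(flags, fs)
  # neural recording whose timescale follows the run/rest flags
  sched <- with(rle(flags), data.frame(
    state = ifelse(values, "run", "rest"), duration = lengths / fs))
  rec <- genStateRecording(sched,
                           list(rest = cfg$synth$tau_rest,
                                run = cfg$synth$tau_run),
                           nChannels = cfg$synth$n_channels, fs = fs,
                           seed = childSeed(cfg$seed, 2L))
  intTab <- windowedINT(rec, windowS = cfg$estimate$window_s,
                        segments = segs)
  sum_ <- restTaskSummary(intTab, restState = cfg$stats$rest_state,
                          taskState = cfg$stats$task_state)
  rest <- intTab$tau_s[intTab$state == cfg$stats$rest_state &
                         intTab$converged]
  task <- intTab$tau_s[intTab$state == cfg$stats$task_state &
                         intTab$converged]
  cmp <- compareGroups(task, rest)
  cls <- NULL
  if (isTRUE(cfg$classify$enabled)) {
    feats <- featureTable(intTab)
    cls <- nestedCVClassify(feats$x, feats$y, model = cfg$classify$model,
                            outer = cfg$classify$outer,
                            inner = cfg$classify$inner,
                            budget = cfg$classify$budget,
                            seed = childSeed(cfg$seed, 3L))
  }
  writeTable(segs, file.path(outDir, "segments.tsv"))
  writeTable(intTab, file.path(outDir, "int_table.tsv"))
  writeTable(sum_, file.path(outDir, "rest_task_summary.tsv"))
  list(segments = segs, intTable = intTab, summary = sum_,
       comparison = cmp, classifier = cls,
       outputs = c("segments.tsv", "int_table.tsv",
                   "rest_task_summary.tsv"),
       log = list(n_segments = nrow(segs),
                  n_windows = length(unique(intTab$window)),
                  n_excluded = sum(!intTab$converged),
                  task_gt_rest_z = cmp$z))
}

runModel <- function(cfg, outDir) {
  con <- genConnectome(cfg$connectome$n_regions,
                       density = cfg$connectome$density,
                       weightLaw = cfg$connectome$weight_law,
                       seed = childSeed(cfg$seed, 10L))
  con <- setRecurrent(scaleOffdiagonal(con), cfg$model$wii)
  par <- modelParams(duration = cfg$model$duration,
                     discard = cfg$model$discard)
  restM <- stimM <- NULL
  for (s in seq_len(cfg$model$n_sims)) {
    simR <- simulateModel(con, input = 0, params = par,
                          seed = childSeed(cfg$seed, 20L + 2L * s))
    simS <- simulateModel(con, input = 1, params = par,
                          seed = childSeed(cfg$seed, 21L + 2L * s))
    restM <- c(restM, regionMeans(windowedModelINT(simR,
                 cfg$estimate$window_s), "tau_s"))
    stimM <- c(stimM, regionMeans(windowedModelINT(simS,
                 cfg$estimate$window_s), "tau_s"))
  }
  ok <- !is.na(restM) & !is.na(stimM)
  cmp <- compareGroups(stimM[ok], restM[ok], paired = TRUE)
  sweep <- NULL
  if (isTRUE(cfg$sweep$enabled)) {
    sweep <- sweepRecurrent(con, wiiValues = unlist(cfg$sweep$wii_values),
                            nSims = cfg$sweep$n_sims, params = par,
                            seed = childSeed(cfg$seed, 30L))
    writeTable(sweep$summary, file.path(outDir, "sweep_summary.tsv"))
  }
  writeConnectome(con, file.path(outDir, "connectome.tsv"))
  tab <- data.frame(region = seq_along(restM)[ok],
                    rest_tau = restM[ok], stim_tau = stimM[ok])
  writeTable(tab, file.path(outDir, "model_int.tsv"))
  list(connectome = con, comparison = cmp, sweep = sweep,
       restTau = restM[ok], stimTau = stimM[ok],
       outputs = c("connectome.tsv", "model_int.tsv",
                   if (!is.null(sweep)) "sweep_summary.tsv"),
       log = list(n_regions = cfg$connectome$n_regions,
                  n_sims = cfg$model$n_sims, stim_gt_rest_z = cmp$z))
}

#' Feature table for state classification
#'
#' Pivots a long-format timescale table into windows x channels features
#' plus a per-window state label, excluding windows with any missing or
#' non-converged estimate.
#'
#' @param intTable long-format table from [windowedINT()].
#' @param measure `"tau_s"` or `"acw0_s"`.
#' @return list `x` (matrix), `y` (factor of state labels).
#' @export
featureTable <- function(intTable, measure = "tau_s") {
  v <- intTable[[measure]]
  v[!intTable$converged] <- NA
  wide <- tapply(v, list(intTable$window, intTable$channel), mean)
  states <- tapply(as.character(intTable$state), intTable$window,
                   function(s) s[1])
  keep <- stats::complete.cases(wide) & !is.na(states) & states != "mixed"
  list(x = wide[keep, , drop = FALSE], y = factor(states[keep]))
}
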