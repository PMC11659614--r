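#' Percent change from rest to a task/behavioral state
#'
#' `((task - rest) / rest) * 100`. Vectorized; undefined (NA, with a
#' warning) where the rest value is not positive.
#'
#' @param rest,task numeric vectors (recycled to common length).
#' @return numeric vector of percent changes.
#' @examples
#' percentChange(2, 3)   # 50
#' percentChange(4, 3)   # -25
#' @export
percentChange <- function(rest, task) {
  bad <- !is.na(rest) & rest <= 0
  if (any(bad)) warning(sum(bad), " entries with rest value <= 0 set to NA")
  out <- (task - rest) / rest * 100
  out[bad] <- NA_real_
  out
}

#' Per-channel rest/task summary of windowed timescales
#'
#' Aggregates a windowed timescale table (see [windowedINT()]) into one
#' row per channel: mean rest value, mean task value, across-window SD of
#' the rest values, and the rest-to-task percent change of the mean.
#' Non-converged windows are excluded.
#'
#' @param intTable long-format table from [windowedINT()].
#' @param restState,taskState state labels to contrast.
#' @param measure `"tau_s"` or `"acw0_s"`.
#' @return data.frame `channel`, `rest_mean`, `task_mean`, `rest_sd`,
#'   `pct_change`.
#' @export
restTaskSummary <- function(intTable, restState = "rest",
                            taskState = "task", measure = "tau_s") {
  tab <- intTable[intTable$converged & !is.na(intTable[[measure]]), ]
  agg <- function(state, f) {
    sub <- tab[tab$state == state, ]
    vapply(split(sub[[measure]], sub$channel), f, 0)
  }
  rm_ <- agg(restState, mean)
  tm <- agg(taskState, mean)
  rs <- agg(restState, sd)
  ch <- intersect(names(rm_), names(tm))
  data.frame(channel = ch, rest_mean = rm_[ch], task_mean = tm[ch],
             rest_sd = rs[ch],
             pct_change = percentChange(rm_[ch], tm[ch]),
             row.names = NULL)
}

#' Spearman correlation with t-approximate p value
#'
#' Rank correlation with average-rank tie handling; two-sided p from the
#' t approximation on `df = n - 2`.
#'
#' @param x,y numeric vectors; pairs with NA are dropped.
#' @return list `rho`, `p`, `df`, `n`.
#' @export
spearmanCor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rho <- suppressWarnings(cor(rank(x), rank(y)))
  if (is.na(rho)) stop("correlation undefined (all-tied input)")
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), df = n - 2, n = n)
}

#' Correlation between resting variability and rest-task change
#'
#' Spearman correlation, across channels/ROIs, between the across-window
#' SD of the resting timescale and the rest-to-task percent change of its
#' mean -- the rest-task modulation statistic.
#'
#' @param summary data.frame from [restTaskSummary()] (columns `rest_sd`,
#'   `pct_change`).
#' @return list `rho`, `p`, `df`, `n`.
#' @export
variabilityChangeCorrelation <- function(summary) {
  spearmanCor(summary$rest_sd, summary$pct_change)
}

#' Two-group Wilcoxon comparison with effect size
#'
#' Rank-sum (unpaired) or signed-rank (paired) comparison reported as a
#' standard-normal `z` (continuity-corrected, tie-corrected variance), a
#' two-sided `p`, and an effect size: the rank-biserial correlation by
#' default (bounded in \[-1, 1\]; complete separation of `a` above `b`
#' gives +1), or `z/sqrt(min(n))` as a configurable variant. Zero paired
#' differences are dropped. For small samples (both groups < 10, no
#' ties) the p value uses the exact distribution.
#'
#' @param a,b numeric vectors; for `paired = TRUE` equal length.
#' @param paired logical.
#' @param effect `"rank-biserial"` or `"z-normalized"`.
#' @return list `z`, `p`, `effect_r`, `n` (per-group sizes), `method`.
#' @examples
#' compareGroups(rnorm(50, 1), rnorm(50), paired = FALSE)$p
#' @export
compareGroups <- function(a, b, paired = FALSE,
                          effect = c("rank-biserial", "z-normalized")) {
  effect <- match.arg(effect)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group")
  if (length(a) < 5 || length(b) < 5)
    warning("fewer than 5 observations in a group")
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must have equal length")
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      return(list(z = 0, p = 1, effect_r = 0,
                  n = c(length(a), length(b)), method = "signed-rank"))
    }
    rk <- rank(abs(d))
    wpos <- sum(rk[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- contZ(wpos, mu, sqrt(sig2))
    rb <- (wpos - (n * (n + 1) / 2 - wpos)) / (n * (n + 1) / 2)
    p <- if (n < 10 && !any(duplicated(abs(d)))) {
      stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    } else 2 * pnorm(-abs(z))
    er <- if (effect == "rank-biserial") rb else z / sqrt(n)
    list(z = z, p = p, effect_r = er, n = c(length(a), length(b)),
         method = "signed-rank")
  } else {
    n1 <- length(a); n2 <- length(b); n <- n1 + n2
    rk <- rank(c(a, b))
    u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- contZ(u1, mu, sqrt(sig2))
    rb <- 2 * u1 / (n1 * n2) - 1
    p <- if (n1 < 10 && n2 < 10 && !any(duplicated(c(a, b)))) {
      stats::wilcox.test(a, b, exact = TRUE)$p.value
    } else 2 * pnorm(-abs(z))
    er <- if (effect == "rank-biserial") rb else z / sqrt(min(n1, n2))
    list(z = z, p = p, effect_r = er, n = c(n1, n2), method = "rank-sum")
  }
}

# continuity-corrected standardization toward zero
contZ <- function(w, mu, s) {
  if (s == 0) return(0)
  d <- w - mu
  (d - sign(d) * 0.5) / s
}

#' MAD-based outlier screening
#'
#' Keeps values within `k` scaled median absolute deviations of the
#' median (scale factor 1.4826, consistent for the normal). With zero
#' MAD, only exact-median values are kept (with a warning).
#'
#' @param x numeric vector.
#' @param k number of scaled MADs (default 3).
#' @return list `values` (kept entries) and `mask` (logical keep flags,
#'   NA entries are `FALSE`).
#' @examples
#' removeOutliersMAD(c(1, 2, 3, 4, 100))$values
#' @export
removeOutliersMAD <- function(x, k = 3) {
  if (sum(!is.na(x)) < 3) stop("need at least 3 non-missing values")
  med <- median(x, na.rm = TRUE)
  m <- mad(x, na.rm = TRUE)  # already scaled by 1.4826
  if (m == 0) {
    warning("MAD is zero; keeping exact-median values only")
    mask <- !is.na(x) & x == med
  } else {
    mask <- !is.na(x) & abs(x - med) <= k * m
  }
  list(values = x[mask], mask = mask)
}

#' Holm step-down multiple-comparison correction
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"` (the
#' Bonferroni-Holm step-down).
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values.
#' @export
holmCorrect <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Clogg comparison of a coefficient across nested models
#'
#' Compares the coefficient of the same predictor estimated in a reduced
#' model (`coef1`, `se1`) and in a model with an added covariate
#' (`coef2`, `se2`) fitted to the same data. For nested models the
#' reduced-model estimator is efficient under the null, so the variance
#' of the difference is the difference of sampling variances:
#' `z = (coef1 - coef2) / sqrt(se2^2 - se1^2)` with a two-sided normal p
#' (Clogg, Petkova & Haritou 1995).
#'
#' @param coef1,se1 coefficient and SE in the reduced model.
#' @param coef2,se2 the same predictor's coefficient and SE in the model
#'   with the added covariate.
#' @return list `z`, `p`, `coef1`, `coef2`, `se_diff`.
#' @examples
#' cloggCompare(0.5, 0.1, 0.45, 0.12)
#' @export
cloggCompare <- function(coef1, se1, coef2, se2) {
  v <- se2^2 - se1^2
  if (coef1 == coef2) {
    return(list(z = 0, p = 1, coef1 = coef1, coef2 = coef2,
                se_diff = sqrt(max(v, 0))))
  }
  if (v <= 0)
    stop("non-positive variance estimate for the coefficient difference ",
         sprintf("(se2^2 - se1^2 = %.3g); ", v),
         "are the models nested on the same data?")
  z <- (coef1 - coef2) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)), coef1 = coef1, coef2 = coef2,
       se_diff = sqrt(v))
}
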