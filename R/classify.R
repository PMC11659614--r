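#' Nested cross-validated behavioral-state classification
#'
#' Classifies behavioral states from whole-brain timescale features with
#' nested cross-validation: outer folds (stratified, sampling without
#' replacement, so the aggregated outer test sets tile the whole data
#' set) estimate generalization; hyperparameters are tuned on inner
#' folds of each outer training set only, so no test information leaks
#' into tuning. Models: an RBF-kernel margin classifier (`"svm"`,
#' tuning cost and kernel scale gamma) or ridge-penalized multinomial
#' logistic regression (`"logistic"`, tuning the regularization strength
#' lambda). Features are z-scored using training-fold statistics only.
#' Hyperparameters are drawn log-uniformly at random, `budget` candidate
#' points per outer fold.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y state labels (coercible to factor, >= 2 classes).
#' @param model `"svm"` or `"logistic"`.
#' @param outer,inner numbers of outer and inner folds (default 10/10).
#' @param budget tuning evaluations per outer fold (default 30).
#' @param seed integer seed for fold assignment and candidate draws.
#' @return list of class `"classifierReport"`:
#'   `confusion` (aggregated outer-test counts, rows = true),
#'   `accuracy` (overall), `class_accuracy`, `roc` (per-class averaged
#'   one-vs-all curves from [averageROC()]), `fold_accuracy`,
#'   `fold_params`, `n`.
#' @examples
#' x <- rbind(matrix(rnorm(200), 100), matrix(rnorm(200, 3), 100))
#' y <- rep(c("a", "b"), each = 100)
#' rep <- nestedCVClassify(x, y, outer = 3, inner = 3, budget = 5, seed = 1)
#' rep$accuracy
#' @export
nestedCVClassify <- function(x, y, model = c("svm", "logistic"),
                             outer = 10, inner = 10, budget = 30,
                             seed = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("labels must span at least 2 classes")
  if (nrow(x) < outer * nlevels(y))
    stop("too few samples for ", outer, " stratified outer folds")
  withSeed(seed, {
    fold <- stratifiedFolds(y, outer)
    preds <- factor(rep(NA, length(y)), levels = levels(y))
    scores <- matrix(NA_real_, length(y), nlevels(y),
                     dimnames = list(NULL, levels(y)))
    foldAcc <- numeric(outer)
    foldPar <- vector("list", outer)
    rocFolds <- replicate(nlevels(y), list(), simplify = FALSE)
    names(rocFolds) <- levels(y)
    for (k in seq_len(outer)) {
      tr <- fold != k; te <- !tr
      if (nlevels(droplevels(y[tr])) < nlevels(y))
        stop("class absent from a training fold; reduce 'outer'")
      ctr <- colMeans(x[tr, , drop = FALSE])
      scl <- apply(x[tr, , drop = FALSE], 2, sd)
      scl[scl == 0] <- 1
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
      cand <- drawCandidates(model, budget, ncol(x))
      innerFold <- stratifiedFolds(y[tr], inner)
      cvAcc <- vapply(seq_len(nrow(cand)), function(j) {
        innerCVAccuracy(xs[tr, , drop = FALSE], y[tr], innerFold,
                        model, cand[j, , drop = FALSE])
      }, 0)
      best <- cand[which.max(cvAcc), , drop = FALSE]
      foldPar[[k]] <- c(as.list(best), cv_accuracy = max(cvAcc))
      fit <- fitModel(xs[tr, , drop = FALSE], y[tr], model, best,
                      probabilities = TRUE)
      pr <- predictModel(fit, xs[te, , drop = FALSE], model, levels(y))
      preds[te] <- pr$class
      scores[te, ] <- pr$prob
      foldAcc[k] <- mean(pr$class == y[te])
      for (cl in levels(y)) {
        truth <- y[te] == cl
        if (length(unique(truth)) < 2) {
          warning("fold ", k, ": single class in test set for '", cl,
                  "'; ROC fold skipped")
          next
        }
        r <- pROC::roc(response = truth, predictor = pr$prob[, cl],
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
        rocFolds[[cl]][[length(rocFolds[[cl]]) + 1L]] <-
          list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
      }
    }
    conf <- table(true = y, predicted = preds)
    structure(list(
      confusion = conf,
      accuracy = mean(preds == y),
      class_accuracy = diag(prop.table(conf, 1)),
      roc = lapply(rocFolds, function(fc)
        if (length(fc) >= 2) averageROC(fc) else NULL),
      fold_accuracy = foldAcc,
      fold_params = foldPar,
      n = length(y)), class = "classifierReport")
  })
}

drawCandidates <- function(model, budget, d) {
  if (model == "svm") {
    data.frame(cost = 10^runif(budget, -2, 3),
               gamma = 10^runif(budget, log10(1 / d) - 2,
                                log10(1 / d) + 2))
  } else {
    data.frame(lambda = 10^runif(budget, -5, 1))
  }
}

innerCVAccuracy <- function(x, y, innerFold, model, par) {
  k <- max(innerFold)
  acc <- vapply(seq_len(k), function(j) {
    tr <- innerFold != j
    if (nlevels(droplevels(y[tr])) < nlevels(y)) return(NA_real_)
    fit <- fitModel(x[tr, , drop = FALSE], y[tr], model, par,
                    probabilities = FALSE)
    pr <- predictModel(fit, x[!tr, , drop = FALSE], model, levels(y),
                       probabilities = FALSE)
    mean(pr$class == y[!tr])
  }, 0)
  mean(acc, na.rm = TRUE)
}

fitModel <- function(x, y, model, par, probabilities = TRUE) {
  if (model == "svm") {
    e1071::svm(x, y, kernel = "radial", cost = par$cost, gamma = par$gamma,
               probability = probabilities, scale = FALSE)
  } else {
    glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                   lambda = par$lambda)
  }
}

predictModel <- function(fit, x, model, lev, probabilities = TRUE) {
  if (model == "svm") {
    pr <- predict(fit, x, probability = probabilities)
    prob <- NULL
    if (probabilities) {
      prob <- attr(pr, "probabilities")[, lev, drop = FALSE]
    }
    list(class = factor(as.character(pr), levels = lev), prob = prob)
  } else {
    prob <- predict(fit, x, type = "response")[, , 1]
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1,
                                           dimnames = list(NULL, names(prob)))
    prob <- prob[, lev, drop = FALSE]
    cls <- factor(lev[max.col(prob)], levels = lev)
    list(class = cls, prob = prob)
  }
}

#' Average one-vs-all ROC curves across folds
#'
#' Interpolates each fold's ROC curve onto a common 101-point
#' false-positive-rate grid and reports the pointwise mean and SD of the
#' true-positive rate together with the AUC of the mean curve (trapezoid
#' rule).
#'
#' @param foldCurves list of per-fold curves, each a list with numeric
#'   `fpr` and `tpr` (need not share a grid).
#' @return list `fpr` (grid), `tpr_mean`, `tpr_sd`, `auc`, `n_folds`.
#' @export
averageROC <- function(foldCurves) {
  if (length(foldCurves) < 2) stop("need at least 2 fold curves")
  grid <- seq(0, 1, length.out = 101L)
  tprs <- vapply(foldCurves, function(cv) {
    o <- order(cv$fpr, cv$tpr)
    fpr <- c(0, cv$fpr[o], 1)
    tpr <- c(0, cv$tpr[o], 1)
    approx(fpr, tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(101L))
  m <- rowMeans(tprs)
  list(fpr = grid, tpr_mean = m, tpr_sd = apply(tprs, 1, sd),
       auc = pracma::trapz(grid, m), n_folds = length(foldCurves))
}

#' @export
print.classifierReport <- function(x, ...) {
  cat("Nested-CV classifier report:", x$n, "samples,",
      nrow(x$confusion), "classes\n")
  cat(sprintf("  overall accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}
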