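# Evaluation: classification and regression metrics with nonparametric
# bootstrap confidence intervals, retrospective conversion analysis
# (sMCI vs pMCI), and the pre-training learning-curve protocol.

#' Generalized Matthews correlation coefficient from a confusion matrix
#'
#' Multiclass (R_k) covariance form; the zero-denominator convention
#' returns 0 (e.g. a degenerate all-one-class predictor on a balanced
#' set).
#'
#' @param cm square confusion matrix (rows = truth, cols = predicted).
#' @export
mccFromConfusion <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

mccBinaryCounts <- function(yTrue, yPred) {
  cm <- table(factor(yTrue, levels = 0:1), factor(yPred, levels = 0:1))
  mccFromConfusion(cm)
}

# weighted-macro F1: per-class F1 (0 when precision+recall are both 0),
# weighted by true class support
f1Weighted <- function(cm) {
  cm <- as.matrix(cm)
  support <- rowSums(cm)
  f1 <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) == 0) 0 else tp / sum(cm[, k])
    rec <- if (support[k] == 0) 0 else tp / support[k]
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  sum(f1 * support) / sum(support)
}

# rank-based (Mann-Whitney) AUC; midranks handle ties
aucRank <- function(yTrue, scores) {
  pos <- yTrue == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

bootCi <- function(statFn, n, nBoot, level = 0.95) {
  if (nBoot <= 0L) return(c(NA_real_, NA_real_))
  reps <- vapply(seq_len(nBoot), function(b) {
    statFn(sample.int(n, n, replace = TRUE))
  }, numeric(1))
  stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}

#' Classification metrics report
#'
#' MCC (generalized multiclass form), weighted-macro F1, AUC (binary, from
#' scores), accuracy, and the confusion matrix, with optional
#' nonparametric bootstrap confidence intervals. With a single observed
#' class, MCC and AUC are undefined and reported as NA.
#'
#' @param yTrue,yPred aligned label vectors (factors or characters).
#' @param yScores optional score vector (binary: probability/score of the
#'   positive class, taken as the second factor level).
#' @param nBoot bootstrap replicates for 95% CIs (default 2000; 0
#'   disables).
#' @return a \code{MetricsReport} list.
#' @export
classificationMetrics <- function(yTrue, yPred, yScores = NULL,
                                  nBoot = 2000L) {
  lev <- if (is.factor(yTrue)) levels(yTrue) else sort(unique(c(yTrue, yPred)))
  yT <- factor(yTrue, levels = lev)
  yP <- factor(yPred, levels = lev)
  cm <- table(truth = yT, predicted = yP)
  singleClass <- length(unique(as.integer(yT))) < 2L
  mcc <- if (singleClass) NA_real_ else mccFromConfusion(cm)
  f1 <- f1Weighted(cm)
  acc <- mean(yT == yP)
  auc <- NULL
  if (!is.null(yScores) && length(lev) == 2L) {
    yb <- as.integer(yT) - 1L
    auc <- if (singleClass) NA_real_ else aucRank(yb, yScores)
  }
  ci <- list()
  if (nBoot > 0L && !singleClass) {
    n <- length(yT)
    ci$mcc <- bootCi(function(i)
      mccFromConfusion(table(factor(yT[i], lev), factor(yP[i], lev))),
      n, nBoot)
    ci$f1 <- bootCi(function(i)
      f1Weighted(table(factor(yT[i], lev), factor(yP[i], lev))), n, nBoot)
    if (!is.null(auc) && !is.na(auc))
      ci$auc <- bootCi(function(i)
        aucRank(as.integer(yT[i]) - 1L, yScores[i]), n, nBoot)
  }
  structure(list(kind = "classification", mcc = mcc, f1 = f1, auc = auc,
                 accuracy = acc, confusion = cm, ci = ci, n = length(yT)),
            class = "MetricsReport")
}

#' Regression metrics report
#'
#' Explained variance EV = 1 - Var(y - yhat)/Var(y) and Pearson's
#' correlation, with optional bootstrap confidence intervals.
#'
#' @param yTrue,yPred aligned numeric vectors (n >= 2).
#' @param nBoot bootstrap replicates (default 2000; 0 disables).
#' @return a \code{MetricsReport} list.
#' @export
regressionMetrics <- function(yTrue, yPred, nBoot = 2000L) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 2L)
  if (stats::var(yTrue) == 0) stop("zero-variance targets")
  ev <- 1 - stats::var(yTrue - yPred) / stats::var(yTrue)
  r <- if (stats::var(yPred) == 0) NA_real_ else stats::cor(yTrue, yPred)
  ci <- list()
  if (nBoot > 0L) {
    n <- length(yTrue)
    ci$ev <- bootCi(function(i) {
      if (stats::var(yTrue[i]) == 0) return(NA_real_)
      1 - stats::var(yTrue[i] - yPred[i]) / stats::var(yTrue[i])
    }, n, nBoot)
    ci$r <- bootCi(function(i) {
      if (stats::var(yTrue[i]) == 0 || stats::var(yPred[i]) == 0)
        return(NA_real_)
      stats::cor(yTrue[i], yPred[i])
    }, n, nBoot)
  }
  structure(list(kind = "regression", ev = ev, r = r, ci = ci,
                 n = length(yTrue)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport (", x$kind, ", n = ", x$n, ")\n", sep = "")
  if (x$kind == "classification") {
    cat("  MCC", format(x$mcc, digits = 3),
        " F1(weighted)", format(x$f1, digits = 3),
        " accuracy", format(x$accuracy, digits = 3))
    if (!is.null(x$auc)) cat("  AUC", format(x$auc, digits = 3))
    cat("\n")
  } else {
    cat("  EV", format(x$ev, digits = 3), " Pearson r",
        format(x$r, digits = 3), "\n")
  }
  invisible(x)
}

#' Retrospective conversion metrics (sMCI vs pMCI)
#'
#' Restricts to subjects with MCI at baseline; a subject is a true
#' progressor (pMCI) iff their diagnosis within the horizon is dementia,
#' and predicted pMCI iff the predicted horizon diagnosis is dementia
#' (score = predicted dementia probability). Reports binary metrics on
#' this derived task; baseline-CN subjects never enter the evaluation.
#'
#' @param baselineDx baseline diagnosis per subject.
#' @param trueDx true diagnosis at the horizon.
#' @param predDx predicted diagnosis at the horizon.
#' @param pDementia predicted dementia probability (scores for AUC).
#' @param nBoot bootstrap replicates.
#' @return a \code{MetricsReport} restricted to baseline-MCI subjects.
#' @export
conversionMetrics <- function(baselineDx, trueDx, predDx, pDementia = NULL,
                              nBoot = 2000L) {
  keep <- baselineDx == "MCI" & !is.na(trueDx) & !is.na(predDx)
  if (!any(keep)) stop("no baseline-MCI subjects with horizon diagnoses")
  yT <- factor(ifelse(trueDx[keep] == "dementia", "pMCI", "sMCI"),
               levels = c("sMCI", "pMCI"))
  yP <- factor(ifelse(predDx[keep] == "dementia", "pMCI", "sMCI"),
               levels = c("sMCI", "pMCI"))
  classificationMetrics(yT, yP,
                        yScores = if (!is.null(pDementia)) pDementia[keep],
                        nBoot = nBoot)
}

#' Pre-training learning curve
#'
#' Repeats the full pretrain/freeze/fuse/fine-tune pipeline while
#' subsampling the pre-training pool to varying proportions, recording the
#' test Pearson correlation of a quantitative decline task for each
#' (proportion, repeat). Repeats are independently seeded; proportions
#' leaving fewer than 10 pre-training subjects are skipped with a warning.
#'
#' @param prepared a prepared modeling dataset from
#'   \code{\link{prepareCohortData}}.
#' @param proportions pre-training data proportions in (0, 1].
#' @param nRepeats repeats per proportion (>= 2).
#' @param task regression task name (default \code{"slope_memory"}).
#' @param state a \code{\link{trainState}} shared by all runs (no
#'   hyperparameter optimization).
#' @param seed base seed; repeat r at proportion i uses a derived seed.
#' @return data.frame with proportion, repeat, seed, and test correlation;
#'   aggregate with \code{aggregate(cor ~ proportion, ...)}.
#' @export
learningCurve <- function(prepared, proportions = c(0.1, 0.25, 0.5, 1),
                          nRepeats = 10L, task = "slope_memory",
                          state = trainState(), seed = 1L) {
  stopifnot(all(proportions > 0), all(proportions <= 1), nRepeats >= 2L)
  out <- data.frame()
  for (pi in seq_along(proportions)) {
    p <- proportions[pi]
    for (r in seq_len(nRepeats)) {
      runSeed <- as.integer(seed) + 1000L * pi + r
      res <- runDeclinePipeline(prepared, task = task, taskKind = "regression",
                                state = state, seed = runSeed,
                                pretrainProportion = p)
      if (is.null(res)) {
        warning("proportion ", p, " leaves too few pre-training subjects; ",
                "skipped")
        next
      }
      out <- rbind(out, data.frame(proportion = p, repeatIdx = r,
                                   seed = runSeed, cor = res$metrics$r))
    }
  }
  out
}
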