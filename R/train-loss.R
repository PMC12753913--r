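#' Default multitask pre-training target set
#'
#' Three 3-class diagnosis tasks (current diagnosis, diagnosis at 2 years,
#' diagnosis at 4 years) and four regression tasks (z-scored per-domain
#' decline slopes), all with weight 1 and Huber delta 2.5. Binary tasks are
#' supported by the loss but the pre-training set contains none; binary
#' decline labels are targets of the fine-tuning stage.
#'
#' @param domains cognitive domains for the slope regression tasks.
#' @return a \code{\link{TaskSpec}}.
#' @export
defaultPretrainTaskSpec <- function(domains = c("memory", "language",
                                                "visuospatial", "executive")) {
  cls <- c("CN", "MCI", "dementia")
  mc <- list(dx_now = cls, dx_2y = cls, dx_4y = cls)
  reg <- paste0("slope_", domains)
  taskSpec(binary = character(0), multiclass = mc, regression = reg)
}

#' Construct a TaskSpec
#'
#' @param binary names of binary tasks.
#' @param multiclass named list mapping task name to class labels.
#' @param regression names of regression tasks.
#' @param weights named nonnegative weights (default 1 for every task).
#' @param huberDelta Huber loss delta (default 2.5).
#' @export
taskSpec <- function(binary = character(0), multiclass = list(),
                     regression = character(0), weights = NULL,
                     huberDelta = 2.5) {
  nm <- c(binary, names(multiclass), regression)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(nm)), nm)
  new("TaskSpec", binary = binary, multiclass = multiclass,
      regression = regression, weights = weights, huberDelta = huberDelta)
}

huberLoss <- function(r, delta) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

huberGrad <- function(r, delta) {
  pmin(pmax(r, -delta), delta)
}

# numerically stable binary cross-entropy with logits
bceLoss <- function(z, y) pmax(z, 0) - y * z + log1p(exp(-abs(z)))

softmaxRows <- function(z) {
  z <- exp(sweep(z, 1L, apply(z, 1L, max)))
  z / rowSums(z)
}

#' Masked multitask loss
#'
#' Computes the pre-training objective: a weighted sum of per-task losses
#' (binary cross-entropy for binary tasks, categorical cross-entropy for
#' multiclass tasks, Huber loss with the spec's delta for regression tasks),
#' where each task loss is the mean over the task's observed entries only.
#' Entries whose ground truth is unavailable are masked out; a task with no
#' observed entries contributes 0.
#'
#' @param preds named list of prediction matrices: n x 1 logits (binary),
#'   n x k logits (multiclass), n x 1 values (regression).
#' @param targets named list: 0/1 vectors (binary), integer class indices
#'   (multiclass), numeric values (regression). Unobserved entries may be NA.
#' @param masks named list of logical vectors (TRUE = observed). NA targets
#'   are additionally treated as unobserved.
#' @param spec a \code{\link{TaskSpec}}.
#' @return list with \code{total} (scalar) and \code{perTask} (named vector
#'   of unweighted per-task means).
#' @export
maskedMultitaskLoss <- function(preds, targets, masks, spec) {
  r <- maskedLossGrad(preds, targets, masks, spec, wantGrad = FALSE)
  list(total = r$total, perTask = r$perTask)
}

maskedLossGrad <- function(preds, targets, masks, spec, wantGrad = TRUE) {
  nm <- taskNames(spec)
  if (!all(nm %in% names(preds)) || !all(nm %in% names(targets)))
    stop("predictions/targets do not cover the task specification")
  perTask <- stats::setNames(numeric(length(nm)), nm)
  gpreds <- list()
  w <- spec@weights
  for (tk in nm) {
    p <- preds[[tk]]
    y <- targets[[tk]]
    obs <- masks[[tk]] %||% rep(TRUE, length(y))
    obs <- obs & !is.na(y)
    n <- nrow(p)
    g <- matrix(0, n, ncol(p))
    k <- sum(obs)
    if (k == 0L) {
      perTask[tk] <- 0
    } else if (tk %in% spec@binary) {
      z <- p[obs, 1L]
      perTask[tk] <- mean(bceLoss(z, y[obs]))
      if (wantGrad)
        g[obs, 1L] <- (1 / (1 + exp(-z)) - y[obs]) / k
    } else if (tk %in% names(spec@multiclass)) {
      zs <- p[obs, , drop = FALSE]
      pr <- softmaxRows(zs)
      yi <- y[obs]
      perTask[tk] <- mean(-log(pmax(pr[cbind(seq_len(k), yi)], 1e-12)))
      if (wantGrad) {
        gg <- pr
        gg[cbind(seq_len(k), yi)] <- gg[cbind(seq_len(k), yi)] - 1
        g[obs, ] <- gg / k
      }
    } else {
      res <- p[obs, 1L] - y[obs]
      perTask[tk] <- mean(huberLoss(res, spec@huberDelta))
      if (wantGrad)
        g[obs, 1L] <- huberGrad(res, spec@huberDelta) / k
    }
    if (wantGrad) gpreds[[tk]] <- g * w[tk]
  }
  list(total = sum(w[nm] * perTask), perTask = perTask, gpreds = gpreds)
}
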