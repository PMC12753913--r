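# Training machinery: subject-level data splits, the optimization schedule
# (Adam, learning rate halved every 20% of epochs, early stopping with
# patience equal to 10% of epochs), masked multitask pre-training of
# modality encoders, and frozen-encoder fusion fine-tuning.

#' Split a cohort into modeling and pre-training partitions
#'
#' Modeling subjects are split 60/10/30 into train/validation/test,
#' stratified by baseline diagnosis; the pre-training pool (every subject
#' with imaging data except modeling-test subjects) is split 85/15 into
#' pre-training train/validation. No test subject ever enters a
#' pre-training split, and all splits are at the subject level.
#'
#' @param cohort a \code{\link{SyntheticCohort-class}}.
#' @param seed integer seed (deterministic assignment).
#' @return list: \code{modeling} (named character vector,
#'   train/val/test), \code{pretrain} (named, train/val).
#' @export
splitCohort <- function(cohort, seed = 1L) {
  mid <- modelingIds(cohort)
  if (length(mid) < 10L)
    stop("modeling subset has ", length(mid), " subjects; need at least 10")
  set.seed(as.integer(seed))
  baseDx <- vapply(cohort@subjects, function(s) s$visits$diagnosis[1L],
                   character(1))
  names(baseDx) <- subjectIds(cohort)
  assign <- character(0)
  for (dx in unique(baseDx[mid])) {
    ids <- sample(mid[baseDx[mid] == dx])
    k <- length(ids)
    nTr <- round(0.6 * k)
    nVa <- round(0.1 * k)
    lab <- c(rep("train", nTr), rep("val", nVa),
             rep("test", k - nTr - nVa))
    assign[ids] <- lab
  }
  pool <- setdiff(subjectIds(cohort), names(assign)[assign == "test"])
  pool <- sample(pool)
  nTr <- round(0.85 * length(pool))
  pre <- stats::setNames(c(rep("train", nTr),
                           rep("val", length(pool) - nTr)), pool)
  list(modeling = assign[mid], pretrain = pre)
}

#' Learning rate at a given epoch
#'
#' The schedule halves the learning rate every 20% of the total number of
#' epochs: lr(e) = lr0 * 0.5^floor(5e/E) for 0 <= e < E (reductions fire
#' at 20/40/60/80% of training; none at epoch 0).
#'
#' @param e epoch index (0-based).
#' @param E total number of epochs.
#' @param lr0 initial learning rate.
#' @export
lrAtEpoch <- function(e, E, lr0) {
  if (E <= 0) stop("total epochs must be positive")
  stopifnot(all(e >= 0), all(e < E))
  lr0 * 0.5^floor(5 * e / E)
}

#' Optimization settings
#'
#' @param lr0 initial Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs total epochs E; the scheduler and the early-stopping
#'   patience (ceil(0.1 E), strict improvement in validation loss, best
#'   weights restored) derive from it.
#' @export
trainState <- function(lr0 = 1e-3, batchSize = 32L, epochs = 30L) {
  list(lr0 = lr0, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs),
       patience = as.integer(ceiling(0.1 * epochs)))
}

subsetInputs <- function(inputs, idx) {
  if (is.matrix(inputs)) inputs[idx, , drop = FALSE] else inputs[idx]
}

subsetTargets <- function(targets, masks, idx) {
  list(targets = lapply(targets, function(v) v[idx]),
       masks = lapply(masks, function(v) v[idx]))
}

#' Pre-train a modality encoder with the masked multitask loss
#'
#' Trains an embedding model plus the multitask pre-training head on one
#' modality's inputs (subjects missing other modalities are still usable
#' here), minimizing the weighted sum of masked per-task losses. Training
#' follows the package schedule (Adam, learning-rate halving, early
#' stopping on validation loss with best-epoch restore). The returned
#' encoder is frozen: fine-tuning never updates it.
#'
#' @param inputs matrix (tabular) or list (volumes / graph node-feature
#'   matrices), one entry per subject.
#' @param targets,masks per-task target values and observation masks (see
#'   \code{\link{maskedMultitaskLoss}}).
#' @param spec a \code{\link{TaskSpec}}.
#' @param config an \code{\link{embeddingModelConfig}}.
#' @param inputSpec input description for
#'   \code{\link{buildEmbeddingModel}}.
#' @param trainIdx,valIdx row indices of the pre-training train and
#'   validation subjects.
#' @param state a \code{\link{trainState}}.
#' @param seed seed for initialization and batch shuffling.
#' @return list: \code{encoder} (frozen \code{ndEmbeddingModel}),
#'   \code{head}, \code{history} (per-epoch train/val loss), and the index
#'   of the restored best epoch.
#' @export
pretrainModality <- function(inputs, targets, masks, spec, config, inputSpec,
                             trainIdx, valIdx, state = trainState(),
                             seed = 1L) {
  if (length(trainIdx) == 0L) stop("empty pre-training dataset")
  encoder <- buildEmbeddingModel(config, inputSpec, seed = seed)
  head <- buildPretrainHead(config$embeddingDim, spec,
                            seed = as.integer(seed) + 1L)
  joint <- list(type = "pretrain",
                layers = list(enc = encoder$net, head = head$net))
  opt <- adamInit(joint)
  E <- state$epochs
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train = numeric(0), val = numeric(0))
  best <- list(val = Inf, joint = joint, epoch = -1L)
  wait <- 0L
  set.seed(as.integer(seed) + 2L)
  evalLoss <- function(joint, idx) {
    encoder$net <- joint$layers$enc
    r <- encoderForward(encoder, subsetInputs(inputs, idx),
                        training = FALSE)
    head$net <- joint$layers$head
    ph <- mtHeadForward(head, r$emb, training = FALSE)
    st <- subsetTargets(targets, masks, idx)
    maskedMultitaskLoss(ph$preds, st$targets, st$masks, spec)$total
  }
  for (e in 0:(E - 1L)) {
    lr <- lrAtEpoch(e, E, state$lr0)
    ord <- sample(trainIdx)
    nb <- ceiling(length(ord) / state$batchSize)
    epochLoss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * state$batchSize + 1L):
                 min(b * state$batchSize, length(ord))]
      encoder$net <- joint$layers$enc
      fe <- encoderForward(encoder, subsetInputs(inputs, idx),
                           training = TRUE)
      joint$layers$enc <- fe$model$net
      head$net <- joint$layers$head
      fh <- mtHeadForward(head, fe$emb, training = TRUE)
      joint$layers$head <- fh$head$net
      st <- subsetTargets(targets, masks, idx)
      lg <- maskedLossGrad(fh$preds, st$targets, st$masks, spec)
      if (!is.finite(lg$total))
        stop("divergence (non-finite loss) at epoch ", e)
      epochLoss <- epochLoss + lg$total * length(idx)
      bh <- mtHeadBackward(fh$head, fh$caches, lg$gpreds)
      fe$model$net <- joint$layers$enc
      be <- encoderBackward(fe$model, fe$caches, bh$gEmb)
      grad <- list(gpar = NULL,
                   glayers = list(enc = be, head = bh))
      upd <- adamStep(joint, grad, opt, lr)
      joint <- upd$mod
      opt <- upd$state
    }
    valLoss <- if (length(valIdx) > 0L) evalLoss(joint, valIdx)
      else epochLoss / length(ord)
    history <- rbind(history,
                     data.frame(epoch = e, lr = lr,
                                train = epochLoss / length(ord),
                                val = valLoss))
    if (valLoss < best$val) {
      best <- list(val = valLoss, joint = joint, epoch = e)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > state$patience) break
    }
  }
  encoder$net <- best$joint$layers$enc
  encoder$frozen <- TRUE
  head$net <- best$joint$layers$head
  list(encoder = encoder, head = head, history = history,
       bestEpoch = best$epoch)
}

#' Fine-tune the attention fusion model on one task
#'
#' Embeds every subject once with the frozen modality encoders (their
#' parameters receive no gradient and are bitwise unchanged), then trains
#' the modality projections, the auxiliary encoder, the multi-head
#' attention layer and the fusion head on the requested task. Model
#' selection keeps the epoch with the best validation MCC (classification)
#' or explained variance (regression).
#'
#' @param encoders named list of frozen \code{ndEmbeddingModel}s.
#' @param inputs named list of per-modality inputs (matrix or list,
#'   aligned across modalities and subjects).
#' @param aux auxiliary feature matrix (n x t) or NULL.
#' @param y task targets: numeric (regression), 0/1 (binary), or integer
#'   class index (multiclass).
#' @param mask logical observation mask.
#' @param task task kind: \code{"regression"}, \code{"binary"},
#'   \code{"multiclass"}.
#' @param nClasses arity for multiclass tasks.
#' @param trainIdx,valIdx modeling train / validation row indices.
#' @param state a \code{\link{trainState}}.
#' @param dropout fusion dropout rate (attention weights and first head
#'   layer).
#' @param seed integer seed.
#' @return list: \code{model} (fitted fusion model), \code{embeddings}
#'   (per-modality matrices), \code{history}, \code{bestEpoch}.
#' @export
finetuneTask <- function(encoders, inputs, aux = NULL, y, mask = NULL,
                         task = c("regression", "binary", "multiclass"),
                         nClasses = 3L, trainIdx, valIdx,
                         state = trainState(), dropout = 0.1, seed = 1L) {
  task <- match.arg(task)
  if (length(valIdx) == 0L) stop("no validation subjects")
  if (is.null(mask)) mask <- !is.na(y)
  stopifnot(all(vapply(encoders, function(e) isTRUE(e$frozen), logical(1))))
  Z <- list()
  for (m in names(encoders))
    Z[[m]] <- encoderForward(encoders[[m]], inputs[[m]],
                             training = FALSE)$emb
  outDim <- switch(task, regression = 1L, binary = 1L,
                   multiclass = as.integer(nClasses))
  fusion <- buildFusionModel(
    vapply(Z, ncol, integer(1)),
    auxDim = if (!is.null(aux)) ncol(aux), outDim = outDim, task = task,
    dropout = dropout, seed = seed)
  spec1 <- switch(task,
    regression = taskSpec(regression = "y"),
    binary = taskSpec(binary = "y"),
    multiclass = taskSpec(multiclass = list(y = paste0("c", 1:nClasses))))
  opt <- adamInit(fusion$net)
  E <- state$epochs
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0), valMetric = numeric(0))
  best <- list(metric = -Inf, loss = Inf, net = fusion$net, epoch = -1L)
  bestLoss <- Inf     # early stopping watches validation loss
  wait <- 0L
  set.seed(as.integer(seed) + 3L)
  # decision threshold for binary tasks: match the training prevalence
  # (a fixed 0.5 logit cut degenerates under class imbalance)
  prevalence <- if (task == "binary")
    mean(y[trainIdx][mask[trainIdx] & !is.na(y[trainIdx])]) else NA
  evalMetric <- function(net, idx) {
    fusion$net <- net
    r <- fusionForward(fusion, lapply(Z, function(z) z[idx, , drop = FALSE]),
                       if (!is.null(aux)) aux[idx, , drop = FALSE],
                       training = FALSE)
    obs <- mask[idx] & !is.na(y[idx])
    yv <- y[idx][obs]
    out <- r$out[obs, , drop = FALSE]
    lg <- maskedLossGrad(list(y = r$out), list(y = y[idx]),
                         list(y = mask[idx]), spec1, wantGrad = FALSE)
    metric <- switch(task,
      regression = {
        ev <- 1 - stats::var(yv - out[, 1L]) / stats::var(yv)
        if (is.finite(ev)) ev else -Inf
      },
      binary = {
        cut <- stats::quantile(out[, 1L], 1 - prevalence, names = FALSE)
        pred <- as.integer(out[, 1L] > cut)
        m <- mccBinaryCounts(yv, pred)
        if (is.finite(m)) m else -Inf
      },
      multiclass = {
        pred <- max.col(out, ties.method = "first")
        cm <- table(factor(yv, levels = 1:nClasses),
                    factor(pred, levels = 1:nClasses))
        mccFromConfusion(cm)
      })
    list(loss = lg$total, metric = metric)
  }
  trainObs <- trainIdx[mask[trainIdx] & !is.na(y[trainIdx])]
  for (e in 0:(E - 1L)) {
    lr <- lrAtEpoch(e, E, state$lr0)
    ord <- sample(trainObs)
    nb <- ceiling(length(ord) / state$batchSize)
    epochLoss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * state$batchSize + 1L):
                 min(b * state$batchSize, length(ord))]
      r <- fusionForward(fusion,
                         lapply(Z, function(z) z[idx, , drop = FALSE]),
                         if (!is.null(aux)) aux[idx, , drop = FALSE],
                         training = TRUE)
      fusion <- r$model
      lg <- maskedLossGrad(list(y = r$out), list(y = y[idx]),
                           list(y = mask[idx]), spec1)
      if (!is.finite(lg$total)) stop("divergence at epoch ", e)
      epochLoss <- epochLoss + lg$total * length(idx)
      gb <- fusionBackward(fusion, r$caches, lg$gpreds$y, r$Tn)
      upd <- adamStep(fusion$net, gb, opt, lr)
      fusion$net <- upd$mod
      opt <- upd$state
    }
    ev <- evalMetric(fusion$net, valIdx)
    history <- rbind(history,
                     data.frame(epoch = e, train = epochLoss / length(ord),
                                val = ev$loss, valMetric = ev$metric))
    if (ev$metric > best$metric ||
        (ev$metric == best$metric && ev$loss < best$loss))
      best <- list(metric = ev$metric, loss = ev$loss, net = fusion$net,
                   epoch = e)
    if (ev$loss < bestLoss) {
      bestLoss <- ev$loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > state$patience) break
    }
  }
  fusion$net <- best$net
  threshold <- 0.5
  if (task == "binary") {
    rtr <- fusionForward(fusion,
                         lapply(Z, function(z) z[trainObs, , drop = FALSE]),
                         if (!is.null(aux)) aux[trainObs, , drop = FALSE],
                         training = FALSE)
    pTrain <- 1 / (1 + exp(-rtr$out[, 1L]))
    threshold <- stats::quantile(pTrain, 1 - prevalence, names = FALSE)
  }
  fusion$threshold <- threshold
  list(model = fusion, embeddings = Z, history = history,
       bestEpoch = best$epoch, threshold = threshold)
}
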