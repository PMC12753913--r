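# End-to-end wiring at desk scale: from a synthetic cohort to fitted
# composite models, decline targets, standardized modality features, and
# the pretrain -> freeze -> fuse -> fine-tune loop. All statistics that
# could leak (imputation fits, measurement models, reference medians,
# normative models, thresholds, target/input standardization, the
# connectivity graph) are fitted on non-test subjects only and carry
# provenance records.

#' Prepare a cohort for modeling
#'
#' Runs the full data side of the framework: item imputation, per-domain
#' one-factor composite models, reference-anchored rescaling, normative
#' age/education adjustment, decline slopes and thresholds, horizon
#' diagnosis targets, z-scored regression targets, ROI-tabular features
#' per modality, input standardization, the FDG connectivity graph, and
#' the subject-level splits. Everything is fitted on train and
#' pre-training subjects only and applied to all.
#'
#' @param cohort a \code{\link{SyntheticCohort-class}} with volumes.
#' @param seed split/assignment seed.
#' @param lambda graphical-lasso penalty for the connectivity graph.
#' @param battery battery spec used to generate the cohort.
#' @return a list ("preparedCohort") with features, targets, masks,
#'   splits, thresholds and fitted parameter objects.
#' @export
prepareCohortData <- function(cohort, seed = 1L, lambda = 0.3,
                              battery = defaultBatterySpec()) {
  atlas <- attr(cohort, "atlas")
  if (is.null(atlas)) stop("cohort has no volumes/atlas attached")
  split <- splitCohort(cohort, seed = seed)
  ids <- subjectIds(cohort)
  n <- length(ids)
  testIds <- names(split$modeling)[split$modeling == "test"]
  trainIds <- names(split$modeling)[split$modeling == "train"]
  fitIds <- setdiff(ids, testIds)

  visits <- cohortVisits(cohort)
  itemCols <- unlist(lapply(battery, `[[`, "items"), use.names = FALSE)
  fitRows <- visits$subject_id %in% fitIds
  completed <- imputeItems(visits[itemCols],
                           demographics = visits[c("age", "sex", "education")],
                           highMissingItem = "lang_bnt", fitRows = fitRows)
  scored <- visits[c("subject_id", "date_days", "diagnosis", "age", "sex",
                     "education")]

  domains <- names(battery)
  models <- list()
  scalers <- list()
  normModels <- list()
  subjMeta <- cohort@subjects
  names(subjMeta) <- ids
  sustainedCN <- vapply(subjMeta, function(s)
    all(s$visits$diagnosis == "CN"), logical(1))
  normativeIds <- ids[sustainedCN &
                      !vapply(subjMeta, function(s)
                        s$truth$amyloidPositive, logical(1))]
  normFitIds <- intersect(normativeIds, fitIds)
  for (dm in domains) {
    spec <- c(battery[[dm]], list(domain = dm))
    mm <- fitCompositeModel(completed[fitRows, , drop = FALSE], spec,
                            provenance = list(split = "train+pretrain",
                                              subjects = fitIds))
    raw <- scoreComposites(mm, completed)
    dx <- visits$diagnosis
    sc <- scalerParams(
      p50dem = stats::median(raw[fitRows & dx == "dementia"]),
      p50cn = stats::median(raw[fitRows & dx == "CN"]))
    scaled <- scaleComposite(raw, sc)
    normRows <- fitRows & visits$subject_id %in% normFitIds
    nmod <- fitNormativeModel(scaled[normRows], visits$age[normRows],
                              visits$education[normRows],
                              provenance = list(split = "train+pretrain",
                                                subjects = normFitIds))
    scored[[paste0("composite_", dm)]] <-
      normativeAdjust(nmod, scaled, visits$age, visits$education)
    models[[dm]] <- mm
    scalers[[dm]] <- sc
    normModels[[dm]] <- nmod
  }

  tt <- buildTargetTable(scored, ids, trainIds, domains = domains)
  normSlopes <- as.list(as.data.frame(
    tt$rawSlopes[intersect(normFitIds, rownames(tt$rawSlopes)), ,
                 drop = FALSE]))
  thresholds <- deriveDeclineThreshold(normSlopes)
  declineLabels <- list()
  for (dm in domains) {
    lab <- labelDecline(tt$rawSlopes[, dm], thresholds, domain = dm)
    declineLabels[[dm]] <- lab
    tk <- paste0("decline_", dm, "_binary")
    tt$targets[[tk]] <- as.integer(lab == "decliner")
    tt$masks[[tk]] <- !is.na(lab)
  }

  modalities <- c("mri", "fdg", "av45")
  feats <- list()
  hasMod <- matrix(FALSE, n, length(modalities),
                   dimnames = list(ids, modalities))
  for (m in modalities) {
    X <- matrix(NA_real_, n, 2L * nRois(atlas))
    rownames(X) <- ids
    for (s in seq_len(n)) {
      sub <- cohort@subjects[[s]]
      if (is.null(sub$volumes)) next
      v <- if (m == "mri") sub$volumes$mri else sub$volumes[[m]]
      if (is.null(v)) next
      X[s, ] <- phiTabular(v, atlas, modality = m)
      hasMod[s, m] <- TRUE
    }
    fitIdx <- which(ids %in% fitIds & hasMod[, m])
    mu <- colMeans(X[fitIdx, , drop = FALSE])
    sdv <- apply(X[fitIdx, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    feats[[m]] <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  }

  # FDG connectivity graph from CN/MCI non-test subjects
  baseDx <- vapply(cohort@subjects, function(s) s$visits$diagnosis[1L],
                   character(1))
  glRows <- which(ids %in% fitIds & hasMod[, "fdg"] &
                  baseDx %in% c("CN", "MCI"))
  fdgMeans <- feats$fdg[glRows, seq(1L, 2L * nRois(atlas), 2L), drop = FALSE]
  graph <- estimateConnectivityGraph(
    fdgMeans, lambda = lambda,
    provenance = list(split = "train+pretrain CN/MCI",
                      subjects = ids[glRows]))

  # auxiliary features: baseline adjusted composites + demographics,
  # standardized with train(+pretrain) statistics
  auxRaw <- matrix(NA_real_, n, length(domains) + 3L)
  rownames(auxRaw) <- ids
  colnames(auxRaw) <- c(paste0("composite_", domains), "age", "sex",
                        "education")
  for (s in seq_len(n)) {
    rows <- scored[scored$subject_id == ids[s], ]
    b <- rows[which.min(rows$date_days), ]
    auxRaw[s, ] <- c(unlist(b[paste0("composite_", domains)]), b$age, b$sex,
                     b$education)
  }
  fitIdx <- which(ids %in% fitIds)
  mu <- colMeans(auxRaw[fitIdx, ])
  sdv <- apply(auxRaw[fitIdx, ], 2L, stats::sd)
  sdv[sdv == 0] <- 1
  aux <- sweep(sweep(auxRaw, 2L, mu), 2L, sdv, "/")

  list(ids = ids, split = split, features = feats, hasModality = hasMod,
       aux = aux, targets = tt$targets, masks = tt$masks,
       rawSlopes = tt$rawSlopes, thresholds = thresholds,
       declineLabels = declineLabels, stdParams = tt$stdParams,
       measurementModels = models, scalers = scalers,
       normativeModels = normModels, graph = graph, scored = scored,
       baselineDx = stats::setNames(baseDx, ids), domains = domains)
}

#' Run the pretrain / freeze / fuse / fine-tune pipeline on one task
#'
#' Pre-trains one tabular encoder per imaging modality on the pre-training
#' pool (subjects with incomplete modalities included for the modalities
#' they have) with the masked multitask loss, freezes them, fine-tunes the
#' attention fusion model (with the auxiliary token) on the requested task
#' over the modeling split, and evaluates on the held-out test subjects.
#'
#' @param prepared output of \code{\link{prepareCohortData}}.
#' @param task target name, e.g. \code{"decline_memory_binary"},
#'   \code{"slope_memory"}, \code{"dx_2y"}.
#' @param taskKind \code{"binary"}, \code{"regression"} or
#'   \code{"multiclass"}.
#' @param state a \code{\link{trainState}} used for both stages.
#' @param seed integer seed for all randomness in the run.
#' @param fusionDropout dropout rate of the fusion stage (the desk-scale
#'   default is stronger than the source protocol's 0.1 because the
#'   fine-tuning sample is a fraction of the original study's).
#' @param pretrainProportion subsample fraction of the pre-training pool
#'   (learning-curve protocol); runs with fewer than 10 remaining
#'   pre-training subjects return NULL.
#' @param embeddingDim encoder embedding width.
#' @param nBoot bootstrap replicates for the test metrics report.
#' @return list: metrics (test \code{MetricsReport}), predictions, test
#'   ids, fitted fusion model, frozen encoders, histories; or NULL if the
#'   pre-training subsample is too small.
#' @export
runDeclinePipeline <- function(prepared, task = "decline_memory_binary",
                               taskKind = c("binary", "regression",
                                            "multiclass"),
                               state = trainState(lr0 = 2e-3,
                                                  batchSize = 32L,
                                                  epochs = 16L),
                               seed = 1L, pretrainProportion = 1,
                               embeddingDim = 32L, fusionDropout = 0.3,
                               nBoot = 0L) {
  taskKind <- match.arg(taskKind)
  ids <- prepared$ids
  spec <- defaultPretrainTaskSpec()
  preLab <- prepared$split$pretrain
  set.seed(as.integer(seed))
  encoders <- list()
  for (m in colnames(prepared$hasModality)) {
    poolIds <- names(preLab)[names(preLab) %in%
                             ids[prepared$hasModality[, m]]]
    if (pretrainProportion < 1) {
      keepN <- floor(pretrainProportion * length(poolIds))
      if (keepN < 10L) return(NULL)
      poolIds <- sample(poolIds, keepN)
    }
    trainIdx <- match(poolIds[preLab[poolIds] == "train"], ids)
    valIdx <- match(poolIds[preLab[poolIds] == "val"], ids)
    cfg <- embeddingModelConfig("ffn", embeddingDim = embeddingDim,
                                hidden = c(64L, 48L))
    pt <- pretrainModality(prepared$features[[m]], prepared$targets,
                           prepared$masks, spec, cfg,
                           list(kind = "tabular",
                                dim = ncol(prepared$features[[m]])),
                           trainIdx, valIdx, state = state,
                           seed = as.integer(seed) + 17L * match(m, names(prepared$features)))
    encoders[[m]] <- pt$encoder
  }
  mod <- prepared$split$modeling
  trainIdx <- match(names(mod)[mod == "train"], ids)
  valIdx <- match(names(mod)[mod == "val"], ids)
  testIdx <- match(names(mod)[mod == "test"], ids)
  y <- prepared$targets[[task]]
  mask <- prepared$masks[[task]]
  ft <- finetuneTask(encoders, prepared$features, aux = prepared$aux,
                     y = y, mask = mask, task = taskKind, nClasses = 3L,
                     trainIdx = trainIdx, valIdx = valIdx, state = state,
                     dropout = fusionDropout,
                     seed = as.integer(seed) + 91L)
  keep <- testIdx[mask[testIdx] & !is.na(y[testIdx])]
  Zt <- lapply(ft$embeddings, function(z) z[keep, , drop = FALSE])
  out <- fuseAndPredict(ft$model, Zt, aux = prepared$aux[keep, , drop = FALSE])
  metrics <- switch(taskKind,
    binary = classificationMetrics(
      factor(c("stable", "decliner")[y[keep] + 1L],
             levels = c("stable", "decliner")),
      factor(c("stable", "decliner")[
               as.integer(out[, 1L] > (ft$threshold %||% 0.5)) + 1L],
             levels = c("stable", "decliner")),
      yScores = out[, 1L], nBoot = nBoot),
    regression = regressionMetrics(y[keep], out[, 1L], nBoot = nBoot),
    multiclass = classificationMetrics(
      factor(c("CN", "MCI", "dementia")[y[keep]],
             levels = c("CN", "MCI", "dementia")),
      factor(c("CN", "MCI", "dementia")[max.col(out, ties.method = "first")],
             levels = c("CN", "MCI", "dementia")),
      nBoot = nBoot))
  list(metrics = metrics, predictions = out, testIds = ids[keep],
       model = ft$model, encoders = encoders, history = ft$history)
}
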