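# Training machinery: splits, masked multitask loss, schedule, pre-training
# and fine-tuning contracts.

test_that("cohort splits follow 60/10/30 and 85/15 with no test leakage", {
  cohort <- fixtureCohort()
  sp <- splitCohort(cohort, seed = 3)
  tab <- table(sp$modeling)
  expect_equal(unname(tab[["train"]]), 24, tolerance = 1)
  expect_equal(unname(tab[["val"]]), 4, tolerance = 1)
  expect_equal(unname(tab[["test"]]), 12, tolerance = 1)
  testIds <- names(sp$modeling)[sp$modeling == "test"]
  expect_length(intersect(testIds, names(sp$pretrain)), 0L)
  ptab <- table(sp$pretrain)
  expect_equal(unname(ptab[["train"]]) / sum(ptab), 0.85, tolerance = 0.03)
  expect_identical(splitCohort(cohort, seed = 3), sp)
  expect_false(identical(splitCohort(cohort, seed = 4)$modeling,
                         sp$modeling))
})

test_that("the masked multitask loss matches an entry-loop oracle", {
  spec <- taskSpec(binary = "b", multiclass = list(m = c("x", "y", "z")),
                   regression = c("r1", "r2"))
  # closed-form Huber anchor values
  expect_equal(neurodecline:::huberLoss(1, 2.5), 0.5)
  expect_equal(neurodecline:::huberLoss(5, 2.5), 2.5 * (5 - 1.25))
  set.seed(71)
  sig <- function(z) 1 / (1 + exp(-z))
  for (i in 1:100) {
    n <- sample(3:12, 1)
    preds <- list(b = matrix(rnorm(n)), m = matrix(rnorm(3 * n), n),
                  r1 = matrix(rnorm(n)), r2 = matrix(rnorm(n)))
    targets <- list(b = rbinom(n, 1, 0.5), m = sample(1:3, n, TRUE),
                    r1 = rnorm(n), r2 = rnorm(n))
    masks <- lapply(1:4, function(j) runif(n) < 0.7)
    names(masks) <- names(preds)
    got <- maskedMultitaskLoss(preds, targets, masks, spec)
    # entry-loop oracle
    oracle <- 0
    accum <- function(tk, lossVec) {
      obs <- which(masks[[tk]])
      if (!length(obs)) 0 else mean(lossVec[obs])
    }
    lb <- -(targets$b * log(sig(preds$b[, 1])) +
            (1 - targets$b) * log(1 - sig(preds$b[, 1])))
    lm_ <- vapply(seq_len(n), function(s) {
      p <- exp(preds$m[s, ]) / sum(exp(preds$m[s, ]))
      -log(p[targets$m[s]])
    }, numeric(1))
    hub <- function(r) ifelse(abs(r) <= 2.5, r^2 / 2, 2.5 * (abs(r) - 1.25))
    oracle <- accum("b", lb) + accum("m", lm_) +
      accum("r1", hub(preds$r1[, 1] - targets$r1)) +
      accum("r2", hub(preds$r2[, 1] - targets$r2))
    expect_equal(got$total, oracle, tolerance = 1e-10)
  }
  # fully masked: zero loss
  allFalse <- lapply(masks, function(m) rep(FALSE, length(m)))
  expect_equal(maskedMultitaskLoss(preds, targets, allFalse, spec)$total, 0)
  # weights of one make the total the sum of per-task losses
  got <- maskedMultitaskLoss(preds, targets, masks, spec)
  expect_equal(got$total, sum(got$perTask), tolerance = 1e-12)
})

test_that("the learning-rate schedule halves every 20% of epochs", {
  expect_equal(lrAtEpoch(19, 100, 1), 1)
  expect_equal(lrAtEpoch(20, 100, 1), 0.5)
  expect_equal(lrAtEpoch(99, 100, 1), 1 / 16)
  expect_equal(lrAtEpoch(0:4, 5, 1), c(1, 0.5, 0.25, 0.125, 0.0625))
  expect_error(lrAtEpoch(0, 0, 1), "positive")
})

test_that("pre-training reduces the loss and freezing survives fine-tuning bitwise", {
  prep <- fixturePrepared()
  ids <- prep$ids
  spec <- defaultPretrainTaskSpec()
  pre <- prep$split$pretrain
  poolIds <- names(pre)[names(pre) %in% ids[prep$hasModality[, "fdg"]]]
  trainIdx <- match(poolIds[pre[poolIds] == "train"], ids)
  valIdx <- match(poolIds[pre[poolIds] == "val"], ids)
  cfg <- embeddingModelConfig("ffn", embeddingDim = 8L, hidden = 16L)
  st <- trainState(lr0 = 1e-3, batchSize = 16L, epochs = 5L)
  pt <- pretrainModality(prep$features$fdg, prep$targets, prep$masks, spec,
                         cfg, list(kind = "tabular",
                                   dim = ncol(prep$features$fdg)),
                         trainIdx, valIdx, state = st, seed = 7)
  expect_lt(tail(pt$history$train, 1), pt$history$train[1])
  expect_true(pt$encoder$frozen)
  # fine-tuning never touches the frozen encoder weights
  nd <- asNamespace("neurodecline")
  before <- nd$nnFlattenParams(pt$encoder$net)
  mod <- prep$split$modeling
  ft <- finetuneTask(list(fdg = pt$encoder),
                     list(fdg = prep$features$fdg),
                     aux = prep$aux, y = prep$targets$slope_memory,
                     mask = prep$masks$slope_memory,
                     task = "regression",
                     trainIdx = match(names(mod)[mod == "train"], ids),
                     valIdx = match(names(mod)[mod == "val"], ids),
                     state = trainState(lr0 = 1e-3, batchSize = 16L,
                                        epochs = 4L),
                     seed = 8)
  expect_identical(nd$nnFlattenParams(pt$encoder$net), before)
  # model selection returns the epoch with the best validation metric
  expect_equal(ft$bestEpoch,
               ft$history$epoch[which.max(ft$history$valMetric)])
  # subjects missing other modalities still pre-train this one
  hasOnlyFdg <- ids[prep$hasModality[, "fdg"] &
                    !prep$hasModality[, "av45"]]
  expect_gt(length(intersect(hasOnlyFdg, poolIds)), 0L)
})

test_that("volume encoders train end to end on a small smoke fixture", {
  set.seed(73)
  n <- 16
  sev <- runif(n)
  vols <- lapply(seq_len(n), function(i)
    array(rnorm(8^3, mean = 3 * sev[i], sd = 0.5), c(8, 8, 8)))
  spec <- taskSpec(regression = "s")
  targets <- list(s = as.numeric(scale(sev)))
  masks <- list(s = rep(TRUE, n))
  cfg <- embeddingModelConfig("cnn_scaffold", embeddingDim = 4L,
                              channels = c(2L, 3L))
  pt <- pretrainModality(vols, targets, masks, spec, cfg,
                         list(kind = "volume", dims = c(8L, 8L, 8L),
                              channels = 1L),
                         trainIdx = 1:12, valIdx = 13:16,
                         state = trainState(lr0 = 3e-3, batchSize = 6L,
                                            epochs = 8L),
                         seed = 9)
  expect_lt(tail(pt$history$train, 1), pt$history$train[1])
  expect_true(all(is.finite(pt$history$val)))
})

test_that("seeded runs are exactly reproducible", {
  prep <- fixturePrepared()
  st <- trainState(lr0 = 2e-3, batchSize = 16L, epochs = 3L)
  r1 <- runDeclinePipeline(prep, task = "slope_memory",
                           taskKind = "regression", state = st, seed = 5)
  r2 <- runDeclinePipeline(prep, task = "slope_memory",
                           taskKind = "regression", state = st, seed = 5)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$metrics$ev, r2$metrics$ev)
})

test_that("fitted preprocessing objects carry train-only provenance", {
  prep <- fixturePrepared()
  testIds <- names(prep$split$modeling)[prep$split$modeling == "test"]
  for (mm in prep$measurementModels)
    expect_length(intersect(mm@provenance$subjects, testIds), 0L)
  expect_length(intersect(prep$graph@meta$provenance$subjects, testIds), 0L)
  for (nm in prep$normativeModels)
    expect_length(intersect(nm$provenance$subjects, testIds), 0L)
})
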