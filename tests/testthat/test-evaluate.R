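# Metrics: oracle equivalence, degenerate conventions, invariances,
# bootstrap behavior, conversion analysis.

test_that("classification metrics hit the perfection and degeneracy anchors", {
  y <- factor(rep(c("a", "b"), each = 10))
  m <- classificationMetrics(y, y, yScores = c(rep(0, 10), rep(1, 10)),
                             nBoot = 0)
  expect_equal(m$mcc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
  # all-one-class prediction on a balanced set: MCC 0 by convention
  m <- classificationMetrics(y, factor(rep("a", 20), levels = c("a", "b")),
                             nBoot = 0)
  expect_equal(m$mcc, 0)
  # single observed class: MCC/AUC undefined markers
  m <- classificationMetrics(factor(rep("a", 5), levels = c("a", "b")),
                             factor(rep("a", 5), levels = c("a", "b")),
                             yScores = rnorm(5), nBoot = 0)
  expect_true(is.na(m$mcc))
  expect_true(is.na(m$auc))
})

test_that("multiclass MCC matches the covariance-form oracle on random instances", {
  mccOracle <- function(yT, yP) {
    # direct covariance formulation over one-hot indicator matrices
    k <- length(levels(yT))
    X <- diag(k)[as.integer(yT), , drop = FALSE]
    Y <- diag(k)[as.integer(yP), , drop = FALSE]
    covf <- function(A, B) sum(diag(crossprod(scale(A, scale = FALSE),
                                              scale(B, scale = FALSE))))
    d <- sqrt(covf(X, X) * covf(Y, Y))
    if (d == 0) 0 else covf(Y, X) / d
  }
  set.seed(81)
  for (n in c(10, 100, 1000)) {
    for (i in 1:40) {
      yT <- factor(sample(1:3, n, TRUE), levels = 1:3)
      yP <- factor(sample(1:3, n, TRUE), levels = 1:3)
      got <- mccFromConfusion(table(yT, yP))
      expect_equal(got, mccOracle(yT, yP), tolerance = 1e-10)
    }
  }
})

test_that("regression metrics match the variance-definition oracle", {
  y <- rnorm(30)
  m <- regressionMetrics(y, y, nBoot = 0)
  expect_equal(m$ev, 1)
  expect_equal(m$r, 1)
  m <- regressionMetrics(y, rep(mean(y), 30), nBoot = 0)
  expect_equal(m$ev, 0)
  set.seed(82)
  for (n in c(10, 100, 1000)) {
    yT <- rnorm(n)
    yP <- 0.5 * yT + rnorm(n)
    m <- regressionMetrics(yT, yP, nBoot = 0)
    res <- yT - yP
    oracle <- 1 - (mean(res^2) - mean(res)^2) / (mean(yT^2) - mean(yT)^2)
    expect_equal(m$ev, oracle, tolerance = 1e-10)
    expect_equal(m$r, cov(yT, yP) / (sd(yT) * sd(yP)), tolerance = 1e-10)
  }
  expect_error(regressionMetrics(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("AUC is invariant under strictly monotone score transforms and matches pROC", {
  nd <- asNamespace("neurodecline")
  set.seed(83)
  y <- rbinom(80, 1, 0.4)
  s <- rnorm(80) + y
  a1 <- nd$aucRank(y, s)
  expect_equal(nd$aucRank(y, exp(s)), a1)
  expect_equal(nd$aucRank(y, 3 * s - 10), a1)
  skip_if_not_installed("pROC")
  a2 <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("bootstrap intervals cover the point estimate and narrow with n", {
  set.seed(84)
  mk <- function(n) {
    y <- factor(sample(c("a", "b"), n, TRUE))
    p <- factor(ifelse(runif(n) < 0.8, as.character(y),
                       sample(c("a", "b"), n, TRUE)), levels = levels(y))
    classificationMetrics(y, p, nBoot = 400)
  }
  m1 <- mk(100)
  m2 <- mk(1000)
  expect_true(m1$ci$mcc[1] <= m1$mcc && m1$mcc <= m1$ci$mcc[2])
  expect_lt(diff(m2$ci$mcc), diff(m1$ci$mcc))
})

test_that("conversion analysis restricts to baseline MCI and matches hand counts", {
  base <- c("MCI", "MCI", "MCI", "MCI", "CN", "CN", "MCI", "MCI", "MCI",
            "MCI")
  true2y <- c("dementia", "MCI", "MCI", "dementia", "MCI", "CN", "MCI",
              "MCI", "dementia", "MCI")
  pred2y <- c("dementia", "MCI", "dementia", "MCI", "dementia", "CN",
              "MCI", "MCI", "dementia", "MCI")
  m <- conversionMetrics(base, true2y, pred2y, nBoot = 0)
  # 8 baseline-MCI subjects; hand-counted confusion
  expect_equal(m$n, 8L)
  cm <- m$confusion
  expect_equal(unname(cm["pMCI", "pMCI"]), 2)   # true converters caught
  expect_equal(unname(cm["pMCI", "sMCI"]), 1)   # missed converter
  expect_equal(unname(cm["sMCI", "pMCI"]), 1)   # false alarm
  expect_equal(unname(cm["sMCI", "sMCI"]), 4)
  # degenerate: everyone stable, everyone predicted stable
  m0 <- conversionMetrics(rep("MCI", 5), rep("MCI", 5), rep("MCI", 5),
                          nBoot = 0)
  expect_equal(m0$accuracy, 1)
  expect_true(is.na(m0$mcc))
  expect_error(conversionMetrics(rep("CN", 4), rep("CN", 4), rep("CN", 4)),
               "MCI")
})

test_that("the learning curve bookkeeping covers every proportion and repeat", {
  prep <- fixturePrepared()
  st <- trainState(lr0 = 2e-3, batchSize = 16L, epochs = 2L)
  lc <- learningCurve(prep, proportions = c(0.5, 1), nRepeats = 2L,
                      task = "slope_memory", state = st, seed = 3)
  expect_equal(nrow(lc), 4L)
  expect_setequal(lc$proportion, c(0.5, 1))
  # identical seeds reproduce identical correlations
  lc2 <- learningCurve(prep, proportions = c(0.5, 1), nRepeats = 2L,
                       task = "slope_memory", state = st, seed = 3)
  expect_identical(lc$cor, lc2$cor)
})
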