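# Synthetic cohort generator: determinism, planted-signal monotonicity,
# and recovery of planted quantities.

test_that("atlas has the requested regions, is deterministic, and rejects impossible shapes", {
  a <- fixtureAtlas()
  lab <- atlasLabels(a)
  expect_identical(sort(unique(as.integer(lab[lab > 0]))), 1:12)
  expect_identical(roiIds(a), 1:12)
  a2 <- makeAtlas(12L, c(10L, 10L, 10L), seed = 7L)
  expect_identical(atlasLabels(a2), lab)
  a3 <- makeAtlas(12L, c(10L, 10L, 10L), seed = 8L)
  expect_false(identical(atlasLabels(a3), lab))
  one <- makeAtlas(1L, c(6L, 6L, 6L), seed = 1L)
  lab1 <- atlasLabels(one)
  expect_true(all(lab1[lab1 != 0L] == 1L))
  expect_error(makeAtlas(1000L, c(4L, 4L, 4L)), "in-mask voxels")
})

test_that("noiseless volumes have exact generative regional means and planted monotonicity", {
  a <- fixtureAtlas()
  lab <- atlasLabels(a)
  tr0 <- makeSubjectTruth(0, seed = 1, amyloidPositive = FALSE)
  tr5 <- makeSubjectTruth(0.5, seed = 1, amyloidPositive = TRUE)
  tr1 <- makeSubjectTruth(1, seed = 1, amyloidPositive = TRUE)
  v0 <- makeSubjectVolumes(a, tr0, seed = 2, noiseSd = 0)
  v5 <- makeSubjectVolumes(a, tr5, seed = 2, noiseSd = 0)
  v1 <- makeSubjectVolumes(a, tr1, seed = 2, noiseSd = 0)
  nAff <- ceiling(0.3 * 12)
  affMask <- lab %in% seq_len(nAff)
  # voxel-loop oracle for the severity-0.5 regional means
  for (roi in c(1L, nAff, nAff + 1L)) {
    vox <- which(lab == roi)
    expected <- if (roi <= nAff) 1.30 - 0.35 * 0.5 else 1.30
    expect_equal(mean(v5$fdg[vox]), expected, tolerance = 1e-12)
    expectedGm <- if (roi <= nAff) 0.70 - 0.25 * 0.5 else 0.70
    expect_equal(mean(v5$gm[vox]), expectedGm, tolerance = 1e-12)
  }
  # monotone in severity within affected regions
  expect_true(mean(v0$gm[affMask]) > mean(v5$gm[affMask]))
  expect_true(mean(v5$gm[affMask]) > mean(v1$gm[affMask]))
  expect_true(mean(v0$fdg[affMask]) > mean(v1$fdg[affMask]))
  expect_true(mean(v0$av45[affMask]) < mean(v1$av45[affMask]))
  # same truth, different noise seeds: only the noise realization differs
  n1 <- makeSubjectVolumes(a, tr5, seed = 3, noiseSd = 0.05)
  n2 <- makeSubjectVolumes(a, tr5, seed = 4, noiseSd = 0.05)
  inMask <- lab != 0L
  expect_false(identical(n1$gm, n2$gm))
  expect_equal(mean(n1$gm[inMask] - n2$gm[inMask]), 0, tolerance = 0.01)
  expect_identical(makeSubjectVolumes(a, tr5, seed = 3, noiseSd = 0.05), n1)
})

test_that("noiseless battery items reproduce the latent trajectory exactly", {
  tr <- makeSubjectTruth(0.5, seed = 5)
  b <- makeLongitudinalBattery(tr, 6, 0.5, seed = 6, missingRate = 0,
                               itemNoiseSd = 0)
  latent <- (100 - 40 * 0.5) + tr$domainSlopes[["memory"]] * (0:5) * 0.5
  expect_equal(b$mem_recall_1, 0.9 * latent, tolerance = 1e-12)
  # timed item is a decreasing transform of the executive latent
  latE <- (100 - 40 * 0.5) + tr$domainSlopes[["executive"]] * (0:5) * 0.5
  expect_equal(log(b$exec_tmt_seconds), 5 - 0.02 * 0.9 * latE,
               tolerance = 1e-12)
  expect_true(all(b$vis_clock %in% 0:4))
  expect_true(all(diff(match(b$diagnosis, c("CN", "MCI", "dementia"))) >= 0))
})

test_that("planted slopes are recovered from noiseless trajectories and MCAR rates match", {
  set.seed(11)
  nSub <- 400
  est <- truth <- numeric(nSub)
  tExact <- 0.5 * (0:7)   # stored dates are day-rounded; use exact times
  for (i in seq_len(nSub)) {
    tr <- makeSubjectTruth(runif(1), seed = 1000L + i)
    b <- makeLongitudinalBattery(tr, 8, 0.5, seed = 2000L + i,
                                 missingRate = 0, itemNoiseSd = 0)
    est[i] <- coef(lm(b$mem_recall_1 / 0.9 ~ tExact))[2]
    truth[i] <- tr$domainSlopes[["memory"]]
  }
  expect_equal(est, truth, tolerance = 1e-8)
  # noisy trajectories: precision-weighted latent reconstruction from all
  # memory items still tracks the planted slopes
  loads <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  t10 <- 0.5 * (0:9)
  for (i in seq_len(nSub)) {
    tr <- makeSubjectTruth(runif(1), seed = 5000L + i)
    b <- makeLongitudinalBattery(tr, 10, 0.5, seed = 6000L + i,
                                 missingRate = 0)
    items <- as.matrix(b[paste0("mem_recall_", 1:5)])
    latentHat <- as.vector(items %*% loads) / sum(loads^2)
    est[i] <- coef(lm(latentHat ~ t10))[2]
    truth[i] <- tr$domainSlopes[["memory"]]
  }
  expect_gt(cor(est, truth), 0.9)
  # MCAR missingness calibration over >= 1e5 generated cells
  nMiss <- 0L
  nCell <- 0L
  for (i in 1:60) {
    b <- makeLongitudinalBattery(makeSubjectTruth(0.4, seed = i), 12, 0.5,
                                 seed = 300L + i, missingRate = 0.04)
    items <- b[, setdiff(names(b), c("date_days", "diagnosis", "age",
                                     "sex", "education"))]
    nMiss <- nMiss + sum(is.na(items))
    nCell <- nCell + length(unlist(items))
  }
  expect_gt(nCell, 1e4)
  expect_lt(abs(nMiss / nCell - 0.04), 0.01)
})

test_that("cohorts have the configured structure and are seed-reproducible", {
  cohort <- fixtureCohort()
  expect_equal(nSubjects(cohort), 60L)
  expect_equal(length(modelingIds(cohort)), 40L)
  meetsCriteria <- vapply(cohortSubjects(cohort), function(s) {
    all(s$hasModality) && max(s$visits$date_days) >= 730  # 2y at day grain
  }, logical(1))
  expect_equal(sum(meetsCriteria), 40L)
  expect_identical(which(meetsCriteria), 1:40)
  cfg <- cohortConfig(nModeling = 10L, nPretrainExtra = 5L,
                      atlasShape = c(8L, 8L, 8L), nRois = 10L)
  c1 <- makeCohort(cfg, seed = 9L)
  c2 <- makeCohort(cfg, seed = 9L)
  expect_identical(cohortSubjects(c1), cohortSubjects(c2))
  expect_error(cohortConfig(normativeFraction = 1.4), "rates")
})

test_that("amyloid-negative sustained-CN subjects occur at the configured rate", {
  cfg <- cohortConfig(nModeling = 0L, nPretrainExtra = 4000L,
                      normativeFraction = 0.3, includeVolumes = FALSE)
  cohort <- makeCohort(cfg, seed = 21L)
  isNorm <- vapply(cohortSubjects(cohort), function(s)
    all(s$visits$diagnosis == "CN") && !s$truth$amyloidPositive, logical(1))
  # every planted normative subject stays CN; a few low-severity
  # non-normative subjects may also qualify, so the rate brackets 0.3
  p <- mean(isNorm)
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_gt(p, 0.3 - 3 * se)
  expect_lt(p, 0.45)
})
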