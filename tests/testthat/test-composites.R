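# Composite construction: imputation contracts, one-factor model fitting
# and scoring, reference rescaling, normative adjustment.

test_that("imputation preserves observed cells, beats marginal means, and rejects empty columns", {
  set.seed(31)
  n <- 300
  f <- rnorm(n)
  full <- data.frame(a = 0.9 * f + rnorm(n, 0, 0.3),
                     b = 0.8 * f + rnorm(n, 0, 0.3),
                     c = 0.7 * f + rnorm(n, 0, 0.3),
                     d = 0.6 * f + rnorm(n, 0, 0.3))
  expect_identical(imputeItems(full), full)
  holes <- full
  hole <- matrix(runif(4 * n) < 0.1, n)
  holes[hole] <- NA
  dem <- data.frame(age = rnorm(n, 73, 5), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 16, 2))
  done <- imputeItems(holes, dem)
  expect_false(anyNA(done))
  obs <- !is.na(holes)
  expect_identical(as.matrix(done)[obs], as.matrix(full)[obs])
  errChained <- mean(abs(as.matrix(done)[!obs] - as.matrix(full)[!obs]))
  marg <- holes
  for (cc in names(marg)) marg[[cc]][is.na(marg[[cc]])] <-
    mean(marg[[cc]], na.rm = TRUE)
  errMarg <- mean(abs(as.matrix(marg)[!obs] - as.matrix(full)[!obs]))
  expect_lt(errChained, errMarg)
  # surrogate random-forest route for the designated high-missingness item
  holes2 <- full
  holes2$d[runif(n) < 0.2] <- NA
  done2 <- imputeItems(holes2, dem, highMissingItem = "d")
  expect_false(anyNA(done2))
  bad <- full
  bad$a[] <- NA
  expect_error(imputeItems(bad), "entirely missing.*a")
})

test_that("one-factor model recovers planted loadings with unit factor variance", {
  set.seed(32)
  n <- 2000
  f <- rnorm(n)
  load <- c(0.9, 0.7, 0.5)
  m <- as.data.frame(sapply(load, function(l)
    l * f + rnorm(n, 0, sqrt(1 - l^2))))
  names(m) <- paste0("i", 1:3)
  spec <- list(domain = "memory", items = names(m),
               ordinal = rep(FALSE, 3), timed = rep(FALSE, 3),
               direction = rep(1, 3))
  mm <- fitCompositeModel(m, spec)
  expect_identical(factorVariance(mm), 1)
  expect_gt(cor(modelLoadings(mm), load), 0.9)
  expect_true(all(modelLoadings(mm) > 0))
  # single-item degenerate model: composite equals the standardized item
  spec1 <- list(domain = "executive", items = "i1",
                ordinal = FALSE, timed = FALSE, direction = 1)
  m1 <- fitCompositeModel(m["i1"], spec1)
  expect_equal(unname(modelLoadings(m1)), 1)
  expect_equal(scoreComposites(m1, m), as.vector(scale(m$i1)),
               tolerance = 1e-12)
})

test_that("composite scores are deterministic, order-invariant, and exact on noiseless data", {
  set.seed(33)
  n <- 400
  f <- rnorm(n)
  m <- as.data.frame(sapply(c(0.9, 0.7, 0.5), function(l) l * f))
  names(m) <- paste0("i", 1:3)
  spec <- list(domain = "memory", items = names(m),
               ordinal = rep(FALSE, 3), timed = rep(FALSE, 3),
               direction = rep(1, 3))
  mm <- fitCompositeModel(m, spec)
  s <- scoreComposites(mm, m)
  expect_gt(cor(s, f), 1 - 1e-6)
  expect_identical(s, scoreComposites(mm, m))
  expect_identical(s, scoreComposites(mm, m[, c(3, 1, 2)]))
  expect_error(scoreComposites(mm, m[, 1:2]), "item column")
  # identical item rows give identical scores
  m2 <- m[c(1, 1, 2), ]
  s2 <- scoreComposites(mm, m2)
  expect_identical(s2[1], s2[2])
})

test_that("reference rescaling hits its anchors and is affine-invariant", {
  p <- scalerParams(p50dem = 40, p50cn = 90)
  expect_equal(scaleComposite(40, p), 0)
  expect_equal(scaleComposite(90, p), 100)
  expect_equal(scaleComposite(65, p), 50)
  expect_error(scalerParams(50, 50), "degenerate")
  # affine invariance: transforming scores and medians together is a no-op
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(5)
    d <- rnorm(1); cn <- d + runif(1, 0.5, 3)
    a <- runif(1, 0.2, 4); b <- rnorm(1)
    p1 <- scalerParams(d, cn)
    p2 <- scalerParams(a * d + b, a * cn + b)
    expect_equal(scaleComposite(a * x + b, p2), scaleComposite(x, p1),
                 tolerance = 1e-10)
  }
})

test_that("normative adjustment recovers covariate effects and removes them", {
  set.seed(35)
  n <- 10000
  half <- seq_len(n / 2)
  age <- rnorm(n, 73, 6)
  edu <- rnorm(n, 16, 2.5)
  scores <- 100 - 0.5 * (age - 70) + 0.6 * (edu - 16) + rnorm(n, 0, 3)
  nm <- fitNormativeModel(scores[half], age[half], edu[half])
  expect_lt(abs(nm$coef[["age"]] + 0.5), 0.05)
  adj <- normativeAdjust(nm, scores[-half], age[-half], edu[-half])
  expect_lt(abs(cor(adj, age[-half])), 0.05)
  expect_lt(abs(cor(adj, edu[-half])), 0.05)
  # subject at the normative mean covariates: shift is the intercept only
  s0 <- 85
  expect_equal(normativeAdjust(nm, s0, nm$ageMean, nm$eduMean),
               s0 - (nm$coef[["(Intercept)"]] + nm$coef[["age"]] * nm$ageMean +
                     nm$coef[["education"]] * nm$eduMean))
  # constant covariates: adjusted scores are the centered raw scores
  sc <- rnorm(30, 50, 5)
  nmc <- fitNormativeModel(sc, rep(70, 30), rep(16, 30))
  expect_equal(normativeAdjust(nmc, sc, rep(70, 30), rep(16, 30)),
               sc - mean(sc), tolerance = 1e-9)
  expect_error(fitNormativeModel(numeric(0), numeric(0), numeric(0)),
               "empty normative")
  expect_error(fitNormativeModel(rnorm(5), rnorm(5), rnorm(5)), "at least 20")
})
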