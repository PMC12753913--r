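# Feature mappings: ROI aggregation vs a voxel-loop oracle, volume
# normalization/downsampling, graphical-lasso connectivity estimation.

voxelLoopOracle <- function(vol, lab, ids, stat) {
  vapply(ids, function(r) {
    acc <- c()
    d <- dim(vol)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if (lab[i, j, k] == r) acc <- c(acc, vol[i, j, k])
    switch(stat, sum = sum(acc), mean = mean(acc),
           sd = sqrt(mean((acc - mean(acc))^2)))
  }, numeric(1))
}

test_that("ROI aggregation equals a brute-force voxel loop", {
  set.seed(51)
  lab <- array(sample(0:2, 4^3, replace = TRUE, prob = c(0.2, 0.4, 0.4)),
               c(4, 4, 4))
  lab[1:2, 1, 1] <- 1:2   # both ROIs occur
  atlas <- new("AtlasVolume", labels = lab, voxelSize = c(2, 2, 2),
               roiIds = 1:2)
  pet <- array(rnorm(64, 1.2, 0.2), c(4, 4, 4))
  f <- phiTabular(pet, atlas, "fdg")
  expect_length(f, 4L)
  expect_equal(unname(f[c(1, 3)]), voxelLoopOracle(pet, lab, 1:2, "mean"),
               tolerance = 1e-12)
  expect_equal(unname(f[c(2, 4)]), voxelLoopOracle(pet, lab, 1:2, "sd"),
               tolerance = 1e-12)
  gm <- array(runif(64), c(4, 4, 4))
  wm <- array(runif(64), c(4, 4, 4))
  fm <- phiTabular(list(gm = gm, wm = wm), atlas, "mri")
  expect_equal(unname(fm[c(1, 3)]),
               voxelLoopOracle(gm, lab, 1:2, "sum") * 8, tolerance = 1e-12)
  expect_equal(unname(fm[c(2, 4)]),
               voxelLoopOracle(wm, lab, 1:2, "sum") * 8, tolerance = 1e-12)
  # constant field: means constant, spreads zero
  cst <- array(1, c(4, 4, 4))
  fc <- phiTabular(cst, atlas, "av45")
  expect_equal(unname(fc[c(1, 3)]), c(1, 1))
  expect_equal(unname(fc[c(2, 4)]), c(0, 0))
  expect_error(phiTabular(array(0, c(3, 3, 3)), atlas, "fdg"),
               "does not match")
})

test_that("the 116-ROI atlas yields 232-length vectors", {
  atlas <- makeAtlas(116L, c(16L, 16L, 16L), seed = 3L)
  vol <- makeSubjectVolumes(atlas, makeSubjectTruth(0.4, seed = 4), seed = 5)
  expect_length(phiTabular(vol$fdg, atlas, "fdg"), 232L)
  expect_length(phiTabular(list(gm = vol$gm, wm = vol$wm), atlas, "mri"),
                232L)
})

test_that("volume mapping halves dimensions, preserves constants, and normalizes by the WM median", {
  set.seed(52)
  v <- array(rnorm(64^1 * 8 * 8), c(8, 8, 8))
  out <- phiVolume(v, "fdg")
  expect_identical(dim(out$data), c(4L, 4L, 4L))
  expect_identical(dim(phiVolume(array(0, c(64, 64, 64)), "fdg")$data),
                   c(32L, 32L, 32L))
  cst <- phiVolume(array(3.7, c(8, 8, 8)), "av45")
  expect_true(all(abs(cst$data - 3.7) < 1e-12))
  mri <- array(runif(512, 1, 3), c(8, 8, 8))
  wm <- array(runif(512), c(8, 8, 8))
  med <- median(mri[wm > 0.5])
  norm <- phiVolume(mri, "mri", wmMask = wm)
  expect_equal(norm$normalization$wmMedian, med)
  expect_equal(median((mri / med)[wm > 0.5]), 1)
  expect_error(phiVolume(mri, "mri"), "WM mask")
  expect_error(phiVolume(array(0, c(8, 8, 8)), "mri", wmMask = wm),
               "zero")
})

test_that("graphical lasso matches the 2-variable penalized-likelihood oracle", {
  grid2Oracle <- function(S, rho) {
    t12 <- seq(-3, 3, length.out = 1201)
    t11 <- seq(0.1, 4, length.out = 391)
    g <- expand.grid(t12 = t12, t11 = t11)
    det <- g$t11^2 - g$t12^2
    ok <- det > 1e-10
    ll <- rep(-Inf, nrow(g))
    ll[ok] <- log(det[ok]) -
      (2 * g$t11[ok] * S[1, 1] + 2 * g$t12[ok] * S[1, 2]) -
      rho * (2 * abs(g$t11[ok]) + 2 * abs(g$t12[ok]))
    g[which.max(ll), ]
  }
  set.seed(53)
  for (i in 1:12) {
    r <- runif(1, -0.95, 0.95)
    rho <- runif(1, 0.02, 0.6)
    S <- matrix(c(1, r, r, 1), 2)
    gl <- graphicalLasso(S, rho)
    or <- grid2Oracle(S, rho)
    expect_lt(abs(gl$Theta[1, 1] - or$t11), 0.02)
    expect_lt(abs(gl$Theta[1, 2] - or$t12), 0.02)
  }
  # independence plus a strong penalty removes every edge
  set.seed(54)
  z <- matrix(rnorm(400 * 8), 400)
  g <- estimateConnectivityGraph(z, lambda = 0.9)
  expect_equal(nrow(graphEdges(g)), 0L)
  # correlated pair at a small penalty keeps its edge
  z[, 2] <- 0.9 * z[, 1] + sqrt(1 - 0.81) * rnorm(400)
  g <- estimateConnectivityGraph(z, lambda = 0.1)
  expect_true(any(graphEdges(g)[, 1] == 1 & graphEdges(g)[, 2] == 2))
})

test_that("connectivity graphs are monotone in lambda and have PD precision", {
  set.seed(55)
  n <- 150; p <- 30
  f <- matrix(rnorm(n * 3), n)
  L <- matrix(rnorm(3 * p, 0, 0.6), 3)
  z <- f %*% L + matrix(rnorm(n * p), n)
  counts <- vapply(c(0.2, 0.3, 0.4), function(l) {
    g <- estimateConnectivityGraph(z, lambda = l)
    expect_no_error(chol(graphPrecision(g)))
    nrow(graphEdges(g))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("node features attach per ROI and concatenate across modalities", {
  g <- fixtureBrainGraph()
  fv <- function(k) {
    v <- as.numeric(1:12) + k * 100
    names(v) <- paste0("roi", rep(1:6, each = 2), "_", c("m", "s"))
    v
  }
  g1 <- phiGraph(fv(0), g)
  expect_identical(dim(nodeFeatures(g1)), c(6L, 2L))
  expect_equal(unname(nodeFeatures(g1)[3, ]), c(5, 6))
  g3 <- phiGraph(list(fv(0), fv(1), fv(2)), g)
  expect_identical(dim(nodeFeatures(g3)), c(6L, 6L))
  expect_equal(unname(nodeFeatures(g3)[2, ]), c(3, 4, 103, 104, 203, 204))
  expect_error(phiGraph(fv(0)[1:10], g), "does not match")
})
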