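# Shared fixtures, built lazily once per test run.

ndFixtures <- new.env(parent = emptyenv())

fixtureAtlas <- function() {
  if (is.null(ndFixtures$atlas))
    ndFixtures$atlas <- makeAtlas(12L, c(10L, 10L, 10L), seed = 7L)
  ndFixtures$atlas
}

# small graph used by GNN tests: 6 nodes, mixed degrees
fixtureGraphAdj <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6),
                 c(2, 5)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  A
}

fixtureBrainGraph <- function(R = 6L) {
  A <- fixtureGraphAdj()
  e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- cbind(as.integer(e[, 1]), as.integer(e[, 2]))
  colnames(edges) <- c("i", "j")
  new("BrainGraph", roiIds = seq_len(R), edges = edges,
      nodeFeatures = matrix(0, 0, 0), lambda = NA_real_,
      precision = matrix(0, 0, 0), meta = list())
}

# tiny but complete cohort with volumes (shared by train/pipeline tests)
fixtureCohort <- function() {
  if (is.null(ndFixtures$cohort)) {
    cfg <- cohortConfig(nModeling = 40L, nPretrainExtra = 20L,
                        atlasShape = c(8L, 8L, 8L), nRois = 10L)
    ndFixtures$cohort <- makeCohort(cfg, seed = 42L)
  }
  ndFixtures$cohort
}

fixturePrepared <- function() {
  if (is.null(ndFixtures$prepared))
    ndFixtures$prepared <- prepareCohortData(fixtureCohort(), seed = 42L,
                                             lambda = 0.3)
  ndFixtures$prepared
}

# central-difference numerical gradient
numGrad <- function(f, theta, eps = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

# analytic-vs-numerical gradient check for one module
expectGradMatch <- function(mod, x, fwd, bwd, tol = 1e-6) {
  r <- fwd(mod, x)
  g <- bwd(mod, r$cache, r$out)
  theta <- neurodecline:::nnFlattenParams(mod)
  if (length(theta)) {
    ga <- neurodecline:::nnFlattenGrads(mod, g)
    gn <- numGrad(function(th) {
      m <- neurodecline:::nnSetFlatParams(mod, th)
      sum(fwd(m, x)$out^2) / 2
    }, theta)
    expect_lt(max(abs(ga - gn)), tol)
  }
  gnx <- numGrad(function(xv) {
    x2 <- x; x2[] <- xv
    sum(fwd(mod, x2)$out^2) / 2
  }, as.vector(x))
  expect_lt(max(abs(as.vector(g$gin) - gnx)), tol)
}
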