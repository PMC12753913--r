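# Model zoo contracts: parameter counts, seeded determinism, permutation
# invariances, expressiveness, architecture wiring, finiteness.

test_that("FFN parameter counts match the closed-form weight/bias count", {
  cfg <- embeddingModelConfig("ffn", embeddingDim = 16L, hidden = c(32L, 32L))
  m <- buildEmbeddingModel(cfg, list(kind = "tabular", dim = 10L), seed = 1)
  # dense(10->32) + bn + dense(32->32) + bn + dense(32->16)
  expected <- (10 * 32 + 32) + 2 * 32 + (32 * 32 + 32) + 2 * 32 +
    (32 * 16 + 16)
  expect_equal(paramCount(m), expected)
  aux <- buildAuxEncoder(7L, D = 16L)
  expected <- (7 * 32 + 32) + 2 * 32 + (32 * 32 + 32) + 2 * 32 +
    (32 * 16 + 16)
  expect_equal(paramCount(aux), expected)
})

test_that("identical seeds give identical initial weights; different seeds differ", {
  cfg <- embeddingModelConfig("ffn", embeddingDim = 8L, hidden = 16L)
  is <- list(kind = "tabular", dim = 6L)
  nd <- asNamespace("neurodecline")
  w1 <- nd$nnFlattenParams(buildEmbeddingModel(cfg, is, seed = 5)$net)
  w2 <- nd$nnFlattenParams(buildEmbeddingModel(cfg, is, seed = 5)$net)
  w3 <- nd$nnFlattenParams(buildEmbeddingModel(cfg, is, seed = 6)$net)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
})

test_that("GNN graph embeddings are invariant to node permutation", {
  nd <- asNamespace("neurodecline")
  A <- fixtureGraphAdj()
  set.seed(61)
  for (kind in c("GCN", "GAT", "GIN")) {
    enc <- nd$ndGnnEncoder(3, 8, 2, kind, A, 5, dropout = 0)
    for (i in 1:20) {
      X <- matrix(rnorm(18), 6)
      e1 <- nd$nnGnnEncForward(enc, X, FALSE)$out
      p <- sample(6)
      Ap <- A[p, p]
      encP <- nd$ndGnnEncoder(3, 8, 2, kind, Ap, 5, dropout = 0)
      # same weights, permuted graph
      encP <- nd$nnSetFlatParams(encP, nd$nnFlattenParams(enc))
      e2 <- nd$nnGnnEncForward(encP, X[p, , drop = FALSE], FALSE)$out
      expect_lt(max(abs(e1 - e2)), 1e-5)
    }
  }
})

test_that("attention fusion output is invariant to token order", {
  nd <- asNamespace("neurodecline")
  set.seed(62)
  mha <- nd$ndMha(16L, heads = 8L, dropout = 0)
  for (i in 1:100) {
    X <- matrix(rnorm(4 * 16), 4)
    o1 <- colMeans(nd$nnMhaForward(mha, X, FALSE)$out)
    p <- sample(4)
    o2 <- colMeans(nd$nnMhaForward(mha, X[p, , drop = FALSE], FALSE)$out)
    expect_lt(max(abs(o1 - o2)), 1e-5)
  }
  # full fusion model: permuting the modality stack order leaves the
  # prediction unchanged
  Z <- list(mri = matrix(rnorm(8), 2), fdg = matrix(rnorm(8), 2),
            av45 = matrix(rnorm(8), 2))
  fus <- buildFusionModel(c(mri = 4L, fdg = 4L, av45 = 4L), outDim = 3L,
                          task = "multiclass", seed = 63)
  o1 <- fuseAndPredict(fus, Z)
  fusP <- fus
  fusP$net$cfg$modalities <- c("av45", "mri", "fdg")
  o2 <- fuseAndPredict(fusP, Z)
  expect_lt(max(abs(o1 - o2)), 1e-5)
  expect_equal(rowSums(o1), c(1, 1), tolerance = 1e-6)
})

test_that("single-token fusion works and binary/multiclass outputs are proper", {
  Z <- list(fdg = matrix(rnorm(6), 2))
  fus <- buildFusionModel(c(fdg = 3L), outDim = 1L, task = "binary",
                          seed = 64)
  out <- fuseAndPredict(fus, Z)
  expect_identical(dim(out), c(2L, 1L))
  expect_true(all(is.finite(out)) && all(out > 0 & out < 1))
  expect_error(fuseAndPredict(fus, list()), "at least one")
})

test_that("the pre-training head shares its trunk and emits one group per task", {
  spec <- defaultPretrainTaskSpec()
  head <- buildPretrainHead(12L, spec, seed = 65)
  emb <- matrix(rnorm(36), 3)
  preds <- multitaskPretrainForward(head, emb)
  expect_length(preds, 7L)
  expect_named(preds, taskNames(spec))
  expect_identical(dim(preds$dx_now), c(3L, 3L))
  expect_identical(dim(preds$slope_memory), c(3L, 1L))
  nd <- asNamespace("neurodecline")
  r <- nd$mtHeadForward(head, emb, FALSE)
  expect_identical(dim(r$trunkOut), c(3L, 48L))   # one trunk for all heads
})

test_that("auxiliary tokens have the shared width and evaluation is deterministic", {
  aux <- buildAuxEncoder(7L, D = 16L, seed = 66)
  x <- rnorm(7)
  t1 <- encodeAux(aux, x)
  expect_identical(dim(t1), c(1L, 16L))
  expect_identical(t1, encodeAux(aux, x))
  expect_error(encodeAux(aux, rnorm(5)), "does not match")
})

test_that("GIN with sum pooling separates non-isomorphic graphs with identical features", {
  nd <- asNamespace("neurodecline")
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  star4 <- matrix(0, 4, 4)
  star4[1, 2:4] <- 1
  star4 <- star4 + t(star4)
  set.seed(67)
  enc <- nd$ndGnnEncoder(2, 8, 2, "GIN", path4, 4, dropout = 0,
                         pooling = "sum")
  encS <- nd$ndGnnEncoder(2, 8, 2, "GIN", star4, 4, dropout = 0,
                          pooling = "sum")
  encS <- nd$nnSetFlatParams(encS, nd$nnFlattenParams(enc))
  X <- matrix(1, 4, 2)
  e1 <- nd$nnGnnEncForward(enc, X, FALSE)$out
  e2 <- nd$nnGnnEncForward(encS, X, FALSE)$out
  expect_gt(max(abs(e1 - e2)), 1e-4)
})

test_that("every model family yields finite outputs on random inputs", {
  set.seed(68)
  graph <- fixtureBrainGraph()
  grid <- list(
    list(cfg = embeddingModelConfig("ffn", embeddingDim = 8L),
         is = list(kind = "tabular", dim = 12L),
         x = matrix(rnorm(36), 3)),
    list(cfg = embeddingModelConfig("cnn_scaffold", embeddingDim = 6L,
                                    channels = c(2L, 4L)),
         is = list(kind = "volume", dims = c(8L, 8L, 8L), channels = 1L),
         x = list(array(rnorm(512), c(8, 8, 8)))),
    list(cfg = embeddingModelConfig("cnn_densenet3d", embeddingDim = 6L,
                                    blocks = c(2L, 2L), growth = 2L),
         is = list(kind = "volume", dims = c(8L, 8L, 8L), channels = 1L),
         x = list(array(rnorm(512), c(8, 8, 8)))),
    list(cfg = embeddingModelConfig("gnn", kind = "GAT", channels = 8L,
                                    nLayers = 2L, embeddingDim = 6L),
         is = list(kind = "graph", graph = graph, nodeDim = 2L),
         x = list(matrix(rnorm(12), 6))),
    list(cfg = embeddingModelConfig("gnn", kind = "GCN", channels = 8L,
                                    nLayers = 3L, embeddingDim = 6L,
                                    pooling = "sum", jumpingKnowledge = FALSE),
         is = list(kind = "graph", graph = graph, nodeDim = 2L),
         x = list(matrix(rnorm(12), 6))))
  nd <- asNamespace("neurodecline")
  for (g in grid) {
    m <- buildEmbeddingModel(g$cfg, g$is, seed = 69)
    emb <- nd$encoderForward(m, g$x, training = FALSE)$emb
    expect_true(all(is.finite(emb)))
    expect_equal(ncol(emb), g$cfg$embeddingDim)
  }
  expect_error(buildEmbeddingModel(
    embeddingModelConfig("ffn"), list(kind = "volume", dims = c(8L, 8L, 8L))),
    "tabular")
})
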