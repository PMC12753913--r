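#' Configuration for a modality embedding model
#'
#' Describes one member of the model zoo used as a modality-specific encoder
#' (or joint encoder): a feed-forward network on ROI feature vectors, a 3D
#' convolutional network on downsampled volumes (plain conv scaffold or a 3D
#' DenseNet), or a graph neural network on atlas brain graphs. Defaults
#' follow the best-performing configurations of the study this package
#' implements: GNNs with 6 message-passing layers, 128 channels, graph
#' normalization, dropout 0.1 and ELU activations; the 3D DenseNet with
#' bottleneck blocks of 4, 6 and 8 layers, growth rate 4, compression 1.0
#' and instance normalization.
#'
#' @param family one of \code{"ffn"}, \code{"cnn_scaffold"},
#'   \code{"cnn_densenet3d"}, \code{"gnn"}.
#' @param embeddingDim width of the output embedding.
#' @param hidden FFN hidden widths.
#' @param channels CNN-scaffold channel widths (one per conv block) or GNN
#'   channel width.
#' @param nLayers GNN message-passing depth.
#' @param kind GNN message-passing family: \code{"GCN"}, \code{"GAT"},
#'   \code{"GIN"}.
#' @param pooling GNN graph pooling, \code{"mean"} or \code{"sum"}.
#' @param jumpingKnowledge concatenate all message-passing layer outputs
#'   before pooling.
#' @param dropout dropout rate.
#' @param act activation function name.
#' @param blocks DenseNet bottleneck layers per block.
#' @param growth DenseNet growth rate.
#' @param compression DenseNet transition compression factor.
#' @param norm normalization kind for CNNs (only \code{"instance"} is
#'   supported in volume encoders).
#' @return an \code{EmbeddingModelConfig} list.
#' @export
embeddingModelConfig <- function(family = c("ffn", "cnn_scaffold",
                                            "cnn_densenet3d", "gnn"),
                                 embeddingDim = 32L, hidden = c(128L, 64L),
                                 channels = NULL, nLayers = 6L,
                                 kind = c("GAT", "GCN", "GIN"),
                                 pooling = c("mean", "sum"),
                                 jumpingKnowledge = TRUE, dropout = 0.1,
                                 act = NULL, blocks = c(4L, 6L, 8L),
                                 growth = 4L, compression = 1.0,
                                 norm = "instance") {
  family <- match.arg(family)
  if (embeddingDim <= 0L) stop("embeddingDim must be positive")
  cfg <- list(family = family, embeddingDim = as.integer(embeddingDim),
              hidden = hidden,
              channels = channels %||%
                switch(family, gnn = 128L, cnn_scaffold = c(8L, 16L, 32L, 64L),
                       NULL),
              nLayers = as.integer(nLayers), kind = match.arg(kind),
              pooling = match.arg(pooling),
              jumpingKnowledge = isTRUE(jumpingKnowledge), dropout = dropout,
              act = act %||% switch(family, ffn = "silu", "elu"),
              blocks = as.integer(blocks), growth = as.integer(growth),
              compression = compression, norm = norm)
  class(cfg) <- "EmbeddingModelConfig"
  cfg
}

#' Build a modality embedding model
#'
#' Instantiates an encoder mapping one input (ROI feature vector, volume, or
#' brain graph) to an embedding vector. Weights are initialized
#' deterministically from \code{seed}.
#'
#' @param config an \code{\link{embeddingModelConfig}}.
#' @param inputSpec list describing the input representation:
#'   \code{list(kind = "tabular", dim = p)},
#'   \code{list(kind = "volume", dims = c(d1, d2, d3), channels = c)}, or
#'   \code{list(kind = "graph", graph = <BrainGraph>, nodeDim = d)}.
#' @param seed integer seed for weight initialization.
#' @return an object of class \code{ndEmbeddingModel}; query its size with
#'   \code{\link{paramCount}}.
#' @export
buildEmbeddingModel <- function(config, inputSpec, seed = 1L) {
  stopifnot(inherits(config, "EmbeddingModelConfig"))
  set.seed(as.integer(seed))
  net <- switch(config$family,
    ffn = {
      if (inputSpec$kind != "tabular")
        stop("ffn family requires tabular input")
      layers <- list()
      din <- inputSpec$dim
      for (h in config$hidden) {
        layers <- c(layers, list(ndDense(din, h), ndBatchNorm(h),
                                 ndAct(config$act), ndDropout(config$dropout)))
        din <- h
      }
      layers <- c(layers, list(ndDense(din, config$embeddingDim)))
      ndSeq(layers)
    },
    cnn_scaffold = {
      if (inputSpec$kind != "volume")
        stop("cnn families require volume input")
      d <- inputSpec$dims
      cin <- inputSpec$channels %||% 1L
      layers <- list()
      for (co in config$channels) {
        if (any(d %% 2L != 0L))
          stop("volume dims must halve cleanly at every pooling stage")
        layers <- c(layers, list(
          ndConv3d(cin, co), ndInstNorm(co), ndAct(config$act),
          ndConv3d(co, co), ndInstNorm(co), ndAct(config$act),
          ndMaxPool3d(), ndDropout(config$dropout)))
        cin <- co
        d <- d %/% 2L
      }
      layers <- c(layers, list(ndFlatten3d(),
                               ndDense(prod(d) * cin, config$embeddingDim)))
      ndSeq(layers)
    },
    cnn_densenet3d = {
      if (inputSpec$kind != "volume")
        stop("cnn families require volume input")
      d <- inputSpec$dims
      cin <- inputSpec$channels %||% 1L
      g <- config$growth
      layers <- list(ndConv3d(cin, 2L * g))
      ch <- 2L * g
      for (bi in seq_along(config$blocks)) {
        for (li in seq_len(config$blocks[bi])) {
          # bottleneck: norm-act-conv1(4g) -> norm-act-conv3(g), concat
          layers <- c(layers, list(structure(list(
            type = "denseblocklayer",
            layers = list(ndInstNorm(ch), ndAct(config$act),
                          ndConv3d(ch, 4L * g, k = 1L),
                          ndInstNorm(4L * g), ndAct(config$act),
                          ndConv3d(4L * g, g)),
            cfg = list(cin = ch, growth = g)))))
          ch <- ch + g
        }
        if (bi < length(config$blocks)) {
          cout <- as.integer(floor(ch * config$compression))
          if (any(d %% 2L != 0L))
            stop("volume dims must halve cleanly at every transition")
          layers <- c(layers, list(ndInstNorm(ch), ndAct(config$act),
                                   ndConv3d(ch, cout, k = 1L), ndAvgPool3d()))
          ch <- cout
          d <- d %/% 2L
        }
      }
      layers <- c(layers, list(ndInstNorm(ch), ndAct(config$act),
                               ndGlobalAvgPool(),
                               ndDense(ch, config$embeddingDim)))
      ndSeq(layers)
    },
    gnn = {
      if (inputSpec$kind != "graph")
        stop("gnn family requires graph input")
      A <- adjacencyMatrix(inputSpec$graph)
      ndGnnEncoder(inputSpec$nodeDim, config$channels, config$nLayers,
                   config$kind, A, config$embeddingDim,
                   pooling = config$pooling, jk = config$jumpingKnowledge,
                   dropout = config$dropout, act = config$act)
    })
  structure(list(net = net, config = config, inputSpec = inputSpec,
                 seed = as.integer(seed), frozen = FALSE),
            class = "ndEmbeddingModel")
}

#' @export
print.ndEmbeddingModel <- function(x, ...) {
  cat("ndEmbeddingModel <", x$config$family, ">: embedding width ",
      x$config$embeddingDim, ", ", paramCount(x), " parameters",
      if (x$frozen) " [frozen]", "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a model object
#'
#' @param model an embedding model, fusion model, or pre-training head.
#' @export
paramCount <- function(model) {
  if (inherits(model, "ndEmbeddingModel")) return(nnParamCount(model$net))
  if (!is.null(model$net)) return(nnParamCount(model$net))
  nnParamCount(model)
}

# forward a batch of inputs through an encoder; returns n x E embeddings.
# `inputs`: matrix (tabular) or list of arrays/matrices (volume/graph).
encoderForward <- function(model, inputs, training = FALSE) {
  net <- model$net
  if (model$inputSpec$kind == "tabular") {
    r <- nnForward(net, inputs, training)
    return(list(emb = r$out, caches = r$cache, model = {
      model$net <- r$mod; model
    }))
  }
  denseblockAware <- function(mod, x, training) {
    if (mod$type == "denseblocklayer") nnDenseBlockForward(mod, x, training)
    else if (mod$type == "gnnenc") nnGnnEncForward(mod, x, training)
    else nnForward(mod, x, training)
  }
  n <- length(inputs)
  caches <- vector("list", n)
  emb <- NULL
  for (s in seq_len(n)) {
    x <- inputs[[s]]
    if (model$inputSpec$kind == "volume" && length(dim(x)) == 3L)
      dim(x) <- c(dim(x), 1L)
    if (net$type == "gnnenc") {
      r <- nnGnnEncForward(net, x, training)
      caches[[s]] <- r$cache
      net <- r$mod
      e <- r$out
    } else {
      cc <- vector("list", length(net$layers))
      for (i in seq_along(net$layers)) {
        r <- denseblockAware(net$layers[[i]], x, training)
        x <- r$out
        cc[[i]] <- r$cache
        net$layers[[i]] <- r$mod
      }
      caches[[s]] <- cc
      e <- x
    }
    if (is.null(emb)) emb <- matrix(0, n, length(e))
    emb[s, ] <- e
  }
  model$net <- net
  list(emb = emb, caches = caches, model = model)
}

# backward: gEmb is n x E; returns grad tree for model$net (summed over the
# batch). For per-sample encoders grads accumulate across samples.
encoderBackward <- function(model, caches, gEmb) {
  net <- model$net
  if (model$inputSpec$kind == "tabular")
    return(nnBackward(net, caches, gEmb))
  addGrads <- function(a, b) {
    if (is.null(a)) return(b)
    if (!is.null(b$gpar))
      for (nm in names(b$gpar)) a$gpar[[nm]] <- a$gpar[[nm]] + b$gpar[[nm]]
    if (!is.null(b$glayers))
      for (i in seq_along(b$glayers))
        a$glayers[[i]] <- addGrads(a$glayers[[i]], b$glayers[[i]])
    a
  }
  total <- NULL
  for (s in seq_len(nrow(gEmb))) {
    gout <- matrix(gEmb[s, ], 1L)
    if (net$type == "gnnenc") {
      g <- nnGnnEncBackward(net, caches[[s]], gout)
      gTree <- list(gpar = NULL, glayers = g$glayers)
    } else {
      glayers <- vector("list", length(net$layers))
      gcur <- gout
      for (i in rev(seq_along(net$layers))) {
        mod <- net$layers[[i]]
        r <- if (mod$type == "denseblocklayer")
          nnDenseBlockBackward(mod, caches[[s]][[i]], gcur)
        else nnBackward(mod, caches[[s]][[i]], gcur)
        glayers[[i]] <- list(gpar = r$gpar, glayers = r$glayers)
        gcur <- r$gin
      }
      gTree <- list(gpar = NULL, glayers = glayers)
    }
    total <- addGrads(total, gTree)
  }
  total
}

# DenseNet bottleneck layer: runs its sub-stack and concatenates the input
# with the new feature maps along the channel axis.
nnDenseBlockForward <- function(mod, x, training) {
  cc <- vector("list", length(mod$layers))
  h <- x
  for (i in seq_along(mod$layers)) {
    r <- nnForward(mod$layers[[i]], h, training)
    h <- r$out
    cc[[i]] <- r$cache
    mod$layers[[i]] <- r$mod
  }
  d <- dim(x)
  out <- array(0, c(d[1:3], d[4L] + mod$cfg$growth))
  out[, , , seq_len(d[4L])] <- x
  out[, , , d[4L] + seq_len(mod$cfg$growth)] <- h
  list(out = out, cache = list(cc = cc, cin = d[4L]), mod = mod)
}

nnDenseBlockBackward <- function(mod, cache, gout) {
  cin <- cache$cin
  gx <- gout[, , , seq_len(cin), drop = FALSE]
  gh <- gout[, , , cin + seq_len(mod$cfg$growth), drop = FALSE]
  glayers <- vector("list", length(mod$layers))
  gcur <- gh
  for (i in rev(seq_along(mod$layers))) {
    r <- nnBackward(mod$layers[[i]], cache$cc[[i]], gcur)
    glayers[[i]] <- list(gpar = r$gpar, glayers = r$glayers)
    gcur <- r$gin
  }
  list(gpar = NULL, gin = gx + gcur, glayers = glayers)
}

#' Build the auxiliary (demographic + neuropsychological) encoder
#'
#' A two-layer feed-forward network with hidden width 32, SiLU activations,
#' batch normalization in both layers and dropout 0.1 in the first, followed
#' by a linear projection to the shared token width D.
#'
#' @param inputDim number of auxiliary features.
#' @param D shared token width (default 16).
#' @param hidden hidden width (default 32).
#' @param seed seed for weight initialization.
#' @export
buildAuxEncoder <- function(inputDim, D = 16L, hidden = 32L, seed = 1L) {
  set.seed(as.integer(seed))
  net <- ndSeq(list(
    ndDense(inputDim, hidden), ndBatchNorm(hidden), ndAct("silu"),
    ndDropout(0.1),
    ndDense(hidden, hidden), ndBatchNorm(hidden), ndAct("silu"),
    ndDense(hidden, D)))
  structure(list(net = net, inputDim = inputDim, D = D,
                 seed = as.integer(seed)),
            class = "ndAuxEncoder")
}

#' Encode auxiliary features into a fusion token
#'
#' Runs the auxiliary encoder in evaluation mode (deterministic: no dropout,
#' normalization uses running statistics).
#'
#' @param model an encoder from \code{\link{buildAuxEncoder}}.
#' @param x numeric vector of length \code{inputDim} or a matrix with one
#'   row per observation.
#' @return matrix of tokens, one row per observation, width D.
#' @export
encodeAux <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (ncol(x) != model$inputDim)
    stop("auxiliary feature width ", ncol(x), " does not match trained width ",
         model$inputDim)
  nnForward(model$net, x, training = FALSE)$out
}

#' Build the attention late-fusion model
#'
#' Per-modality linear projections W_m map frozen embeddings to a common
#' token width D; tokens (plus an optional auxiliary token) are fused by an
#' 8-head multi-head attention layer (embedding dimension 16, attention
#' dropout 0.1, mean pooling over tokens) and passed to a four-layer
#' feed-forward head with hidden widths 64, 48, 32 and 16, SiLU activations,
#' batch normalization on the first four layers and dropout 0.1 in the
#' first. The output layer is linear for regression and emits softmax
#' probabilities for classification.
#'
#' @param embeddingDims named integer vector: embedding width per modality.
#' @param auxDim auxiliary feature width, or NULL for no auxiliary token.
#' @param outDim output arity (1 for regression/binary score, k classes).
#' @param task \code{"regression"}, \code{"binary"} or \code{"multiclass"}.
#' @param D token width (default 16). @param heads attention heads (8).
#' @param headWidths fusion head hidden widths.
#' @param dropout dropout rate for the attention weights and the first head
#'   layer (0.1 in the source protocol; desk-scale fits may need more).
#' @param seed seed for weight initialization.
#' @export
buildFusionModel <- function(embeddingDims, auxDim = NULL, outDim = 1L,
                             task = c("regression", "binary", "multiclass"),
                             D = 16L, heads = 8L,
                             headWidths = c(64L, 48L, 32L, 16L),
                             dropout = 0.1, seed = 1L) {
  task <- match.arg(task)
  set.seed(as.integer(seed))
  layers <- list()
  for (m in names(embeddingDims))
    layers[[paste0("proj_", m)]] <- ndDense(embeddingDims[[m]], D)
  if (!is.null(auxDim)) {
    aux <- buildAuxEncoder(auxDim, D = D,
                           seed = as.integer(seed) + 101L)
    layers[["aux"]] <- aux$net
  }
  layers[["mha"]] <- ndMha(D, heads = heads, dropout = dropout)
  hl <- list()
  din <- D
  for (i in seq_along(headWidths)) {
    hl <- c(hl, list(ndDense(din, headWidths[i]), ndBatchNorm(headWidths[i]),
                     ndAct("silu")))
    if (i == 1L) hl <- c(hl, list(ndDropout(dropout)))
    din <- headWidths[i]
  }
  hl <- c(hl, list(ndDense(din, outDim)))
  layers[["head"]] <- ndSeq(hl)
  structure(list(net = list(type = "fusion", layers = layers,
                            cfg = list(modalities = names(embeddingDims),
                                       hasAux = !is.null(auxDim), D = D)),
                 task = task, outDim = outDim, auxDim = auxDim,
                 seed = as.integer(seed)),
            class = "ndFusionModel")
}

# forward: Z named list of n x E_m embedding matrices; xaux n x t or NULL.
fusionForward <- function(model, Z, xaux = NULL, training = FALSE) {
  net <- model$net
  mods <- net$cfg$modalities
  if (length(Z) == 0L) stop("at least one embedding token is required")
  n <- nrow(Z[[1L]])
  tokens <- list()
  caches <- list()
  for (m in mods) {
    r <- nnForward(net$layers[[paste0("proj_", m)]], Z[[m]], training)
    tokens[[m]] <- r$out
    caches[[paste0("proj_", m)]] <- r$cache
    net$layers[[paste0("proj_", m)]] <- r$mod
  }
  if (net$cfg$hasAux) {
    if (is.null(xaux)) stop("model expects auxiliary features")
    r <- nnForward(net$layers[["aux"]], xaux, training)
    tokens[["aux"]] <- r$out
    caches[["aux"]] <- r$cache
    net$layers[["aux"]] <- r$mod
  }
  Tn <- length(tokens)
  D <- net$cfg$D
  pooled <- matrix(0, n, D)
  mhaCaches <- vector("list", n)
  for (s in seq_len(n)) {
    X <- do.call(rbind, lapply(tokens, function(tk) tk[s, ]))
    r <- nnMhaForward(net$layers[["mha"]], X, training)
    mhaCaches[[s]] <- r$cache
    pooled[s, ] <- colMeans(r$out)
  }
  caches[["mha"]] <- mhaCaches
  r <- nnForward(net$layers[["head"]], pooled, training)
  caches[["head"]] <- r$cache
  net$layers[["head"]] <- r$mod
  model$net <- net
  list(out = r$out, caches = caches, model = model, Tn = Tn)
}

fusionBackward <- function(model, caches, gout, Tn) {
  net <- model$net
  mods <- net$cfg$modalities
  glayers <- stats::setNames(vector("list", length(net$layers)),
                             names(net$layers))
  rh <- nnBackward(net$layers[["head"]], caches[["head"]], gout)
  glayers[["head"]] <- list(gpar = NULL, glayers = rh$glayers)
  gpooled <- rh$gin
  n <- nrow(gpooled)
  D <- net$cfg$D
  gtokens <- matrix(0, 0, 0)
  gtok <- array(0, c(n, Tn, D))
  gparMha <- NULL
  for (s in seq_len(n)) {
    gX <- matrix(rep(gpooled[s, ] / Tn, each = Tn), Tn, D)
    r <- nnMhaBackward(net$layers[["mha"]], caches[["mha"]][[s]], gX)
    if (is.null(gparMha)) gparMha <- r$gpar
    else for (nm in names(r$gpar))
      gparMha[[nm]] <- gparMha[[nm]] + r$gpar[[nm]]
    gtok[s, , ] <- r$gin
  }
  glayers[["mha"]] <- list(gpar = gparMha, glayers = NULL)
  gZ <- list()
  ti <- 1L
  for (m in mods) {
    r <- nnBackward(net$layers[[paste0("proj_", m)]],
                    caches[[paste0("proj_", m)]],
                    matrix(gtok[, ti, ], n, D))
    glayers[[paste0("proj_", m)]] <- list(gpar = r$gpar, glayers = NULL)
    gZ[[m]] <- r$gin
    ti <- ti + 1L
  }
  if (net$cfg$hasAux) {
    r <- nnBackward(net$layers[["aux"]], caches[["aux"]],
                    matrix(gtok[, ti, ], n, D))
    glayers[["aux"]] <- list(gpar = NULL, glayers = r$glayers)
  }
  list(gpar = NULL, glayers = glayers, gZ = gZ)
}

#' Fuse modality embeddings and predict a task output
#'
#' Evaluation-mode forward pass of a fusion model: project each modality
#' embedding to a token, run multi-head attention over the token stack (no
#' positional encoding), mean-pool, and apply the fusion head. Multiclass
#' outputs are softmax probabilities summing to 1.
#'
#' @param model a \code{\link{buildFusionModel}} object.
#' @param embeddings named list of embedding matrices (n x E_m), one per
#'   modality the model was built for.
#' @param aux optional auxiliary feature matrix (n x t).
#' @return matrix of task outputs (n x outDim).
#' @export
fuseAndPredict <- function(model, embeddings, aux = NULL) {
  r <- fusionForward(model, embeddings, aux, training = FALSE)
  out <- r$out
  if (model$task == "multiclass") {
    out <- exp(sweep(out, 1L, apply(out, 1L, max)))
    out <- out / rowSums(out)
  } else if (model$task == "binary") {
    out <- 1 / (1 + exp(-out))
  }
  out
}

#' Build the multitask pre-training head
#'
#' A shared trunk (hidden widths 64 and 48, SiLU, batch normalization,
#' dropout 0.1 in the first layer) whose final two layers (widths 32 and 16)
#' are replicated once per task as task-specific heads, each ending in a
#' linear output layer of the task's arity.
#'
#' @param embeddingDim width of the incoming embedding.
#' @param spec a \code{\link{TaskSpec}}.
#' @param seed seed for weight initialization.
#' @export
buildPretrainHead <- function(embeddingDim, spec, seed = 1L) {
  stopifnot(is(spec, "TaskSpec"))
  set.seed(as.integer(seed))
  trunk <- ndSeq(list(
    ndDense(embeddingDim, 64L), ndBatchNorm(64L), ndAct("silu"),
    ndDropout(0.1),
    ndDense(64L, 48L), ndBatchNorm(48L), ndAct("silu")))
  layers <- list(trunk = trunk)
  arities <- taskArities(spec)
  for (tk in names(arities)) {
    layers[[paste0("head_", tk)]] <- ndSeq(list(
      ndDense(48L, 32L), ndBatchNorm(32L), ndAct("silu"),
      ndDense(32L, 16L), ndBatchNorm(16L), ndAct("silu"),
      ndDense(16L, arities[[tk]])))
  }
  structure(list(net = list(type = "mthead", layers = layers,
                            cfg = list(tasks = names(arities))),
                 spec = spec, seed = as.integer(seed)),
            class = "ndPretrainHead")
}

taskArities <- function(spec) {
  ar <- c(stats::setNames(rep(1L, length(spec@binary)), spec@binary),
          vapply(spec@multiclass, length, integer(1)),
          stats::setNames(rep(1L, length(spec@regression)), spec@regression))
  ar[taskNames(spec)]
}

#' Per-task predictions of the multitask pre-training head
#'
#' Runs the shared trunk once and every task-specific head on its output
#' (predictions are produced for all tasks; target masks apply only in the
#' loss). Classification heads emit logits.
#'
#' @param head a \code{\link{buildPretrainHead}} object.
#' @param emb embedding matrix (n x embeddingDim).
#' @return named list of prediction matrices, one per task.
#' @export
multitaskPretrainForward <- function(head, emb) {
  mtHeadForward(head, emb, training = FALSE)$preds
}

mtHeadForward <- function(head, emb, training = FALSE) {
  net <- head$net
  rt <- nnForward(net$layers[["trunk"]], emb, training)
  net$layers[["trunk"]] <- rt$mod
  caches <- list(trunk = rt$cache)
  preds <- list()
  for (tk in net$cfg$tasks) {
    r <- nnForward(net$layers[[paste0("head_", tk)]], rt$out, training)
    preds[[tk]] <- r$out
    caches[[paste0("head_", tk)]] <- r$cache
    net$layers[[paste0("head_", tk)]] <- r$mod
  }
  head$net <- net
  list(preds = preds, caches = caches, head = head, trunkOut = rt$out)
}

mtHeadBackward <- function(head, caches, gpreds) {
  net <- head$net
  glayers <- stats::setNames(vector("list", length(net$layers)),
                             names(net$layers))
  gtrunkOut <- NULL
  for (tk in net$cfg$tasks) {
    r <- nnBackward(net$layers[[paste0("head_", tk)]],
                    caches[[paste0("head_", tk)]], gpreds[[tk]])
    glayers[[paste0("head_", tk)]] <- list(gpar = NULL, glayers = r$glayers)
    gtrunkOut <- if (is.null(gtrunkOut)) r$gin else gtrunkOut + r$gin
  }
  rt <- nnBackward(net$layers[["trunk"]], caches[["trunk"]], gtrunkOut)
  glayers[["trunk"]] <- list(gpar = NULL, glayers = rt$glayers)
  list(gpar = NULL, glayers = glayers, gEmb = rt$gin)
}

#' Read an embedding-model configuration from YAML
#'
#' The YAML keys mirror the arguments of
#' \code{\link{embeddingModelConfig}} (e.g. \code{family},
#' \code{embeddingDim}, \code{channels}, \code{kind}).
#'
#' @param path YAML file.
#' @export
readModelConfigYaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  do.call(embeddingModelConfig, yaml::read_yaml(path))
}

#' Save / load a model checkpoint
#'
#' Weights are serialized in R's native format next to a JSON sidecar
#' recording the configuration hash, seed and parameter count, so a
#' checkpoint's provenance can be inspected without loading it.
#'
#' @param model an \code{ndEmbeddingModel} (or any model object with a
#'   \code{net} field).
#' @param path checkpoint path (an \code{.rds} file); the sidecar is
#'   written as \code{<path>.json}.
#' @export
saveModelCheckpoint <- function(model, path) {
  saveRDS(model, path)
  cfgHash <- sum(as.integer(charToRaw(paste(
    deparse(model$config %||% model$task), collapse = ""))))
  jsonlite::write_json(
    list(configHash = cfgHash, seed = model$seed %||% NA,
         paramCount = paramCount(model),
         frozen = isTRUE(model$frozen)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModelCheckpoint
#' @export
loadModelCheckpoint <- function(path) readRDS(path)
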