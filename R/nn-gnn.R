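# Graph message-passing layers on a fixed atlas graph (node-feature matrix
# X: R x d per sample). Three UPDATE/AGGREGATE families are provided: GCN
# with symmetric normalization, GATv2-style attention with self-loops, and
# GIN (sum aggregation followed by a two-layer MLP). Graph normalization
# standardizes each feature over the nodes of the graph (learnable scale
# and shift). Jumping-knowledge concatenates the outputs of all
# message-passing layers before graph pooling.

ndGraphNorm <- function(n, eps = 1e-5) {
  list(type = "graphnorm",
       par = list(gamma = rep(1, n), beta = numeric(n)),
       cfg = list(n = n, eps = eps))
}

ndGcn <- function(nin, nout, Ahat) {
  list(type = "gcn",
       par = list(W = nnGlorot(nin, nout), b = numeric(nout)),
       cfg = list(Ahat = Ahat))
}

ndGin <- function(nin, nout, A) {
  list(type = "gin",
       par = list(W1 = nnGlorot(nin, nout), b1 = numeric(nout),
                  W2 = nnGlorot(nout, nout), b2 = numeric(nout)),
       cfg = list(A = A))
}

ndGat <- function(nin, nout, src, dst) {
  list(type = "gat",
       par = list(Wl = nnGlorot(nin, nout), Wr = nnGlorot(nin, nout),
                  a = stats::runif(nout, -0.3, 0.3)),
       cfg = list(src = src, dst = dst))
}

# symmetric normalization of (A + I)
gcnNormAdj <- function(A) {
  A <- A + diag(nrow(A))
  dg <- 1 / sqrt(rowSums(A))
  A * outer(dg, dg)
}

nnGnnLayerForward <- function(mod, x, training) {
  switch(mod$type,
    gcn = {
      ax <- mod$cfg$Ahat %*% x
      out <- sweep(ax %*% mod$par$W, 2L, mod$par$b, "+")
      list(out = out, cache = list(ax = ax), mod = mod)
    },
    gin = {
      s <- x + mod$cfg$A %*% x
      h1 <- sweep(s %*% mod$par$W1, 2L, mod$par$b1, "+")
      r <- pmax(h1, 0)
      out <- sweep(r %*% mod$par$W2, 2L, mod$par$b2, "+")
      list(out = out, cache = list(s = s, h1 = h1, r = r), mod = mod)
    },
    gat = {
      src <- mod$cfg$src; dst <- mod$cfg$dst
      Hl <- x %*% mod$par$Wl
      Hr <- x %*% mod$par$Wr
      s <- Hl[dst, , drop = FALSE] + Hr[src, , drop = FALSE]
      z <- ifelse(s > 0, s, 0.2 * s)
      e <- as.vector(z %*% mod$par$a)
      emax <- stats::ave(e, dst, FUN = max)
      ex <- exp(e - emax)
      denom <- stats::ave(ex, dst, FUN = sum)
      alpha <- ex / denom
      msg <- alpha * Hr[src, , drop = FALSE]
      out <- rowsum(msg, dst)
      list(out = out,
           cache = list(x = x, Hl = Hl, Hr = Hr, s = s, z = z,
                        alpha = alpha),
           mod = mod)
    },
    nnForward(mod, x, training))
}

nnGnnLayerBackward <- function(mod, cache, gout) {
  switch(mod$type,
    gcn = {
      gax <- gout %*% t(mod$par$W)
      list(gpar = list(W = crossprod(cache$ax, gout), b = colSums(gout)),
           gin = t(mod$cfg$Ahat) %*% gax)
    },
    gin = {
      gr <- gout %*% t(mod$par$W2)
      gh1 <- gr * (cache$h1 > 0)
      gs <- gh1 %*% t(mod$par$W1)
      gin <- gs + t(mod$cfg$A) %*% gs
      list(gpar = list(W1 = crossprod(cache$s, gh1), b1 = colSums(gh1),
                       W2 = crossprod(cache$r, gout), b2 = colSums(gout)),
           gin = gin)
    },
    gat = {
      src <- mod$cfg$src; dst <- mod$cfg$dst
      alpha <- cache$alpha
      Hr <- cache$Hr
      gmsg <- gout[dst, , drop = FALSE]
      gHr <- rowsum(alpha * gmsg, src)
      galpha <- rowSums(gmsg * Hr[src, , drop = FALSE])
      S <- stats::ave(alpha * galpha, dst, FUN = sum)
      ge <- alpha * (galpha - S)
      gz <- outer(ge, mod$par$a)
      gs <- gz * ifelse(cache$s > 0, 1, 0.2)
      gHl <- rowsum(gs, dst)
      gHr <- gHr + rowsum(gs, src)
      ga <- colSums(cache$z * ge)
      x <- cache$x
      gin <- gHl %*% t(mod$par$Wl) + gHr %*% t(mod$par$Wr)
      list(gpar = list(Wl = crossprod(x, gHl), Wr = crossprod(x, gHr),
                       a = ga),
           gin = gin)
    },
    graphnorm = nnBackward(mod, cache, gout),
    nnBackward(mod, cache, gout))
}

# graphnorm shares the instance-norm math (features standardized over rows)
nnGraphNormForward <- function(mod, x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + mod$cfg$eps)
  xh <- sweep(xc, 2L, inv, "*")
  out <- sweep(sweep(xh, 2L, mod$par$gamma, "*"), 2L, mod$par$beta, "+")
  list(out = out, cache = list(xh = xh, inv = inv), mod = mod)
}

nnGraphNormBackward <- function(mod, cache, gout) {
  xh <- cache$xh
  ggamma <- colSums(gout * xh)
  gbeta <- colSums(gout)
  gxh <- sweep(gout, 2L, mod$par$gamma, "*")
  n <- nrow(xh)
  gin <- sweep(gxh -
               matrix(colMeans(gxh), n, ncol(xh), byrow = TRUE) -
               xh * matrix(colMeans(gxh * xh), n, ncol(xh), byrow = TRUE),
               2L, cache$inv, "*")
  list(gpar = list(gamma = ggamma, beta = gbeta), gin = gin)
}

## GNN encoder composite: blocks of (mp, norm, act, dropout), optional
## jumping knowledge, mean/sum graph pooling, final dense projection.

ndGnnEncoder <- function(nin, channels, nLayers, kind, graphA, embeddingDim,
                         pooling = "mean", jk = TRUE, dropout = 0.1,
                         act = "elu") {
  R <- nrow(graphA)
  Ahat <- gcnNormAdj(graphA)
  Asl <- graphA + diag(R)
  ePairs <- which(Asl != 0, arr.ind = TRUE)
  src <- ePairs[, 2L]
  dst <- ePairs[, 1L]
  ord <- order(dst, src)
  src <- src[ord]; dst <- dst[ord]
  layers <- list()
  din <- nin
  for (i in seq_len(nLayers)) {
    mp <- switch(kind,
      GCN = ndGcn(din, channels, Ahat),
      GIN = ndGin(din, channels, graphA),
      GAT = ndGat(din, channels, src, dst),
      stop("unknown GNN kind: ", kind))
    layers[[length(layers) + 1L]] <- mp
    layers[[length(layers) + 1L]] <- ndGraphNorm(channels)
    layers[[length(layers) + 1L]] <- ndAct(act)
    layers[[length(layers) + 1L]] <- ndDropout(dropout)
    din <- channels
  }
  pooledDim <- if (jk) nLayers * channels else channels
  layers[[length(layers) + 1L]] <- ndDense(pooledDim, embeddingDim)
  list(type = "gnnenc", layers = layers,
       cfg = list(nLayers = nLayers, jk = jk, pooling = pooling, R = R))
}

nnGnnEncForward <- function(mod, x, training) {
  k <- mod$cfg$nLayers
  caches <- vector("list", length(mod$layers))
  blockOut <- vector("list", k)
  idx <- 1L
  for (i in seq_len(k)) {
    for (j in 1:4) {
      r <- if (j == 1L) nnGnnLayerForward(mod$layers[[idx]], x, training)
           else if (mod$layers[[idx]]$type == "graphnorm")
             nnGraphNormForward(mod$layers[[idx]], x)
           else nnForward(mod$layers[[idx]], x, training)
      x <- r$out
      caches[[idx]] <- r$cache
      mod$layers[[idx]] <- r$mod
      idx <- idx + 1L
    }
    blockOut[[i]] <- x
  }
  H <- if (mod$cfg$jk) do.call(cbind, blockOut) else x
  pooled <- if (mod$cfg$pooling == "mean") colMeans(H) else colSums(H)
  pooled <- matrix(pooled, 1L)
  r <- nnForward(mod$layers[[idx]], pooled, training)
  caches[[idx]] <- r$cache
  mod$layers[[idx]] <- r$mod
  list(out = r$out, cache = caches, mod = mod)
}

nnGnnEncBackward <- function(mod, cache, gout) {
  k <- mod$cfg$nLayers
  nl <- length(mod$layers)
  glayers <- vector("list", nl)
  rOut <- nnBackward(mod$layers[[nl]], cache[[nl]], gout)
  glayers[[nl]] <- list(gpar = rOut$gpar, glayers = NULL)
  gpooled <- as.vector(rOut$gin)
  R <- mod$cfg$R
  gH <- matrix(rep(gpooled, each = R), R)
  if (mod$cfg$pooling == "mean") gH <- gH / R
  ch <- ncol(gH) / if (mod$cfg$jk) k else 1L
  gx <- matrix(0, R, ch)
  for (i in rev(seq_len(k))) {
    gblock <- if (mod$cfg$jk)
      gH[, ((i - 1L) * ch + 1L):(i * ch), drop = FALSE]
    else if (i == k) gH else matrix(0, R, ch)
    gcur <- gx + gblock
    for (j in 4:1) {
      idx <- (i - 1L) * 4L + j
      r <- if (j == 1L)
        nnGnnLayerBackward(mod$layers[[idx]], cache[[idx]], gcur)
      else if (mod$layers[[idx]]$type == "graphnorm")
        nnGraphNormBackward(mod$layers[[idx]], cache[[idx]], gcur)
      else nnBackward(mod$layers[[idx]], cache[[idx]], gcur)
      glayers[[idx]] <- list(gpar = r$gpar, glayers = r$glayers)
      gcur <- r$gin
    }
    gx <- gcur
  }
  list(gpar = NULL, gin = gx, glayers = glayers)
}
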