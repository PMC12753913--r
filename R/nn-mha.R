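# Multi-head attention over a small stack of modality tokens (T x D per
# sample), followed by mean pooling. The layer is a bare MHA block: no
# positional encoding and no residual/layer-norm wrapper, so the pooled
# output is invariant to token order (pinned by a property test).

ndMha <- function(D, heads = 8L, dropout = 0.1) {
  stopifnot(D %% heads == 0L)
  list(type = "mha",
       par = list(Wq = nnGlorot(D, D), bq = numeric(D),
                  Wk = nnGlorot(D, D), bk = numeric(D),
                  Wv = nnGlorot(D, D), bv = numeric(D),
                  Wo = nnGlorot(D, D), bo = numeric(D)),
       cfg = list(D = D, heads = heads, dh = D %/% heads, dropout = dropout))
}

nnMhaForward <- function(mod, x, training = FALSE) {
  D <- mod$cfg$D; H <- mod$cfg$heads; dh <- mod$cfg$dh
  Tn <- nrow(x)
  Q <- sweep(x %*% mod$par$Wq, 2L, mod$par$bq, "+")
  K <- sweep(x %*% mod$par$Wk, 2L, mod$par$bk, "+")
  V <- sweep(x %*% mod$par$Wv, 2L, mod$par$bv, "+")
  O <- matrix(0, Tn, D)
  Ps <- vector("list", H)
  masks <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    L <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    L <- sweep(L, 1L, apply(L, 1L, max))
    P <- exp(L)
    P <- P / rowSums(P)
    if (training && mod$cfg$dropout > 0) {
      keep <- 1 - mod$cfg$dropout
      mk <- (stats::runif(length(P)) < keep) / keep
      dim(mk) <- dim(P)
      masks[[h]] <- mk
      Pd <- P * mk
    } else Pd <- P
    Ps[[h]] <- list(P = P, Pd = Pd)
    O[, cols] <- Pd %*% V[, cols, drop = FALSE]
  }
  out <- sweep(O %*% mod$par$Wo, 2L, mod$par$bo, "+")
  list(out = out,
       cache = list(x = x, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    masks = masks),
       mod = mod)
}

nnMhaBackward <- function(mod, cache, gout) {
  D <- mod$cfg$D; H <- mod$cfg$heads; dh <- mod$cfg$dh
  x <- cache$x
  gWo <- crossprod(cache$O, gout)
  gbo <- colSums(gout)
  gO <- gout %*% t(mod$par$Wo)
  gQ <- matrix(0, nrow(x), D)
  gK <- matrix(0, nrow(x), D)
  gV <- matrix(0, nrow(x), D)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    P <- cache$Ps[[h]]$P
    Pd <- cache$Ps[[h]]$Pd
    Vh <- cache$V[, cols, drop = FALSE]
    gOh <- gO[, cols, drop = FALSE]
    gPd <- gOh %*% t(Vh)
    gV[, cols] <- crossprod(Pd, gOh)
    gP <- if (is.null(cache$masks[[h]])) gPd else gPd * cache$masks[[h]]
    gL <- P * (gP - rowSums(gP * P))
    gQ[, cols] <- (gL %*% cache$K[, cols, drop = FALSE]) / sqrt(dh)
    gK[, cols] <- (t(gL) %*% cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  gin <- gQ %*% t(mod$par$Wq) + gK %*% t(mod$par$Wk) + gV %*% t(mod$par$Wv)
  list(gpar = list(Wq = crossprod(x, gQ), bq = colSums(gQ),
                   Wk = crossprod(x, gK), bk = colSums(gK),
                   Wv = crossprod(x, gV), bv = colSums(gV),
                   Wo = gWo, bo = gbo),
       gin = gin)
}
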