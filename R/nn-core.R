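# Compact neural-network engine: layer modules with analytic backprop.
#
# A module is a plain list with fields:
#   type    layer kind (dispatch key)
#   par     named list of numeric arrays (trainable parameters)
#   layers  named/ordered list of child modules (composites only)
#   cfg     static configuration
# Forward passes return list(out, cache, mod); `mod` is returned because
# normalization layers update running statistics during training. Backward
# passes return list(gpar, gin, glayers) mirroring the module tree. All
# correctness is pinned by finite-difference gradient checks in the tests.

nnGlorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

## ---- activations --------------------------------------------------------

nnActForward <- function(kind, x) {
  switch(kind,
    linear = x,
    relu = pmax(x, 0),
    silu = x / (1 + exp(-x)),
    elu = ifelse(x > 0, x, expm1(x)),
    leakyrelu = ifelse(x > 0, x, 0.2 * x),
    stop("unknown activation: ", kind))
}

nnActGrad <- function(kind, x, y) {
  switch(kind,
    linear = array(1, dim = dim(x) %||% length(x)),
    relu = (x > 0) * 1,
    silu = { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) },
    elu = ifelse(x > 0, 1, y + 1),
    leakyrelu = ifelse(x > 0, 1, 0.2),
    stop("unknown activation: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementary layers --------------------------------------------------

ndDense <- function(nin, nout) {
  list(type = "dense",
       par = list(W = nnGlorot(nin, nout), b = numeric(nout)),
       cfg = list(nin = nin, nout = nout))
}

ndAct <- function(kind) list(type = "act", cfg = list(kind = kind))

ndDropout <- function(rate) list(type = "dropout", cfg = list(rate = rate))

ndBatchNorm <- function(n, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm",
       par = list(gamma = rep(1, n), beta = numeric(n)),
       cfg = list(n = n, momentum = momentum, eps = eps),
       state = list(mean = numeric(n), var = rep(1, n)))
}

ndSeq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.null(layers[[1L]]$type)) layers <- layers[[1L]]
  list(type = "seq", layers = layers)
}

## ---- forward ------------------------------------------------------------

nnForward <- function(mod, x, training = FALSE) {
  switch(mod$type,
    dense = {
      out <- x %*% mod$par$W
      out <- sweep(out, 2L, mod$par$b, "+")
      list(out = out, cache = list(x = x), mod = mod)
    },
    act = {
      out <- nnActForward(mod$cfg$kind, x)
      list(out = out, cache = list(x = x, y = out), mod = mod)
    },
    dropout = {
      if (!training || mod$cfg$rate <= 0)
        return(list(out = x, cache = list(mask = NULL), mod = mod))
      keep <- 1 - mod$cfg$rate
      mask <- (stats::runif(length(x)) < keep) / keep
      dim(mask) <- dim(x)
      list(out = x * mask, cache = list(mask = mask), mod = mod)
    },
    batchnorm = {
      eps <- mod$cfg$eps
      if (training && nrow(x) > 1L) {
        mu <- colMeans(x)
        xc <- sweep(x, 2L, mu)
        v <- colMeans(xc^2)
        m <- mod$cfg$momentum
        mod$state$mean <- (1 - m) * mod$state$mean + m * mu
        mod$state$var <- (1 - m) * mod$state$var + m * v
      } else {
        mu <- mod$state$mean
        v <- mod$state$var
        xc <- sweep(x, 2L, mu)
      }
      inv <- 1 / sqrt(v + eps)
      xh <- sweep(xc, 2L, inv, "*")
      out <- sweep(sweep(xh, 2L, mod$par$gamma, "*"), 2L, mod$par$beta, "+")
      list(out = out,
           cache = list(xh = xh, inv = inv, batch = training && nrow(x) > 1L),
           mod = mod)
    },
    seq = {
      caches <- vector("list", length(mod$layers))
      for (i in seq_along(mod$layers)) {
        r <- nnForward(mod$layers[[i]], x, training)
        x <- r$out
        caches[[i]] <- r$cache
        mod$layers[[i]] <- r$mod
      }
      list(out = x, cache = caches, mod = mod)
    },
    conv3d = nnConvForward(mod, x),
    instnorm = nnInstNormForward(mod, x),
    maxpool3d = nnMaxPoolForward(mod, x),
    avgpool3d = nnAvgPoolForward(mod, x),
    globalavgpool = nnGlobalPoolForward(mod, x),
    flatten3d = {
      list(out = matrix(as.vector(x), 1L), cache = list(dims = dim(x)),
           mod = mod)
    },
    stop("unknown module type: ", mod$type))
}

## ---- backward -----------------------------------------------------------

nnBackward <- function(mod, cache, gout) {
  switch(mod$type,
    dense = {
      list(gpar = list(W = crossprod(cache$x, gout), b = colSums(gout)),
           gin = gout %*% t(mod$par$W))
    },
    act = {
      list(gpar = NULL, gin = gout * nnActGrad(mod$cfg$kind, cache$x, cache$y))
    },
    dropout = {
      if (is.null(cache$mask)) list(gpar = NULL, gin = gout)
      else list(gpar = NULL, gin = gout * cache$mask)
    },
    batchnorm = {
      xh <- cache$xh
      inv <- cache$inv
      ggamma <- colSums(gout * xh)
      gbeta <- colSums(gout)
      gxh <- sweep(gout, 2L, mod$par$gamma, "*")
      if (cache$batch) {
        n <- nrow(xh)
        gin <- sweep(gxh - matrix(gbetaRep <- colMeans(gxh), n, ncol(xh),
                                  byrow = TRUE) -
                     xh * matrix(colMeans(gxh * xh), n, ncol(xh), byrow = TRUE),
                     2L, inv, "*")
      } else {
        gin <- sweep(gxh, 2L, inv, "*")
      }
      list(gpar = list(gamma = ggamma, beta = gbeta), gin = gin)
    },
    seq = {
      glayers <- vector("list", length(mod$layers))
      for (i in rev(seq_along(mod$layers))) {
        r <- nnBackward(mod$layers[[i]], cache[[i]], gout)
        glayers[[i]] <- list(gpar = r$gpar, glayers = r$glayers)
        gout <- r$gin
      }
      list(gpar = NULL, gin = gout, glayers = glayers)
    },
    conv3d = nnConvBackward(mod, cache, gout),
    instnorm = nnInstNormBackward(mod, cache, gout),
    maxpool3d = nnMaxPoolBackward(mod, cache, gout),
    avgpool3d = nnAvgPoolBackward(mod, cache, gout),
    globalavgpool = nnGlobalPoolBackward(mod, cache, gout),
    flatten3d = {
      gin <- array(as.vector(gout), cache$dims)
      list(gpar = NULL, gin = gin)
    },
    stop("unknown module type: ", mod$type))
}

## ---- parameter-tree utilities ------------------------------------------

nnMapParams <- function(mod, fn, path = "") {
  out <- list()
  if (!is.null(mod$par))
    for (nm in names(mod$par))
      out[[paste0(path, "/", nm)]] <- fn(mod$par[[nm]])
  for (ch in c("layers")) {
    if (!is.null(mod[[ch]]))
      for (i in seq_along(mod[[ch]]))
        out <- c(out, nnMapParams(mod[[ch]][[i]], fn,
                                  paste0(path, "/", ch, i)))
  }
  out
}

nnParamCount <- function(mod)
  sum(vapply(nnMapParams(mod, length), identity, numeric(1)))

nnFlattenParams <- function(mod)
  unlist(nnMapParams(mod, as.vector), use.names = FALSE)

nnSetFlatParams <- function(mod, theta) {
  pos <- 0L
  set <- function(m) {
    if (!is.null(m$par))
      for (nm in names(m$par)) {
        k <- length(m$par[[nm]])
        v <- theta[(pos + 1L):(pos + k)]
        pos <<- pos + k
        dim(v) <- dim(m$par[[nm]])
        m$par[[nm]] <- v
      }
    if (!is.null(m$layers))
      for (i in seq_along(m$layers)) m$layers[[i]] <- set(m$layers[[i]])
    m
  }
  set(mod)
}

nnFlattenGrads <- function(mod, grad) {
  out <- c()
  if (!is.null(mod$par))
    for (nm in names(mod$par)) {
      g <- grad$gpar[[nm]]
      out <- c(out, if (is.null(g)) numeric(length(mod$par[[nm]]))
               else as.vector(g))
    }
  if (!is.null(mod$layers))
    for (i in seq_along(mod$layers))
      out <- c(out, nnFlattenGrads(mod$layers[[i]], grad$glayers[[i]]))
  out
}

## ---- Adam ---------------------------------------------------------------

adamInit <- function(mod) {
  n <- nnParamCount(mod)
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adamStep <- function(mod, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  g <- nnFlattenGrads(mod, grad)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- nnFlattenParams(mod) - lr * mhat / (sqrt(vhat) + eps)
  list(mod = nnSetFlatParams(mod, theta), state = state)
}
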