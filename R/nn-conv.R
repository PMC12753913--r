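# 3D convolution / pooling / instance-norm layers (per-sample arrays,
# dim = c(d1, d2, d3, channels)). Convolution is realized as an im2col
# gather followed by one matrix product, which makes the backward pass a
# matrix product plus a scatter-add.

ndConv3d <- function(cin, cout, k = 3L) {
  stopifnot(k %in% c(1L, 3L))
  fan <- k^3 * cin
  list(type = "conv3d",
       par = list(W = nnGlorot(fan, cout), b = numeric(cout)),
       cfg = list(cin = cin, cout = cout, k = k, pad = (k - 1L) %/% 2L))
}

ndInstNorm <- function(n, eps = 1e-5) {
  list(type = "instnorm",
       par = list(gamma = rep(1, n), beta = numeric(n)),
       cfg = list(n = n, eps = eps))
}

ndMaxPool3d <- function() list(type = "maxpool3d", cfg = list())
ndAvgPool3d <- function() list(type = "avgpool3d", cfg = list())
ndGlobalAvgPool <- function() list(type = "globalavgpool", cfg = list())
ndFlatten3d <- function() list(type = "flatten3d", cfg = list())

# im2col index matrix: rows = output voxels, cols = k^3 * C positions into
# the zero-padded input. Cached per (dims, k, C) in a package-local env.
.ndIdxCache <- new.env(parent = emptyenv())

nnConvIdx <- function(d, k, C) {
  key <- paste(c(d, k, C), collapse = "_")
  hit <- .ndIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  D <- d + 2L * p
  vox <- as.matrix(expand.grid(i = seq_len(d[1L]), j = seq_len(d[2L]),
                               l = seq_len(d[3L])))
  off <- as.matrix(expand.grid(a = 0:(k - 1L), b = 0:(k - 1L),
                               c = 0:(k - 1L)))
  I1 <- outer(vox[, 1L] - 1L, off[, 1L], "+")
  I2 <- outer(vox[, 2L] - 1L, off[, 2L], "+")
  I3 <- outer(vox[, 3L] - 1L, off[, 3L], "+")
  lin <- 1L + I1 + I2 * D[1L] + I3 * (D[1L] * D[2L])
  chOff <- (seq_len(C) - 1L) * prod(D)
  idx <- matrix(0L, nrow(lin), ncol(lin) * C)
  for (ch in seq_len(C))
    idx[, ((ch - 1L) * ncol(lin) + 1L):(ch * ncol(lin))] <- lin + chOff[ch]
  out <- list(idx = idx, D = D, p = p)
  .ndIdxCache[[key]] <- out
  out
}

nnPad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]),
     (p + 1L):(p + d[3L]), ] <- x
  xp
}

nnConvForward <- function(mod, x) {
  d <- dim(x)[1:3]
  C <- dim(x)[4L]
  stopifnot(C == mod$cfg$cin)
  ii <- nnConvIdx(d, mod$cfg$k, C)
  xp <- nnPad(x, ii$p)
  patches <- matrix(xp[as.vector(ii$idx)], nrow(ii$idx), ncol(ii$idx))
  om <- patches %*% mod$par$W
  om <- sweep(om, 2L, mod$par$b, "+")
  out <- array(om, c(d, mod$cfg$cout))
  list(out = out, cache = list(patches = patches, d = d, C = C), mod = mod)
}

nnConvBackward <- function(mod, cache, gout) {
  d <- cache$d
  C <- cache$C
  ii <- nnConvIdx(d, mod$cfg$k, C)
  gm <- matrix(as.vector(gout), prod(d), mod$cfg$cout)
  gW <- crossprod(cache$patches, gm)
  gb <- colSums(gm)
  gpatch <- gm %*% t(mod$par$W)
  lenp <- prod(ii$D) * C
  agg <- rowsum(as.vector(gpatch), group = as.vector(ii$idx))
  gflat <- numeric(lenp)
  gflat[as.integer(rownames(agg))] <- agg
  gxp <- array(gflat, c(ii$D, C))
  p <- ii$p
  gin <- if (p == 0L) gxp else
    gxp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]),
        (p + 1L):(p + d[3L]), , drop = FALSE]
  list(gpar = list(W = gW, b = gb), gin = gin)
}

## instance norm: normalize each channel over its voxels (single sample)

nnInstNormForward <- function(mod, x) {
  d <- dim(x)
  xm <- matrix(as.vector(x), prod(d[1:3]), d[4L])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + mod$cfg$eps)
  xh <- sweep(xc, 2L, inv, "*")
  om <- sweep(sweep(xh, 2L, mod$par$gamma, "*"), 2L, mod$par$beta, "+")
  list(out = array(om, d), cache = list(xh = xh, inv = inv, d = d), mod = mod)
}

nnInstNormBackward <- function(mod, cache, gout) {
  d <- cache$d
  gm <- matrix(as.vector(gout), prod(d[1:3]), d[4L])
  xh <- cache$xh
  ggamma <- colSums(gm * xh)
  gbeta <- colSums(gm)
  gxh <- sweep(gm, 2L, mod$par$gamma, "*")
  n <- nrow(xh)
  gin <- sweep(gxh -
               matrix(colMeans(gxh), n, ncol(xh), byrow = TRUE) -
               xh * matrix(colMeans(gxh * xh), n, ncol(xh), byrow = TRUE),
               2L, cache$inv, "*")
  list(gpar = list(gamma = ggamma, beta = gbeta), gin = array(gin, d))
}

## 2x pooling ---------------------------------------------------------------

nnPoolIdx <- function(d, C) {
  key <- paste(c("pool", d, C), collapse = "_")
  hit <- .ndIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  do <- d %/% 2L
  vox <- as.matrix(expand.grid(i = seq_len(do[1L]), j = seq_len(do[2L]),
                               l = seq_len(do[3L])))
  off <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  I1 <- outer(2L * (vox[, 1L] - 1L), off[, 1L], "+")
  I2 <- outer(2L * (vox[, 2L] - 1L), off[, 2L], "+")
  I3 <- outer(2L * (vox[, 3L] - 1L), off[, 3L], "+")
  lin <- 1L + I1 + I2 * d[1L] + I3 * (d[1L] * d[2L])
  chOff <- (seq_len(C) - 1L) * prod(d)
  out <- list(lin = lin, chOff = chOff, do = do)
  .ndIdxCache[[key]] <- out
  out
}

nnMaxPoolForward <- function(mod, x) {
  d <- dim(x)[1:3]
  C <- dim(x)[4L]
  ii <- nnPoolIdx(d, C)
  nout <- prod(ii$do)
  om <- matrix(0, nout, C)
  arg <- matrix(0L, nout, C)
  xv <- as.vector(x)
  for (ch in seq_len(C)) {
    pr <- matrix(xv[ii$lin + ii$chOff[ch]], nout, 8L)
    a <- max.col(pr, ties.method = "first")
    arg[, ch] <- ii$lin[cbind(seq_len(nout), a)] + ii$chOff[ch]
    om[, ch] <- pr[cbind(seq_len(nout), a)]
  }
  list(out = array(om, c(ii$do, C)),
       cache = list(arg = arg, dIn = c(d, C)), mod = mod)
}

nnMaxPoolBackward <- function(mod, cache, gout) {
  gin <- numeric(prod(cache$dIn))
  gin[as.vector(cache$arg)] <- as.vector(gout)
  list(gpar = NULL, gin = array(gin, cache$dIn))
}

nnAvgPoolForward <- function(mod, x) {
  d <- dim(x)[1:3]
  C <- dim(x)[4L]
  ii <- nnPoolIdx(d, C)
  nout <- prod(ii$do)
  om <- matrix(0, nout, C)
  xv <- as.vector(x)
  for (ch in seq_len(C))
    om[, ch] <- rowMeans(matrix(xv[ii$lin + ii$chOff[ch]], nout, 8L))
  list(out = array(om, c(ii$do, C)),
       cache = list(dIn = c(d, C), d = d, C = C), mod = mod)
}

nnAvgPoolBackward <- function(mod, cache, gout) {
  d <- cache$d
  C <- cache$C
  ii <- nnPoolIdx(d, C)
  gin <- numeric(prod(cache$dIn))
  gv <- as.vector(gout) / 8
  nout <- prod(ii$do)
  for (ch in seq_len(C)) {
    gch <- gv[((ch - 1L) * nout + 1L):(ch * nout)]
    for (o in 1:8) {
      tgt <- ii$lin[, o] + ii$chOff[ch]
      gin[tgt] <- gin[tgt] + gch
    }
  }
  list(gpar = NULL, gin = array(gin, cache$dIn))
}

nnGlobalPoolForward <- function(mod, x) {
  d <- dim(x)
  xm <- matrix(as.vector(x), prod(d[1:3]), d[4L])
  list(out = matrix(colMeans(xm), 1L), cache = list(d = d), mod = mod)
}

nnGlobalPoolBackward <- function(mod, cache, gout) {
  d <- cache$d
  nv <- prod(d[1:3])
  gin <- array(rep(as.vector(gout) / nv, each = nv), d)
  list(gpar = NULL, gin = gin)
}
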