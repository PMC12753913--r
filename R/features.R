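# The three mapping functions from template-space volumes to model inputs:
# tabular ROI aggregation (2 statistics per ROI), normalized/downsampled
# volumes for the 3D CNNs, and atlas brain graphs with per-ROI node
# features for the GNNs.

#' ROI-aggregated tabular features
#'
#' Aggregates template-space volumes into one feature per (ROI, statistic)
#' pair, in the fixed atlas ROI order. For MRI the statistics are the GM
#' and WM volumes per ROI (sum of tissue probability times voxel volume,
#' mm^3); for PET (FDG/AV45) the mean and standard deviation of the SUVR
#' values per ROI (population denominator). With a 116-ROI atlas the
#' output has length 232.
#'
#' @param volumes for \code{modality = "mri"} a list with elements
#'   \code{gm} and \code{wm}; for PET a single 3D array.
#' @param atlas an \code{\link{AtlasVolume-class}} on the same grid.
#' @param modality \code{"mri"}, \code{"fdg"} or \code{"av45"}.
#' @return named numeric vector of length 2R (interleaved
#'   roi1_stat1, roi1_stat2, roi2_stat1, ...), with the modality recorded
#'   as an attribute.
#' @export
phiTabular <- function(volumes, atlas, modality = c("mri", "fdg", "av45")) {
  modality <- match.arg(modality)
  lab <- atlas@labels
  ids <- atlas@roiIds
  checkGrid <- function(v) {
    if (!identical(dim(v), dim(lab)))
      stop("volume grid ", paste(dim(v), collapse = "x"),
           " does not match atlas grid ", paste(dim(lab), collapse = "x"))
  }
  inMask <- lab != 0L
  labf <- factor(lab[inMask], levels = ids)
  if (modality == "mri") {
    checkGrid(volumes$gm); checkGrid(volumes$wm)
    vv <- prod(atlas@voxelSize)
    gmv <- as.vector(tapply(volumes$gm[inMask], labf, sum)) * vv
    wmv <- as.vector(tapply(volumes$wm[inMask], labf, sum)) * vv
    out <- as.vector(rbind(gmv, wmv))
    names(out) <- paste0("roi", rep(ids, each = 2L), "_", c("gm", "wm"))
  } else {
    v <- if (is.list(volumes)) volumes[[modality]] else volumes
    checkGrid(v)
    x <- v[inMask]
    mu <- as.vector(tapply(x, labf, mean))
    sdp <- as.vector(tapply(x, labf, function(z)
      sqrt(mean((z - mean(z))^2))))
    out <- as.vector(rbind(mu, sdp))
    names(out) <- paste0("roi", rep(ids, each = 2L), "_", c("mean", "sd"))
  }
  attr(out, "modality") <- modality
  out
}

#' Normalized, downsampled volume input
#'
#' Prepares a volume for the 3D CNNs: MRI intensities are first divided by
#' the median value inside the WM region (so the normalized WM median is
#' 1), then every modality is downsampled by a factor of 2 per axis using
#' trilinear interpolation at the centers of 2x2x2 blocks (equivalently,
#' block means; constants are preserved exactly).
#'
#' @param volume 3D array.
#' @param modality \code{"mri"}, \code{"fdg"} or \code{"av45"}.
#' @param wmMask for MRI, a WM probability map (voxels with probability
#'   > 0.5 define the WM region) on the same grid.
#' @return list: \code{data} (downsampled array, each dim =
#'   floor(input/2)), \code{modality}, \code{normalization} record.
#' @export
phiVolume <- function(volume, modality = c("mri", "fdg", "av45"),
                      wmMask = NULL) {
  modality <- match.arg(modality)
  normRec <- list(kind = "none")
  if (modality == "mri") {
    if (is.null(wmMask)) stop("MRI normalization requires a WM mask")
    wmMed <- stats::median(volume[wmMask > 0.5])
    if (!is.finite(wmMed) || wmMed == 0)
      stop("WM median is zero; cannot normalize")
    volume <- volume / wmMed
    normRec <- list(kind = "wm-median-divisor", wmMedian = wmMed)
  }
  d <- dim(volume)
  do <- d %/% 2L
  v <- volume[seq_len(2L * do[1L]), seq_len(2L * do[2L]),
              seq_len(2L * do[3L]), drop = FALSE]
  # trilinear interpolation at block centers == mean over each 2x2x2 block
  out <- v[seq(1L, 2L * do[1L], 2L), , , drop = FALSE] +
         v[seq(2L, 2L * do[1L], 2L), , , drop = FALSE]
  out <- out[, seq(1L, 2L * do[2L], 2L), , drop = FALSE] +
         out[, seq(2L, 2L * do[2L], 2L), , drop = FALSE]
  out <- out[, , seq(1L, 2L * do[3L], 2L), drop = FALSE] +
         out[, , seq(2L, 2L * do[3L], 2L), drop = FALSE]
  list(data = out / 8, modality = modality, normalization = normRec,
       interpolation = "trilinear-block-centers")
}

#' Estimate the atlas connectivity graph by graphical lasso
#'
#' L1-penalized maximum-likelihood estimation of the inverse covariance
#' (precision) matrix of ROI-mean FDG SUVR values across subjects
#' (block coordinate descent; columns are standardized internally, the
#' penalty weight is \code{lambda}, and the diagonal is penalized as in
#' the classic algorithm). An undirected unweighted edge (i, j) is present
#' iff |precision_ij| exceeds the zero tolerance.
#'
#' @param roiMat subjects x R matrix of ROI-mean SUVR values.
#' @param lambda L1 penalty weight (the study explored 0.2, 0.3, 0.4).
#' @param zeroTol absolute precision threshold for edge detection.
#' @param maxIter,tol outer-loop controls.
#' @param provenance optional fitting-sample record.
#' @return a \code{\link{BrainGraph-class}} (edges only; attach node
#'   features with \code{\link{phiGraph}}).
#' @export
estimateConnectivityGraph <- function(roiMat, lambda = 0.3, zeroTol = 1e-8,
                                      maxIter = 100L, tol = 1e-5,
                                      provenance = list()) {
  roiMat <- as.matrix(roiMat)
  if (nrow(roiMat) < 10L)
    stop("need at least 10 subjects, got ", nrow(roiMat))
  z <- scale(roiMat)
  S <- stats::cov(z) * (nrow(z) - 1) / nrow(z)
  gl <- graphicalLasso(S, rho = lambda, maxIter = maxIter, tol = tol)
  Theta <- gl$Theta
  R <- ncol(S)
  adj <- abs(Theta) > zeroTol
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  e <- which(adj, arr.ind = TRUE)
  edges <- cbind(as.integer(e[, 1L]), as.integer(e[, 2L]))
  colnames(edges) <- c("i", "j")
  new("BrainGraph", roiIds = seq_len(R), edges = edges,
      nodeFeatures = matrix(0, 0, 0), lambda = lambda, precision = Theta,
      meta = list(zeroTol = zeroTol, iterations = gl$iterations,
                  converged = gl$converged, provenance = provenance))
}

#' Graphical lasso (block coordinate descent)
#'
#' Maximizes log det(Theta) - tr(S Theta) - rho * sum(|Theta|) by the
#' classic block coordinate descent over columns of W = Theta^-1 (each
#' column update is an L1-penalized regression solved by coordinate
#' descent). Returns the precision matrix, which is symmetric positive
#' definite by construction.
#'
#' @param S covariance (or correlation) matrix.
#' @param rho L1 penalty.
#' @param maxIter,tol outer-loop controls.
#' @param innerIter coordinate-descent sweeps per column.
#' @return list: Theta, W (estimated covariance), iterations, converged.
#' @export
graphicalLasso <- function(S, rho, maxIter = 100L, tol = 1e-5,
                           innerIter = 50L) {
  p <- ncol(S)
  if (p == 1L) return(list(Theta = matrix(1 / (S[1, 1] + rho)), W = S + rho,
                           iterations = 0L, converged = TRUE))
  W <- S + rho * diag(p)
  B <- matrix(0, p - 1L, p)   # lasso coefficients per column
  thresh <- tol * mean(abs(S[upper.tri(S)])) + 1e-12
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    Wold <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      beta <- B[, j]
      for (sw in seq_len(innerIter)) {
        bOld <- beta
        for (k in seq_len(p - 1L)) {
          r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          beta[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(beta - bOld)) < 1e-9) break
      }
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[-j, j] <- w12
      W[j, -j] <- w12
    }
    if (mean(abs(W - Wold)) < thresh) { converged <- TRUE; break }
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    theta22 <- 1 / (W[j, j] - sum(W[-j, j] * B[, j]))
    Theta[j, j] <- theta22
    Theta[-j, j] <- -B[, j] * theta22
  }
  Theta <- (Theta + t(Theta)) / 2
  if (!converged && it == maxIter)
    warning("graphical lasso: outer loop did not converge in ", maxIter,
            " iterations (lambda = ", rho, ")")
  list(Theta = Theta, W = W, iterations = it, converged = converged)
}

#' Attach per-ROI node features to a brain graph
#'
#' Node u's features are that ROI's tabular statistics: GM and WM volumes
#' for MRI, mean and standard deviation of SUVR for PET (d = 2 per
#' modality); supplying several modalities concatenates per node (d = 6
#' for all three).
#'
#' @param roiFeatures a single \code{\link{phiTabular}} vector or a list of
#'   them (one per modality).
#' @param graph a \code{\link{BrainGraph-class}}.
#' @return the graph with \code{nodeFeatures} set (R x d).
#' @export
phiGraph <- function(roiFeatures, graph) {
  if (!is.list(roiFeatures)) roiFeatures <- list(roiFeatures)
  R <- length(graph@roiIds)
  feats <- lapply(roiFeatures, function(v) {
    if (length(v) != 2L * R)
      stop("feature length ", length(v), " does not match 2 x ", R, " ROIs")
    matrix(v, nrow = R, ncol = 2L, byrow = TRUE)
  })
  X <- do.call(cbind, feats)
  rownames(X) <- paste0("roi", graph@roiIds)
  graph@nodeFeatures <- X
  validObject(graph)
  graph
}

#' Dense adjacency matrix of a brain graph
#'
#' @param graph a \code{BrainGraph}.
#' @return symmetric 0/1 matrix (no self loops).
#' @export
adjacencyMatrix <- function(graph) {
  R <- length(graph@roiIds)
  A <- matrix(0, R, R)
  e <- graph@edges
  if (nrow(e) > 0L) {
    A[e] <- 1
    A[e[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}
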