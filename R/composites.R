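# Cognitive composite construction: item imputation, one-factor measurement
# models per domain (latent factor variance fixed at 1), reference-anchored
# rescaling (0 = mild-dementia median, 100 = CN median), and normative
# age/education adjustment.

#' Impute missing neuropsychological item scores
#'
#' Two strategies, applied together: chained-equation imputation (iterative
#' regression sweeps over the incomplete columns, initialized at column
#' means) for ordinary low-missingness items, and a single random-forest
#' surrogate model for a designated high-missingness item, using the
#' remaining items plus age, sex and years of education as predictors.
#' Observed entries are never altered.
#'
#' @param batteryTable data.frame of item columns (may contain NA).
#' @param demographics data.frame with age, sex, education (same rows).
#' @param highMissingItem optional column name imputed with the surrogate
#'   random-forest model instead of chained equations.
#' @param maxMissing per-column missingness cap (precondition).
#' @param nSweeps chained-equation sweeps.
#' @param fitRows optional logical/integer subset of rows used to fit the
#'   imputation models (e.g. non-test subjects); predictions fill all rows.
#' @return completed data.frame (no NA remain).
#' @export
imputeItems <- function(batteryTable, demographics = NULL,
                        highMissingItem = NULL, maxMissing = 0.25,
                        nSweeps = 5L, fitRows = NULL) {
  x <- as.data.frame(batteryTable)
  items <- names(x)
  missFrac <- vapply(x, function(cc) mean(is.na(cc)), numeric(1))
  if (any(missFrac == 1))
    stop("column entirely missing: ",
         paste(items[missFrac == 1], collapse = ", "))
  capCols <- setdiff(items, highMissingItem)
  if (any(missFrac[capCols] > maxMissing))
    stop("missingness above cap in: ",
         paste(capCols[missFrac[capCols] > maxMissing], collapse = ", "))
  if (all(missFrac == 0)) return(x)
  obs <- !is.na(x)
  if (is.null(fitRows)) fitRows <- rep(TRUE, nrow(x))
  dem <- if (!is.null(demographics))
    as.data.frame(demographics)[, intersect(c("age", "sex", "education"),
                                            names(demographics)),
                                drop = FALSE]
  # initialize at observed column means
  for (cc in items) x[[cc]][is.na(x[[cc]])] <- mean(x[[cc]], na.rm = TRUE)
  chainCols <- setdiff(items[missFrac > 0], highMissingItem)
  for (sweep in seq_len(nSweeps)) {
    for (cc in chainCols) {
      preds <- setdiff(items, cc)
      df <- cbind(x[preds], dem)
      fit <- stats::lm(y ~ ., data = cbind(y = x[[cc]], df),
                       subset = fitRows & obs[, cc])
      hole <- !obs[, cc]
      x[[cc]][hole] <- stats::predict(fit, newdata = df[hole, , drop = FALSE])
    }
  }
  if (!is.null(highMissingItem) && missFrac[highMissingItem] > 0) {
    cc <- highMissingItem
    preds <- setdiff(items, cc)
    df <- cbind(x[preds], dem)
    rf <- randomForest::randomForest(
      x = df[fitRows & obs[, cc], , drop = FALSE],
      y = batteryTable[[cc]][fitRows & obs[, cc]], ntree = 200L)
    hole <- !obs[, cc]
    x[[cc]][hole] <- stats::predict(rf, newdata = df[hole, , drop = FALSE])
  }
  # observed cells are untouched by construction; assert the contract
  stopifnot(all(x[obs] == as.data.frame(batteryTable)[obs]))
  x
}

# item pre-transformation shared by fitting and scoring: log-transform
# timed items (completion times in seconds, natural log), apply direction
# so that higher always means better cognition.
transformItems <- function(tbl, spec) {
  m <- as.matrix(tbl[, spec$items, drop = FALSE])
  for (ii in seq_along(spec$items)) {
    if (spec$timed[ii]) m[, ii] <- log(m[, ii])
    m[, ii] <- spec$direction[ii] * m[, ii]
  }
  m
}

#' Fit a one-factor measurement model for a cognitive domain
#'
#' Maximum-likelihood single-factor model on standardized indicators with
#' the latent factor variance fixed at 1 for identification. Loadings are
#' sign-aligned so that a higher composite means better cognition. Domains
#' with two items use the closed-form equal-loading solution
#' (loading = sqrt(r)); single-item domains have loading 1 and the
#' composite is the standardized item.
#'
#' @param completedTable imputed visit table (no NA in the domain's items).
#' @param domainSpec one entry of \code{\link{defaultBatterySpec}} plus a
#'   \code{domain} name, i.e. \code{list(domain=, items=, ordinal=, timed=,
#'   direction=)}.
#' @param provenance optional list recording the fitting sample (subject
#'   ids, split) for leakage auditing.
#' @return a \code{\link{MeasurementModel-class}}.
#' @export
fitCompositeModel <- function(completedTable, domainSpec,
                              provenance = list()) {
  spec <- domainSpec
  if (!all(spec$items %in% names(completedTable)))
    stop("missing item columns: ",
         paste(setdiff(spec$items, names(completedTable)), collapse = ", "))
  m <- transformItems(completedTable, spec)
  if (anyNA(m)) stop("items must be imputed before model fitting")
  p <- ncol(m)
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  if (any(scl == 0)) stop("zero-variance item in domain ", spec$domain)
  z <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  if (p == 1L) {
    lo <- 1
    un <- 0.005
    est <- "single-item"
  } else if (p == 2L) {
    r <- stats::cor(z)[1L, 2L]
    lo <- rep(sqrt(max(r, 0.01)), 2L)
    un <- pmax(1 - lo^2, 0.005)
    est <- "two-item-sqrt-r"
  } else {
    if (nrow(z) < 10L * p)
      stop("need at least ", 10L * p, " rows to fit a ", p, "-item model")
    R <- stats::cov(z)
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      # (near-)noiseless indicators: the correlation matrix is singular and
      # the ML factor model is degenerate; the first principal component is
      # the exact factor solution (loading_i = sqrt(ev1) * |v1_i|)
      lo <- sqrt(ev$values[1L]) * ev$vectors[, 1L]
      if (sum(lo) < 0) lo <- -lo
      un <- pmax(1 - lo^2, 0.005)
      est <- "pc-degenerate"
    } else {
      fa <- tryCatch(stats::factanal(covmat = R, factors = 1L,
                                     n.obs = nrow(z)),
                     error = function(e)
                       stop("one-factor model did not converge for domain ",
                            spec$domain, ": ", conditionMessage(e)))
      lo <- as.vector(fa$loadings)
      un <- fa$uniquenesses
      est <- "ml-onefactor"
    }
  }
  if (sum(lo) < 0) lo <- -lo   # joint sign flip: higher composite = better
  new("MeasurementModel", domain = spec$domain, itemNames = spec$items,
      loadings = as.numeric(lo), uniquenesses = as.numeric(un),
      ordinalFlags = spec$ordinal, timedFlags = spec$timed,
      directions = spec$direction, itemCenter = ctr, itemScale = scl,
      estimator = est, factorVariance = 1, provenance = provenance)
}

#' Score per-visit cognitive composites
#'
#' Bartlett factor scores from the fitted one-factor model: deterministic
#' given the model, invariant to item column order, and exact (correlation
#' 1 with the generating factor) when the indicators are noiseless.
#'
#' @param model a \code{\link{MeasurementModel-class}}.
#' @param completedTable imputed table containing the model's items.
#' @return numeric vector, one composite score per row.
#' @export
scoreComposites <- function(model, completedTable) {
  spec <- list(items = model@itemNames, timed = model@timedFlags,
               direction = model@directions, domain = model@domain)
  if (!all(spec$items %in% names(completedTable)))
    stop("unknown or missing item column: ",
         paste(setdiff(spec$items, names(completedTable)), collapse = ", "))
  m <- transformItems(completedTable, spec)
  if (anyNA(m)) stop("items must be imputed before scoring")
  z <- sweep(sweep(m, 2L, model@itemCenter), 2L, model@itemScale, "/")
  lo <- model@loadings
  psi <- pmax(model@uniquenesses, 0.005)
  w <- (lo / psi) / sum(lo^2 / psi)
  as.vector(z %*% w)
}

#' Reference medians for composite rescaling
#'
#' @param p50dem median composite of the mild-dementia reference group.
#' @param p50cn median composite of the cognitively normal reference group.
#' @return a \code{ScalerParams} list.
#' @export
scalerParams <- function(p50dem, p50cn) {
  if (!is.finite(p50dem) || !is.finite(p50cn) || p50cn == p50dem)
    stop("degenerate reference: P50cn must differ from P50dem")
  structure(list(p50dem = p50dem, p50cn = p50cn), class = "ScalerParams")
}

#' Rescale a raw composite to the 0/100 reference scale
#'
#' Affine rescaling anchored at the two reference medians: a score of 0
#' corresponds to the median of mild-dementia subjects and a score of 100
#' to the median of cognitively normal subjects,
#' \deqn{x_{adj} = \frac{x - P50_{dem}}{P50_{cn} - P50_{dem}} \cdot 100.}
#'
#' @param x raw composite score(s).
#' @param params a \code{\link{scalerParams}}.
#' @return adjusted score(s) on the 0-100 anchored scale.
#' @export
scaleComposite <- function(x, params) {
  stopifnot(inherits(params, "ScalerParams"))
  (x - params$p50dem) / (params$p50cn - params$p50dem) * 100
}

#' Fit the normative age/education model
#'
#' Linear regression of composite scores on age and years of education,
#' fitted only on normative subjects (cognitively normal at every visit
#' with sustained amyloid-negative status).
#'
#' @param scores composite scores of normative visits.
#' @param age,education covariates (same length).
#' @param provenance optional fitting-sample record.
#' @return a \code{NormativeModel} list: coefficients, covariate means,
#'   residual sd, n.
#' @export
fitNormativeModel <- function(scores, age, education, provenance = list()) {
  if (length(scores) == 0L) stop("empty normative subset")
  if (length(scores) < 20L)
    stop("normative model requires at least 20 subjects, got ",
         length(scores))
  df <- data.frame(y = scores, age = age, education = education)
  fit <- stats::lm(y ~ age + education, data = df)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  structure(list(coef = cf, ageMean = mean(age), eduMean = mean(education),
                 residSd = stats::sd(stats::resid(fit)), n = length(scores),
                 provenance = provenance),
            class = "NormativeModel")
}

#' Adjust composite scores for age and education
#'
#' Residualizes scores against the normative expectation: the adjusted
#' score is the deviation (in composite points) from what the normative
#' model predicts for a subject of that age and education. Within a
#' normative sample the adjusted scores are centered near zero and
#' uncorrelated with age and education.
#'
#' @param model a \code{\link{fitNormativeModel}}.
#' @param scores,age,education scores and covariates to adjust.
#' @return adjusted scores.
#' @export
normativeAdjust <- function(model, scores, age, education) {
  stopifnot(inherits(model, "NormativeModel"))
  pred <- model$coef[["(Intercept)"]] + model$coef[["age"]] * age +
    model$coef[["education"]] * education
  scores - pred
}
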