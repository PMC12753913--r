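# Prediction-target construction: per-domain decline slopes (OLS over
# visits measured from the neuroimaging acquisition), normative
# 5th-percentile decliner thresholds, binary decline labels, horizon
# diagnosis labels, and winsorized z-scoring of regression targets with
# train-only statistics.

#' Per-domain cognitive decline slope
#'
#' Ordinary-least-squares slope of the composite score against years since
#' the neuroimaging acquisition (t0), using every visit at or after t0.
#' With fewer than two usable visits the slope is missing (NA with
#' n_points recorded), not an error, so the target mask can be set.
#'
#' @param dates visit dates in days from baseline.
#' @param scores composite scores at those visits.
#' @param t0 date (days) of the neuroimaging acquisition used as model
#'   input.
#' @return list: slope (composite points/year, NA if undetermined),
#'   nPoints, t0.
#' @export
computeDeclineSlope <- function(dates, scores, t0 = 0) {
  keep <- !is.na(scores) & dates >= t0
  t <- (dates[keep] - t0) / 365.25
  x <- scores[keep]
  ok <- length(unique(t)) >= 2L
  slope <- if (!ok) NA_real_ else {
    tc <- t - mean(t)
    sum(tc * (x - mean(x))) / sum(tc^2)
  }
  list(slope = slope, nPoints = sum(keep), t0 = t0)
}

#' Normative decline thresholds
#'
#' Empirical 5th percentile of the per-domain decline slopes in the
#' normative sample (linear interpolation between order statistics,
#' quantile type 7; the convention is recorded in the result so tests can
#' pin it against a sort-based oracle).
#'
#' @param normativeSlopes named list (or data.frame) of numeric slope
#'   vectors, one per domain.
#' @param probs percentile (default 0.05).
#' @return a \code{DeclineThresholds} list: per-domain cutoff, normative n,
#'   percentile convention.
#' @export
deriveDeclineThreshold <- function(normativeSlopes, probs = 0.05) {
  if (is.data.frame(normativeSlopes)) normativeSlopes <- as.list(normativeSlopes)
  if (length(normativeSlopes) == 0L ||
      any(vapply(normativeSlopes, length, integer(1)) == 0L))
    stop("empty normative slope set")
  cuts <- vapply(normativeSlopes, function(s)
    stats::quantile(s[!is.na(s)], probs = probs, type = 7L, names = FALSE),
    numeric(1))
  structure(list(cutoffs = cuts,
                 normativeN = vapply(normativeSlopes,
                                     function(s) sum(!is.na(s)), integer(1)),
                 prob = probs, convention = "type7-linear-interpolation"),
            class = "DeclineThresholds")
}

#' Binary decline label
#'
#' A subject is a decliner if their rate of decline falls strictly below
#' the normative threshold (i.e. below that of 95 percent of control
#' subjects); equality is classified stable.
#'
#' @param slope decline slope (composite points/year).
#' @param threshold per-domain cutoff (scalar, or a
#'   \code{DeclineThresholds} plus \code{domain}).
#' @param domain domain name when \code{threshold} is a
#'   \code{DeclineThresholds}.
#' @return factor with levels stable/decliner (NA propagates).
#' @export
labelDecline <- function(slope, threshold, domain = NULL) {
  if (inherits(threshold, "DeclineThresholds")) {
    stopifnot(!is.null(domain))
    threshold <- threshold$cutoffs[[domain]]
  }
  factor(ifelse(is.na(slope), NA, ifelse(slope < threshold,
                                         "decliner", "stable")),
         levels = c("stable", "decliner"))
}

#' Diagnosis labels at fixed horizons
#'
#' For each horizon, the diagnosis at the visit nearest to t0 + horizon
#' within a +/- 6-month window; if no visit falls inside the window the
#' label is missing (masked), and ties between equidistant visits go to the
#' earlier visit.
#'
#' @param dates visit dates (days from baseline).
#' @param diagnoses diagnosis labels at those visits (may contain NA).
#' @param t0 neuroimaging acquisition date (days).
#' @param horizonsYears prediction horizons (default 2 and 4 years).
#' @param windowDays half-width of the matching window (default 182.625
#'   days, i.e. 6 months).
#' @return named character vector of labels (NA = missing).
#' @export
buildDiagnosisTargets <- function(dates, diagnoses, t0 = 0,
                                  horizonsYears = c(2, 4),
                                  windowDays = 182.625) {
  out <- stats::setNames(rep(NA_character_, length(horizonsYears)),
                         paste0("dx_", horizonsYears, "y"))
  ok <- !is.na(diagnoses)
  for (i in seq_along(horizonsYears)) {
    target <- t0 + horizonsYears[i] * 365.25
    d <- abs(dates[ok] - target)
    if (!any(d <= windowDays)) next
    cand <- which(d <= windowDays)
    # nearest visit; equidistant ties resolved to the earlier visit
    best <- cand[order(d[cand], dates[ok][cand])][1L]
    out[i] <- diagnoses[ok][best]
  }
  out
}

#' Winsorized z-scoring of regression targets
#'
#' Trims outliers by clipping at the training sample's 5th and 95th
#' percentiles, then standardizes with the post-trim training mean and
#' standard deviation. The returned parameters are reusable on validation
#' and test values, which are never standardized with their own statistics.
#'
#' @param train training-split target values (NA allowed, ignored in the
#'   parameter fit).
#' @param applyTo values to transform (default the training values).
#' @param params optionally, previously computed parameters (train is then
#'   ignored).
#' @param trimProbs trimming percentiles.
#' @return list: z (transformed applyTo), params
#'   (\code{StandardizationParams}: trim bounds, train mean, train sd).
#' @export
standardizeRegressionTargets <- function(train, applyTo = train,
                                         params = NULL,
                                         trimProbs = c(0.05, 0.95)) {
  if (is.null(params)) {
    tv <- train[!is.na(train)]
    if (length(tv) < 20L)
      stop("need at least 20 training values, got ", length(tv))
    bounds <- stats::quantile(tv, probs = trimProbs, type = 7L,
                              names = FALSE)
    tw <- pmin(pmax(tv, bounds[1L]), bounds[2L])
    mu <- mean(tw)
    sdv <- stats::sd(tw)
    if (sdv == 0) stop("zero variance after trimming")
    params <- structure(list(lower = bounds[1L], upper = bounds[2L],
                             mean = mu, sd = sdv, trimProbs = trimProbs),
                        class = "StandardizationParams")
  }
  w <- pmin(pmax(applyTo, params$lower), params$upper)
  list(z = (w - params$mean) / params$sd, params = params)
}

#' Assemble the multitask target table for a cohort
#'
#' Computes, for every subject: the current diagnosis, the diagnosis at 2
#' and 4 years (6-month matching window), and the four per-domain decline
#' slopes from adjusted composite trajectories (OLS from the neuroimaging
#' acquisition). Slopes are z-scored with winsorized train-only statistics.
#' Masks flag entries whose ground truth is unavailable.
#'
#' @param scored data.frame with columns subject_id, date_days, diagnosis,
#'   and one adjusted-composite column per domain (named
#'   \code{composite_<domain>}).
#' @param subjectIds subjects to include, in output order.
#' @param trainIds subjects whose values define the standardization
#'   parameters.
#' @param domains cognitive domains.
#' @param t0 named numeric of acquisition dates per subject (default 0).
#' @return list: targets (named list per task), masks, rawSlopes,
#'   standardization params per domain.
#' @export
buildTargetTable <- function(scored, subjectIds, trainIds,
                             domains = c("memory", "language",
                                         "visuospatial", "executive"),
                             t0 = NULL) {
  n <- length(subjectIds)
  cls <- c("CN", "MCI", "dementia")
  targets <- list(
    dx_now = integer(n), dx_2y = integer(n), dx_4y = integer(n))
  masks <- list(dx_now = logical(n), dx_2y = logical(n), dx_4y = logical(n))
  rawSlopes <- matrix(NA_real_, n, length(domains),
                      dimnames = list(subjectIds, domains))
  for (s in seq_len(n)) {
    rows <- scored[scored$subject_id == subjectIds[s], ]
    rows <- rows[order(rows$date_days), ]
    tt0 <- if (is.null(t0)) 0 else t0[[subjectIds[s]]]
    base <- rows$diagnosis[which.min(abs(rows$date_days - tt0))]
    targets$dx_now[s] <- match(base, cls)
    masks$dx_now[s] <- !is.na(targets$dx_now[s])
    hz <- buildDiagnosisTargets(rows$date_days, rows$diagnosis, t0 = tt0)
    targets$dx_2y[s] <- match(hz[["dx_2y"]], cls)
    masks$dx_2y[s] <- !is.na(targets$dx_2y[s])
    targets$dx_4y[s] <- match(hz[["dx_4y"]], cls)
    masks$dx_4y[s] <- !is.na(targets$dx_4y[s])
    for (dm in domains) {
      sl <- computeDeclineSlope(rows$date_days,
                                rows[[paste0("composite_", dm)]], t0 = tt0)
      rawSlopes[s, dm] <- sl$slope
    }
  }
  stdParams <- list()
  isTrain <- subjectIds %in% trainIds
  for (dm in domains) {
    tk <- paste0("slope_", dm)
    std <- standardizeRegressionTargets(rawSlopes[isTrain, dm],
                                        applyTo = rawSlopes[, dm])
    targets[[tk]] <- std$z
    masks[[tk]] <- !is.na(rawSlopes[, dm])
    stdParams[[dm]] <- std$params
  }
  list(targets = targets, masks = masks, rawSlopes = rawSlopes,
       stdParams = stdParams)
}
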