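# Synthetic ADNI-like cohort generator. Produces, at desk scale, data with
# the statistical structure the modeling framework assumes: a Voronoi
# parcellation atlas, per-modality template-space volumes whose regional
# values shift with a planted severity variable, longitudinal item
# batteries driven by one latent factor per cognitive domain with planted
# per-subject slopes, a monotone diagnosis path, and configurable
# missingness (incomplete PET modalities, variable follow-up).

#' Generate a synthetic ROI label atlas
#'
#' Builds a brain-like ellipsoidal mask and partitions it into \code{nRois}
#' contiguous regions by nearest-seed-point (Voronoi) assignment from
#' seeded random centers. Deterministic given the seed; every ROI id occurs
#' at least once.
#'
#' @param nRois number of regions (default 116, the AAL atlas node count).
#' @param shape 3D array dimensions (default 32^3, the desk-scale volume).
#' @param seed integer seed.
#' @param voxelSize mm per axis.
#' @return an \code{\link{AtlasVolume-class}} object.
#' @export
makeAtlas <- function(nRois = 116L, shape = c(32L, 32L, 32L), seed = 1L,
                      voxelSize = c(1, 1, 1)) {
  stopifnot(nRois >= 1L, length(shape) == 3L)
  set.seed(as.integer(seed))
  ctr <- shape / 2 + 0.5
  rad <- shape * 0.42
  g <- as.matrix(expand.grid(i = seq_len(shape[1L]), j = seq_len(shape[2L]),
                             k = seq_len(shape[3L])))
  inMask <- ((g[, 1L] - ctr[1L]) / rad[1L])^2 +
            ((g[, 2L] - ctr[2L]) / rad[2L])^2 +
            ((g[, 3L] - ctr[3L]) / rad[3L])^2 <= 1
  nm <- sum(inMask)
  if (nm < nRois)
    stop("shape ", paste(shape, collapse = "x"), " has only ", nm,
         " in-mask voxels for ", nRois, " ROIs")
  maskVox <- g[inMask, , drop = FALSE]
  seedIdx <- sample.int(nm, nRois)
  centers <- maskVox[seedIdx, , drop = FALSE]
  # nearest seed point, ties broken by lowest ROI id (max.col on -dist,
  # ties.method = "first")
  d2 <- outer(maskVox[, 1L], centers[, 1L], "-")^2 +
        outer(maskVox[, 2L], centers[, 2L], "-")^2 +
        outer(maskVox[, 3L], centers[, 3L], "-")^2
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, shape)
  labels[inMask] <- lab
  new("AtlasVolume", labels = labels, voxelSize = voxelSize,
      roiIds = seq_len(nRois))
}

#' Planted ground truth for one synthetic subject
#'
#' Draws the latent disease severity's consequences: per-domain decline
#' slopes (composite points/year, mean shifted downward as severity grows),
#' amyloid status, and a monotone non-improving CN/MCI/dementia diagnosis
#' path over follow-up time.
#'
#' @param severity disease severity in [0, 1].
#' @param seed integer seed.
#' @param amyloidPositive logical; if NULL, drawn with probability
#'   increasing in severity.
#' @param slopeBase,slopeSevScale,slopeSd slope model: slopes are drawn from
#'   N(slopeBase - slopeSevScale * severity, slopeSd) per domain.
#' @param progressionRate relative severity growth per year (drives the
#'   diagnosis path).
#' @return list with severity, domainSlopes (named, 4 domains),
#'   amyloidPositive, and diagnosisAt(tYears) giving the path.
#' @export
makeSubjectTruth <- function(severity, seed = 1L, amyloidPositive = NULL,
                             slopeBase = -0.3, slopeSevScale = 6,
                             slopeSd = 0.8, progressionRate = 0.05) {
  stopifnot(severity >= 0, severity <= 1)
  set.seed(as.integer(seed))
  domains <- c("memory", "language", "visuospatial", "executive")
  slopes <- stats::rnorm(4L, mean = slopeBase - slopeSevScale * severity,
                         sd = slopeSd)
  names(slopes) <- domains
  if (is.null(amyloidPositive))
    amyloidPositive <- stats::runif(1) < stats::plogis(8 * (severity - 0.3))
  list(severity = severity, domainSlopes = slopes,
       amyloidPositive = amyloidPositive,
       progressionRate = progressionRate)
}

# diagnosis stage at a set of follow-up times; monotone non-improving
truthDiagnosisAt <- function(truth, tYears) {
  sev <- pmin(1, truth$severity * (1 + truth$progressionRate * tYears))
  stage <- findInterval(sev, c(0.35, 0.7)) + 1L
  stage <- cummax(stage)
  c("CN", "MCI", "dementia")[stage]
}

#' Generate per-modality volumes for one subject
#'
#' Produces GM/WM tissue-probability maps and FDG/AV45 SUVR maps on the
#' atlas grid. Regional means are piecewise constant per ROI: in the
#' "affected" ROI set, GM and FDG decrease and AV45 increases with planted
#' severity; voxel noise is additive Gaussian. With zero noise the regional
#' means equal the generative means exactly.
#'
#' @param atlas an \code{AtlasVolume}.
#' @param truth a \code{\link{makeSubjectTruth}} result.
#' @param seed integer seed (noise realization).
#' @param noiseSd additive voxel noise standard deviation.
#' @param affectedFraction fraction of ROIs (by id order) carrying the
#'   severity effect.
#' @return list with elements \code{gm}, \code{wm}, \code{fdg}, \code{av45}
#'   (3D arrays; background voxels are 0).
#' @export
makeSubjectVolumes <- function(atlas, truth, seed = 1L, noiseSd = 0.05,
                               affectedFraction = 0.3) {
  set.seed(as.integer(seed))
  lab <- atlas@labels
  R <- nRois(atlas)
  nAff <- ceiling(affectedFraction * R)
  affected <- seq_len(nAff)
  sev <- truth$severity
  roiMean <- function(base, affDelta) {
    m <- rep(base, R)
    m[affected] <- base + affDelta
    m
  }
  means <- list(
    gm = roiMean(0.70, -0.25 * sev),
    wm = roiMean(0.60, 0),
    fdg = roiMean(1.30, -0.35 * sev),
    av45 = roiMean(1.00, (0.40 + 0.10 * truth$amyloidPositive) * sev))
  inMask <- lab != 0L
  labIdx <- lab[inMask]
  out <- lapply(means, function(m) {
    v <- array(0, dim(lab))
    base <- m[labIdx]
    if (noiseSd > 0) base <- base + stats::rnorm(length(base), 0, noiseSd)
    v[inMask] <- base
    v
  })
  out
}

#' Default synthetic neuropsychological battery
#'
#' Items per cognitive domain with one-factor structure: continuous value =
#' loading x latent + noise. Ordinal items are generated continuous and
#' binned at fixed cut-points; the timed executive item is stored as a
#' completion time in seconds (log-linearly decreasing in the latent) and
#' flagged so the composite model log-transforms and direction-flips it.
#'
#' @return list of per-domain item specifications.
#' @export
defaultBatterySpec <- function() {
  mk <- function(items, loadings, ordinal, timed, direction, noiseSd = 3) {
    list(items = items, loadings = loadings, ordinal = ordinal,
         timed = timed, direction = direction, noiseSd = noiseSd)
  }
  list(
    memory = mk(paste0("mem_recall_", 1:5),
                c(0.9, 0.8, 0.7, 0.6, 0.5),
                ordinal = rep(FALSE, 5), timed = rep(FALSE, 5),
                direction = rep(1, 5)),
    language = mk(c("lang_fluency", "lang_naming", "lang_wordfind",
                    "lang_bnt"),
                  c(0.9, 0.8, 0.6, 0.5),
                  ordinal = c(FALSE, TRUE, TRUE, FALSE),
                  timed = rep(FALSE, 4), direction = rep(1, 4)),
    visuospatial = mk(c("vis_clock", "vis_praxis_constr", "vis_praxis_idea"),
                     c(0.8, 0.7, 0.6),
                     ordinal = rep(TRUE, 3), timed = rep(FALSE, 3),
                     direction = rep(1, 3)),
    executive = mk(c("exec_tmt_seconds", "exec_cancellation",
                     "exec_switching"),
                   c(0.9, 0.7, 0.5),
                   ordinal = c(FALSE, FALSE, FALSE),
                   timed = c(TRUE, FALSE, FALSE),
                   direction = c(-1, 1, 1)))
}

ordinalCutpoints <- function(loading) loading * c(30, 55, 75, 90)

#' Generate a longitudinal visit battery for one subject
#'
#' For each domain, a latent trajectory latent(t) = intercept + slope * t
#' (slope from the planted truth) generates item scores as
#' loading x latent + noise; ordinal items are binned at fixed cut-points
#' and the timed item is emitted in seconds. Item cells are knocked out
#' missing-completely-at-random at \code{missingRate}.
#'
#' @param truth a \code{\link{makeSubjectTruth}} result.
#' @param nVisits number of visits (>= 1).
#' @param spacingYears years between consecutive visits.
#' @param seed integer seed.
#' @param battery a battery spec (\code{\link{defaultBatterySpec}}).
#' @param missingRate MCAR missingness rate per item cell.
#' @param itemNoiseSd 0 disables item noise (noiseless trajectories).
#' @param baselineAge,sex,education demographics carried on every visit.
#' @return data.frame of visits: date_days, item columns, diagnosis, age,
#'   sex, education.
#' @export
makeLongitudinalBattery <- function(truth, nVisits, spacingYears = 0.5,
                                    seed = 1L,
                                    battery = defaultBatterySpec(),
                                    missingRate = 0.04, itemNoiseSd = NULL,
                                    baselineAge = 73, sex = 0L,
                                    education = 16) {
  stopifnot(nVisits >= 1L, missingRate >= 0, missingRate <= 0.2)
  set.seed(as.integer(seed))
  tYears <- spacingYears * (seq_len(nVisits) - 1L)
  intercepts <- 100 - 40 * truth$severity
  df <- data.frame(date_days = round(365.25 * tYears))
  for (dom in names(battery)) {
    sp <- battery[[dom]]
    latent <- intercepts + truth$domainSlopes[[dom]] * tYears
    for (ii in seq_along(sp$items)) {
      l <- sp$loadings[ii]
      sd <- if (is.null(itemNoiseSd)) sp$noiseSd else itemNoiseSd
      cont <- l * latent + if (sd > 0) stats::rnorm(nVisits, 0, sd) else 0
      val <- if (sp$ordinal[ii]) {
        findInterval(cont, ordinalCutpoints(l))
      } else if (sp$timed[ii]) {
        exp(5 - 0.02 * cont)
      } else cont
      if (missingRate > 0)
        val[stats::runif(nVisits) < missingRate] <- NA
      df[[sp$items[ii]]] <- val
    }
  }
  df$diagnosis <- truthDiagnosisAt(truth, tYears)
  df$age <- baselineAge + tYears
  df$sex <- sex
  df$education <- education
  df
}

#' Configuration for a synthetic cohort
#'
#' Defines the study conditions: a modeling subset (all modalities present,
#' at least two years of follow-up, CN or MCI at baseline) and a larger
#' pre-training pool with incomplete modalities and shorter follow-up,
#' including dementia-stage subjects; a configured fraction of
#' amyloid-negative sustained-CN (normative) subjects.
#'
#' @param nModeling modeling-subset size.
#' @param nPretrainExtra additional pre-training-only subjects.
#' @param normativeFraction fraction of subjects drawn as amyloid-negative
#'   sustained-CN.
#' @param pFdgMissing,pAv45Missing probability that a pre-training-only
#'   subject lacks the FDG / AV45 modality.
#' @param itemMissingRate MCAR missingness per battery item cell.
#' @param noiseSd voxel noise sd for the volumes.
#' @param atlasShape atlas grid (default 32^3).
#' @param nRois number of atlas regions (default 116).
#' @param includeVolumes generate voxel data (disable for large
#'   statistics-only cohorts).
#' @param spacingYears visit spacing.
#' @export
cohortConfig <- function(nModeling = 50L, nPretrainExtra = 100L,
                         normativeFraction = 0.3, pFdgMissing = 0.4,
                         pAv45Missing = 0.5, itemMissingRate = 0.04,
                         noiseSd = 0.05, atlasShape = c(32L, 32L, 32L),
                         nRois = 116L, includeVolumes = TRUE,
                         spacingYears = 0.5) {
  rates <- c(normativeFraction, pFdgMissing, pAv45Missing, itemMissingRate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]")
  list(nModeling = as.integer(nModeling),
       nPretrainExtra = as.integer(nPretrainExtra),
       normativeFraction = normativeFraction, pFdgMissing = pFdgMissing,
       pAv45Missing = pAv45Missing, itemMissingRate = itemMissingRate,
       noiseSd = noiseSd, atlasShape = as.integer(atlasShape),
       nRois = as.integer(nRois), includeVolumes = isTRUE(includeVolumes),
       spacingYears = spacingYears)
}

#' Generate a seeded synthetic cohort
#'
#' Value-identical regeneration under the same seed and config. The first
#' \code{nModeling} subjects satisfy the modeling criteria (all three
#' imaging modalities, >= 2 years follow-up, CN/MCI at baseline); the
#' remaining subjects form the pre-training-only pool with planted modality
#' missingness and shorter follow-up.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer seed.
#' @param atlas optionally, a prebuilt \code{AtlasVolume} (otherwise built
#'   from the config).
#' @return a \code{\link{SyntheticCohort-class}}.
#' @export
makeCohort <- function(config = cohortConfig(), seed = 1L, atlas = NULL) {
  seed <- as.integer(seed)
  if (is.null(atlas) && config$includeVolumes)
    atlas <- makeAtlas(config$nRois, config$atlasShape, seed = seed)
  set.seed(seed)
  n <- config$nModeling + config$nPretrainExtra
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    modeling <- i <= config$nModeling
    isNorm <- stats::runif(1) < config$normativeFraction
    severity <- if (isNorm) stats::runif(1, 0, 0.15)
      else if (modeling) stats::runif(1, 0.15, 0.68)
      else stats::runif(1, 0.15, 1)
    amy <- if (isNorm) FALSE else NULL
    baselineAge <- stats::rnorm(1, 73, 6)
    sex <- stats::rbinom(1, 1, 0.47)
    education <- round(stats::rnorm(1, 16, 2.5))
    nVisits <- if (modeling) sample(5:13, 1) else sample(1:6, 1)
    hasFdg <- modeling || stats::runif(1) > config$pFdgMissing
    hasAv45 <- modeling || stats::runif(1) > config$pAv45Missing
    if (!modeling && hasFdg && hasAv45 && nVisits >= 5L)
      hasAv45 <- FALSE     # keep the modeling criteria exclusive
    truth <- makeSubjectTruth(severity, seed = seed + 7L * i,
                              amyloidPositive = amy)
    visits <- makeLongitudinalBattery(
      truth, nVisits, spacingYears = config$spacingYears,
      seed = seed + 7L * i + 1L, missingRate = config$itemMissingRate,
      baselineAge = baselineAge, sex = sex, education = education)
    vols <- NULL
    if (config$includeVolumes) {
      vv <- makeSubjectVolumes(atlas, truth, seed = seed + 7L * i + 2L,
                               noiseSd = config$noiseSd)
      vols <- list(mri = list(gm = vv$gm, wm = vv$wm),
                   fdg = if (hasFdg) vv$fdg,
                   av45 = if (hasAv45) vv$av45)
    }
    subjects[[i]] <- list(
      id = sprintf("S%04d", i), truth = truth, visits = visits,
      volumes = vols, modeling = modeling,
      hasModality = c(mri = TRUE, fdg = hasFdg, av45 = hasAv45),
      baselineAge = baselineAge, sex = sex, education = education,
      t0 = 0)
    # reseed the cohort-level stream so per-subject generators (which set
    # their own seeds) do not disturb it
    set.seed(seed + 13L * i)
  }
  cohort <- new("SyntheticCohort", subjects = subjects, seed = seed,
                config = config)
  if (config$includeVolumes) attr(cohort, "atlas") <- atlas
  cohort
}
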