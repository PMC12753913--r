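#' @import methods
NULL

#' AtlasVolume: integer ROI label map
#'
#' A 3D integer label volume defining a brain parcellation. Voxels labelled 0
#' are background; labels 1..R identify regions of interest (ROIs). The ROI
#' ordering stored in \code{roiIds} is fixed and reused by every downstream
#' feature mapping (tabular, volume, graph), so that feature positions are
#' comparable across subjects and modalities.
#'
#' @slot labels 3D integer array (0 = background).
#' @slot voxelSize numeric length-3, mm per axis.
#' @slot roiIds ordered integer vector of region ids.
#' @exportClass AtlasVolume
setClass("AtlasVolume",
  representation(labels = "array", voxelSize = "numeric", roiIds = "integer"))

setValidity("AtlasVolume", function(object) {
  lab <- object@labels
  if (length(dim(lab)) != 3L) return("labels must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  ids <- sort(unique(as.integer(lab[lab != 0])))
  if (!identical(ids, sort(object@roiIds)))
    return("every ROI id must occur at least once and no others")
  TRUE
})

#' BrainGraph: atlas-level connectivity graph with node features
#'
#' Undirected, unweighted graph over the R atlas ROIs. Edges come from the
#' sparsity pattern of a graphical-lasso precision matrix estimated on
#' ROI-mean FDG SUVR values; node features hold per-ROI statistics from one
#' or several imaging modalities (d = 2 per modality).
#'
#' @slot roiIds node order (identical to the atlas ROI order).
#' @slot edges integer matrix with two columns (i, j), i < j, no self loops.
#' @slot nodeFeatures numeric matrix R x d, or a 0 x 0 matrix when unset.
#' @slot lambda the L1 penalty weight used for estimation (NA when edges were
#'   supplied directly).
#' @slot precision the estimated precision matrix (R x R), kept for
#'   diagnostics; 0 x 0 when unavailable.
#' @slot meta list: estimation record (edge zero-tolerance, convergence info,
#'   provenance of the fitting sample).
#' @exportClass BrainGraph
setClass("BrainGraph",
  representation(roiIds = "integer", edges = "matrix",
                 nodeFeatures = "matrix", lambda = "numeric",
                 precision = "matrix", meta = "list"))

setValidity("BrainGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2L && nrow(e) > 0L) return("edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] >= e[, 2L])) return("edges must be stored with i < j")
    if (max(e) > length(object@roiIds)) return("edge endpoint outside node set")
  }
  nf <- object@nodeFeatures
  if (nrow(nf) > 0L && nrow(nf) != length(object@roiIds))
    return("nodeFeatures must have one row per ROI")
  TRUE
})

#' SyntheticCohort: seeded ADNI-like study population
#'
#' Container for a synthetic longitudinal cohort. Each subject carries ground
#' truth (severity, per-domain decline slopes, diagnosis path, amyloid
#' status), a visit table with item scores and demographics, and per-modality
#' template-space volumes (possibly absent, emulating incomplete modality
#' acquisition). A modeling subset (complete modalities, >= 2 years
#' follow-up) is distinguished from the larger pre-training pool.
#'
#' @slot subjects list of subject records (see \code{\link{makeCohort}}).
#' @slot seed integer seed the cohort was generated from.
#' @slot config generation parameters.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(subjects = "list", seed = "integer", config = "list"))

#' MeasurementModel: one-factor cognitive composite model
#'
#' A single-factor measurement model for one cognitive domain, with the
#' latent factor variance fixed at 1 for identification. Higher composite
#' scores mean better cognition (loadings are sign-aligned after fitting).
#' Timed items are log-transformed and direction-flipped before fitting;
#' item standardization statistics are stored so scoring new tables is
#' deterministic.
#'
#' @slot domain one of memory, language, visuospatial, executive.
#' @slot itemNames ordered item columns.
#' @slot loadings standardized loadings per item.
#' @slot uniquenesses residual variances per item.
#' @slot ordinalFlags,timedFlags,directions per-item metadata.
#' @slot itemCenter,itemScale standardization statistics from the fitting
#'   sample.
#' @slot estimator estimation record (e.g. "ml-onefactor").
#' @slot factorVariance fixed at 1.
#' @slot provenance list: subject ids / split the model was fitted on.
#' @exportClass MeasurementModel
setClass("MeasurementModel",
  representation(domain = "character", itemNames = "character",
                 loadings = "numeric", uniquenesses = "numeric",
                 ordinalFlags = "logical", timedFlags = "logical",
                 directions = "numeric", itemCenter = "numeric",
                 itemScale = "numeric", estimator = "character",
                 factorVariance = "numeric", provenance = "list"))

setValidity("MeasurementModel", function(object) {
  p <- length(object@itemNames)
  if (p < 1L) return("at least one item per domain")
  if (length(object@loadings) != p) return("one loading per item")
  if (!all(is.finite(object@loadings))) return("loadings must be finite")
  if (!identical(object@factorVariance, 1)) return("factor variance must be 1")
  TRUE
})

#' TaskSpec: multitask target-set specification
#'
#' Declares the binary, multiclass, and regression tasks of a (pre-)training
#' target set, with per-task loss weights and the Huber delta for regression
#' losses. Every task name must appear in exactly one family.
#'
#' @slot binary character vector of binary task names.
#' @slot multiclass named list: task name -> class labels.
#' @slot regression character vector of regression task names.
#' @slot weights named numeric, one nonnegative weight per task (default 1).
#' @slot huberDelta numeric, delta of the Huber loss (default 2.5).
#' @exportClass TaskSpec
setClass("TaskSpec",
  representation(binary = "character", multiclass = "list",
                 regression = "character", weights = "numeric",
                 huberDelta = "numeric"))

setValidity("TaskSpec", function(object) {
  nm <- c(object@binary, names(object@multiclass), object@regression)
  if (anyDuplicated(nm)) return("a task may appear in only one family")
  if (!all(nm %in% names(object@weights))) return("every task needs a weight")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (object@huberDelta <= 0) return("huberDelta must be positive")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "AtlasVolume", function(object) {
  cat("AtlasVolume:", paste(dim(object@labels), collapse = " x "),
      "voxels,", length(object@roiIds), "ROIs, voxel size",
      paste(object@voxelSize, collapse = "x"), "mm\n")
})

setMethod("show", "BrainGraph", function(object) {
  cat("BrainGraph:", length(object@roiIds), "nodes,", nrow(object@edges),
      "edges")
  if (!is.na(object@lambda)) cat(" (lambda =", object@lambda, ")")
  if (nrow(object@nodeFeatures) > 0L)
    cat(",", ncol(object@nodeFeatures), "node features")
  cat("\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  n <- length(object@subjects)
  nm <- sum(vapply(object@subjects, function(s) isTRUE(s$modeling), logical(1)))
  cat("SyntheticCohort:", n, "subjects (", nm, "modeling,", n - nm,
      "pre-training only ), seed", object@seed, "\n")
})

setMethod("show", "MeasurementModel", function(object) {
  cat("MeasurementModel [", object@domain, "]: ",
      length(object@itemNames), " items, estimator ", object@estimator,
      ", factor variance 1\n", sep = "")
})

setMethod("show", "TaskSpec", function(object) {
  cat("TaskSpec:", length(object@binary), "binary,",
      length(object@multiclass), "multiclass,",
      length(object@regression), "regression tasks; Huber delta",
      object@huberDelta, "\n")
})

## ---- accessors ----------------------------------------------------------

#' @describeIn AtlasVolume-accessors number of ROIs
#' @export
nRois <- function(atlas) length(atlas@roiIds)

#' Accessors for AtlasVolume
#'
#' @param atlas an \code{AtlasVolume}.
#' @name AtlasVolume-accessors
#' @export
atlasLabels <- function(atlas) atlas@labels

#' @rdname AtlasVolume-accessors
#' @export
voxelSize <- function(atlas) atlas@voxelSize

#' @rdname AtlasVolume-accessors
#' @export
roiIds <- function(atlas) atlas@roiIds

#' Accessors for BrainGraph
#'
#' @param graph a \code{BrainGraph}.
#' @name BrainGraph-accessors
#' @export
graphEdges <- function(graph) graph@edges

#' @rdname BrainGraph-accessors
#' @export
nodeFeatures <- function(graph) graph@nodeFeatures

#' @rdname BrainGraph-accessors
#' @export
graphLambda <- function(graph) graph@lambda

#' @rdname BrainGraph-accessors
#' @export
graphPrecision <- function(graph) graph@precision

#' Accessors for SyntheticCohort
#'
#' @param cohort a \code{SyntheticCohort}.
#' @name SyntheticCohort-accessors
#' @export
cohortSubjects <- function(cohort) cohort@subjects

#' @rdname SyntheticCohort-accessors
#' @export
nSubjects <- function(cohort) length(cohort@subjects)

#' @rdname SyntheticCohort-accessors
#' @export
subjectIds <- function(cohort)
  vapply(cohort@subjects, function(s) s$id, character(1))

#' @rdname SyntheticCohort-accessors
#' @export
modelingIds <- function(cohort) {
  keep <- vapply(cohort@subjects, function(s) isTRUE(s$modeling), logical(1))
  subjectIds(cohort)[keep]
}

#' Stack all per-subject visit tables of a cohort into one long table
#'
#' @param cohort a \code{SyntheticCohort}.
#' @return data.frame with one row per subject-visit.
#' @export
cohortVisits <- function(cohort) {
  do.call(rbind, lapply(cohort@subjects, function(s) {
    cbind(subject_id = s$id, s$visits, stringsAsFactors = FALSE)
  }))
}

#' Accessors for MeasurementModel
#'
#' @param model a \code{MeasurementModel}.
#' @name MeasurementModel-accessors
#' @export
modelLoadings <- function(model) stats::setNames(model@loadings, model@itemNames)

#' @rdname MeasurementModel-accessors
#' @export
modelDomain <- function(model) model@domain

#' @rdname MeasurementModel-accessors
#' @export
factorVariance <- function(model) model@factorVariance

#' List all task names of a TaskSpec
#'
#' @param spec a \code{TaskSpec}.
#' @export
taskNames <- function(spec)
  c(spec@binary, names(spec@multiclass), spec@regression)
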