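# File interchange: NIfTI volumes (RNifti), TSV visit/feature/edge tables,
# JSON metadata.

#' Write an atlas (or any 3D volume) to NIfTI
#'
#' @param x an \code{AtlasVolume} or a 3D array.
#' @param path output .nii / .nii.gz path.
#' @param voxelSize mm per axis (taken from the atlas when given one).
#' @export
writeVolumeNifti <- function(x, path, voxelSize = c(1, 1, 1)) {
  if (is(x, "AtlasVolume")) {
    voxelSize <- x@voxelSize
    x <- x@labels
  }
  img <- RNifti::asNifti(x, reference = NULL)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI label volume back into an AtlasVolume
#'
#' @param path .nii / .nii.gz file.
#' @export
readAtlasNifti <- function(path) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(round(img)), dim(img))
  ids <- sort(unique(as.integer(lab[lab != 0L])))
  new("AtlasVolume", labels = lab,
      voxelSize = as.numeric(RNifti::pixdim(img))[1:3],
      roiIds = ids)
}

#' Write cohort visit tables as TSV
#'
#' One row per subject-visit: subject_id, date_days, item columns,
#' diagnosis, age, sex, education.
#'
#' @param cohort a \code{SyntheticCohort} (or a prepared long table).
#' @param path output .tsv path.
#' @export
writeVisitsTsv <- function(cohort, path) {
  tbl <- if (is(cohort, "SyntheticCohort")) cohortVisits(cohort) else cohort
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a visit TSV table
#' @param path .tsv file.
#' @export
readVisitsTsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Write ROI features as TSV (one row per scan)
#' @param features named numeric vector or matrix of
#'   \code{\link{phiTabular}} outputs.
#' @param path output path.
#' @export
writeFeaturesTsv <- function(features, path) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a brain graph as an edge-list TSV plus a JSON sidecar
#'
#' The sidecar records the penalty weight, node order and estimation
#' metadata.
#'
#' @param graph a \code{BrainGraph}.
#' @param edgePath edge-list .tsv path.
#' @param metaPath .json sidecar path (default: edgePath with .json).
#' @export
writeGraphTsv <- function(graph, edgePath,
                          metaPath = sub("\\.tsv$", ".json", edgePath)) {
  e <- as.data.frame(graph@edges)
  utils::write.table(e, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(lambda = graph@lambda, nodes = graph@roiIds,
         zeroTol = graph@meta$zeroTol %||% NA),
    metaPath, auto_unbox = TRUE, digits = NA)
  invisible(edgePath)
}

#' Write subject ground truth and generation config as JSON
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param path output .json path.
#' @export
writeCohortJson <- function(cohort, path) {
  truth <- lapply(cohort@subjects, function(s)
    list(id = s$id, severity = s$truth$severity,
         domainSlopes = as.list(s$truth$domainSlopes),
         amyloidPositive = s$truth$amyloidPositive,
         modeling = s$modeling,
         hasModality = as.list(s$hasModality)))
  jsonlite::write_json(list(seed = cohort@seed, config = cohort@config,
                            subjects = truth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
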