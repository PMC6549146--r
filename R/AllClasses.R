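#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' MethylSet: probes-by-samples methylation container
#'
#' `MethylSet` extends [SummarizedExperiment::SummarizedExperiment] with two
#' assays, `beta` (methylation fractions in \code{[0, 1]}) and `detectionP`
#' (detection p-values), a probe manifest in `rowData()` and the clinical
#' sample sheet in `colData()`. All quality-control and normalization
#' functions operate on this container.
#'
#' The manifest (see [simulateManifest()]) carries, per probe: `probe_id`,
#' `chrom`, 1-based `pos`, Infinium `design_type` (`"I"`/`"II"`), and the
#' flags `is_sex_chrom`, `is_cross_reactive`, `is_bisulfite_control`,
#' `near_snp`. Exactly ten probes per manifest are bisulfite-conversion
#' controls (six type I, four type II), used to score per-sample conversion
#' efficiency.
#'
#' @aliases MethylSet-class
#' @exportClass MethylSet
setClass("MethylSet", contains = "SummarizedExperiment")

.manifestCols <- c("probe_id", "chrom", "pos", "design_type", "is_sex_chrom",
                   "is_cross_reactive", "is_bisulfite_control", "near_snp")

setValidity("MethylSet", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("beta", "detectionP") %in% an))
    msg <- c(msg, "assays must include 'beta' and 'detectionP'")
  if ("beta" %in% an) {
    b <- assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if ("detectionP" %in% an) {
    dp <- assay(object, "detectionP")
    if (any(dp < 0 | dp > 1, na.rm = TRUE))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  missing <- setdiff(.manifestCols, colnames(rowData(object)))
  if (length(missing))
    msg <- c(msg, paste0("rowData is missing manifest columns: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MethylSet
#'
#' @param beta probes-by-samples matrix of beta values in \code{[0, 1]}, with
#'   probe ids as rownames and sample ids as colnames.
#' @param detectionP matching matrix of detection p-values; defaults to all
#'   zeros (every call passed detection).
#' @param manifest probe manifest `data.frame`; rows are matched to `beta` by
#'   `probe_id`.
#' @param sampleSheet per-sample clinical covariates `data.frame` with a
#'   `sample_id` column matched to the columns of `beta`.
#' @return a [MethylSet-class] object.
#' @export
#' @examples
#' man <- simulateManifest(200, seed = 1)
#' sim <- simulateCohort(man, nSamples = 12, seed = 1)
#' sim$mset
MethylSet <- function(beta, detectionP = NULL, manifest = NULL,
                      sampleSheet = NULL) {
  beta <- as.matrix(beta)
  if (is.null(detectionP))
    detectionP <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  detectionP <- as.matrix(detectionP)
  if (!identical(dim(beta), dim(detectionP)))
    stop("'beta' and 'detectionP' must have identical dimensions")
  if (is.null(manifest))
    stop("a probe manifest is required")
  manifest <- as.data.frame(manifest)
  if (!all(rownames(beta) %in% manifest$probe_id))
    stop("all probes in 'beta' must appear in the manifest")
  manifest <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  cd <- if (is.null(sampleSheet)) {
    DataFrame(sample_id = colnames(beta), row.names = colnames(beta))
  } else {
    sampleSheet <- as.data.frame(sampleSheet)
    stopIfNotUnique(sampleSheet$sample_id, "sample_id")
    if (!setequal(sampleSheet$sample_id, colnames(beta)))
      stop("sample sheet ids must match the columns of 'beta'")
    sampleSheet <- sampleSheet[match(colnames(beta), sampleSheet$sample_id), ,
                               drop = FALSE]
    DataFrame(sampleSheet, row.names = sampleSheet$sample_id)
  }
  se <- SummarizedExperiment(
    assays = SimpleList(beta = beta, detectionP = detectionP),
    rowData = DataFrame(manifest, row.names = manifest$probe_id),
    colData = cd)
  new("MethylSet", se)
}

#' QC report for probe and sample filtering
#'
#' Records every probe and sample removed during quality control together
#' with the (single, first-matching) reason, the per-sample bisulfite
#' conversion efficiency, and before/after counts. Probe reasons follow the
#' fixed precedence `control > sex_chrom > cross_reactive > near_snp /
#' gap_signal > detection`; sample reason is `pca_outlier`.
#'
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport", representation(
  removedProbes = "data.frame",
  removedSamples = "data.frame",
  bisulfiteEfficiency = "numeric",
  probesBefore = "integer", probesAfter = "integer",
  samplesBefore = "integer", samplesAfter = "integer"))

setValidity("QCReport", function(object) {
  msg <- character()
  if (!identical(sort(names(object@removedProbes)), c("probe_id", "reason")))
    msg <- c(msg, "removedProbes needs columns probe_id, reason")
  if (anyDuplicated(object@removedProbes$probe_id))
    msg <- c(msg, "each removed probe must carry exactly one reason")
  if (object@probesAfter != object@probesBefore - nrow(object@removedProbes))
    msg <- c(msg, "probe counts do not reconcile with removals")
  if (object@samplesAfter !=
      object@samplesBefore - nrow(object@removedSamples))
    msg <- c(msg, "sample counts do not reconcile with removals")
  if (length(msg)) msg else TRUE
})

#' Cross-cohort replication report
#'
#' Produced by [replicateProbes()]: primary discoveries (BH q < 0.05), the
#' subset testable in the replication cohort, the subset replicating
#' (replication p below alpha with the same direction of effect), probes
#' excluded because they did not survive replication-cohort QC, and -- once
#' [combinedAssociation()] has been run -- the replicated probes that remain
#' significant in the pooled cohort.
#'
#' @aliases ReplicationReport-class
#' @exportClass ReplicationReport
setClass("ReplicationReport", representation(
  primarySignificant = "character",
  tested = "character",
  replicated = "character",
  combinedSignificant = "character",
  excluded = "data.frame"))

setValidity("ReplicationReport", function(object) {
  msg <- character()
  if (!all(object@tested %in% object@primarySignificant))
    msg <- c(msg, "tested must be a subset of primarySignificant")
  if (!all(object@replicated %in% object@tested))
    msg <- c(msg, "replicated must be a subset of tested")
  if (!all(object@combinedSignificant %in% object@replicated))
    msg <- c(msg, "combinedSignificant must be a subset of replicated")
  if (length(msg)) msg else TRUE
})
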