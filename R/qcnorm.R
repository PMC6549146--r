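#' @rdname bisulfiteEfficiency
#' @export
setMethod("bisulfiteEfficiency", "MethylSet", function(object) {
  man <- probeManifest(object)
  ctrl <- man$probe_id[man$is_bisulfite_control]
  if (length(ctrl) != 10L)
    stop("the manifest must flag exactly 10 bisulfite control probes ",
         "present in the matrix (found ", length(ctrl), ")")
  apply(betaValues(object)[ctrl, , drop = FALSE], 2, stats::median,
        na.rm = TRUE)
})

#' Gap-signal probe detection
#'
#' Flags probes whose beta distribution across samples splits into discrete,
#' well-separated clusters -- the signature of an underlying sequence
#' variant rather than a continuous methylation signal. Per probe the sorted
#' beta values are cut wherever a successive gap exceeds `gapThreshold`; the
#' probe is flagged when at least two of the resulting groups each hold at
#' least `outlierMin` samples (so a lone outlier sample does not create a
#' gap call).
#'
#' @param beta probes-by-samples beta matrix (or a [MethylSet-class]).
#' @param gapThreshold minimum beta gap that splits groups, in (0, 1).
#' @param outlierMin minimum group size for a split to count.
#' @return character vector of flagged probe ids.
#' @export
#' @examples
#' b <- rbind(gap = rep(c(0.05, 0.5, 0.95), each = 10),
#'            flat = runif(30, 0.4, 0.45))
#' colnames(b) <- paste0("s", 1:30)
#' gapHunt(b)
gapHunt <- function(beta, gapThreshold = 0.05, outlierMin = 3L) {
  if (is(beta, "MethylSet")) beta <- betaValues(beta)
  if (gapThreshold <= 0 || gapThreshold >= 1)
    stop("gapThreshold must lie strictly between 0 and 1")
  if (ncol(beta) < 2L * outlierMin)
    stop("need at least 2 * outlierMin samples to call gap probes")
  flagged <- apply(beta, 1, function(x) {
    x <- sort(x[!is.na(x)])
    if (length(x) < 2L * outlierMin) return(FALSE)
    cuts <- which(diff(x) > gapThreshold)
    if (!length(cuts)) return(FALSE)
    sizes <- diff(c(0L, cuts, length(x)))
    sum(sizes >= outlierMin) >= 2L
  })
  rownames(beta)[flagged]
}

#' Probe-level quality-control filtering
#'
#' Removes, in a fixed precedence order (`control > sex_chrom >
#' cross_reactive > near_snp / gap_signal > detection`): bisulfite control
#' probes, sex-chromosome probes, known cross-reactive probes, then either
#' externally supplied gap-signal probes (kidney mode) or SNP-adjacent
#' probes (blood mode, where gap hunting is replaced by a dbSNP proximity
#' filter), and finally probes whose detection p-value exceeds
#' `detectionThreshold` in more than `detectionFraction` of samples.
#' Individual failing entries of retained probes are set to `NA` when
#' `setFailingNA` is `TRUE`.
#'
#' @param mset a [MethylSet-class].
#' @param detectionThreshold detection p-value above which a call fails.
#' @param detectionFraction maximum tolerated fraction of failing samples
#'   per probe.
#' @param mode `"kidney"` (gap filter) or `"blood"` (near-SNP filter).
#' @param gapProbes probe ids from [gapHunt()]; ignored in blood mode.
#' @param setFailingNA mask failing entries of retained probes as `NA`.
#' @return list with `mset` (filtered) and `report` (a [QCReport-class];
#'   sample-level fields are filled in by [runQc()]).
#' @export
filterProbes <- function(mset, detectionThreshold = 0.01,
                         detectionFraction = 0.05,
                         mode = c("kidney", "blood"), gapProbes = character(),
                         setFailingNA = TRUE) {
  mode <- match.arg(mode)
  man <- probeManifest(mset)
  detp <- detectionP(mset)
  failFrac <- rowMeans(detp > detectionThreshold, na.rm = TRUE)
  reason <- rep(NA_character_, nrow(man))
  assignReason <- function(idx, label) {
    idx <- idx & is.na(reason)
    reason[idx] <<- label
  }
  assignReason(man$is_bisulfite_control, "control")
  assignReason(man$is_sex_chrom, "sex_chrom")
  assignReason(man$is_cross_reactive, "cross_reactive")
  if (mode == "blood") {
    assignReason(man$near_snp, "near_snp")
  } else {
    assignReason(man$probe_id %in% gapProbes, "gap_signal")
  }
  assignReason(failFrac > detectionFraction, "detection")
  drop <- !is.na(reason)
  if (all(drop))
    stop("no probes survive quality-control filtering")
  kept <- mset[!drop, ]
  if (setFailingNA) {
    b <- assay(kept, "beta")
    b[detectionP(kept) > detectionThreshold] <- NA_real_
    assays(kept)$beta <- b
  }
  report <- new("QCReport",
    removedProbes = data.frame(probe_id = man$probe_id[drop],
                               reason = reason[drop],
                               stringsAsFactors = FALSE),
    removedSamples = data.frame(sample_id = character(),
                                reason = character(),
                                stringsAsFactors = FALSE),
    bisulfiteEfficiency = numeric(),
    probesBefore = nrow(mset), probesAfter = nrow(kept),
    samplesBefore = ncol(mset), samplesAfter = ncol(kept))
  list(mset = kept, report = report)
}

#' @importFrom SummarizedExperiment assays assays<-
NULL

#' PCA-based sample outlier flagging
#'
#' Projects samples onto the first two principal components of the M-value
#' matrix and flags those whose Euclidean distance from the centroid exceeds
#' `median(d) + kSd * mad(d)`, a robust rule that a handful of aberrant
#' samples cannot inflate.
#'
#' @param m probes-by-samples M-value matrix.
#' @param kSd robust-SD multiplier.
#' @return character vector of flagged sample ids.
#' @export
pcaOutliers <- function(m, kSd = 4) {
  if (ncol(m) < 10L)
    stop("PCA outlier detection needs at least 10 samples")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L || all(apply(m, 1, stats::var) == 0))
    stop("M-value matrix is degenerate (zero variance)")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = 2L)
  d <- sqrt(rowSums(pc$x[, 1:2, drop = FALSE]^2))
  s <- stats::mad(d)
  if (s == 0) return(character())
  colnames(m)[d > stats::median(d) + kSd * s]
}

#' End-to-end quality control
#'
#' Scores bisulfite efficiency, calls gap probes (kidney mode), applies
#' [filterProbes()], transforms to M-values and flags PCA outlier samples,
#' returning the cleaned [MethylSet-class] with the efficiency score added
#' to the sample sheet and a complete [QCReport-class].
#'
#' @inheritParams filterProbes
#' @param gapThreshold,outlierMin passed to [gapHunt()] in kidney mode.
#' @param kSd passed to [pcaOutliers()].
#' @return list with `mset`, `m` (post-QC M-value matrix) and `report`.
#' @export
#' @examples
#' man <- simulateManifest(300, seed = 3)
#' sim <- simulateCohort(man, nSamples = 30, seed = 3)
#' qc <- runQc(sim$mset)
#' qc$report
runQc <- function(mset, detectionThreshold = 0.01, detectionFraction = 0.05,
                  mode = c("kidney", "blood"), gapThreshold = 0.05,
                  outlierMin = 3L, kSd = 4, setFailingNA = TRUE) {
  mode <- match.arg(mode)
  man <- probeManifest(mset)
  eff <- if (sum(man$is_bisulfite_control) == 10L) {
    bisulfiteEfficiency(mset)
  } else if ("bisulfite_efficiency_measured" %in% names(colData(mset))) {
    # already QC'd input: controls are gone, reuse the recorded score
    stats::setNames(colData(mset)$bisulfite_efficiency_measured,
                    colnames(mset))
  } else {
    warning("control probes absent and no recorded conversion score; ",
            "bisulfite efficiency unavailable")
    stats::setNames(rep(NA_real_, ncol(mset)), colnames(mset))
  }
  gap <- if (mode == "kidney")
    gapHunt(betaValues(mset), gapThreshold, outlierMin) else character()
  fp <- filterProbes(mset, detectionThreshold, detectionFraction, mode,
                     gapProbes = gap, setFailingNA = setFailingNA)
  m <- betaToM(betaValues(fp$mset))
  out <- if (ncol(m) >= 10L) pcaOutliers(m, kSd) else character()
  keptSamples <- setdiff(colnames(m), out)
  mset2 <- fp$mset[, keptSamples]
  colData(mset2)$bisulfite_efficiency_measured <- eff[keptSamples]
  report <- new("QCReport",
    removedProbes = fp$report@removedProbes,
    removedSamples = data.frame(
      sample_id = out,
      reason = rep("pca_outlier", length(out)),
      stringsAsFactors = FALSE),
    bisulfiteEfficiency = eff,
    probesBefore = nrow(mset), probesAfter = nrow(mset2),
    samplesBefore = ncol(mset), samplesAfter = ncol(mset2))
  list(mset = mset2, m = m[, keptSamples, drop = FALSE], report = report)
}

#' @importFrom SummarizedExperiment colData colData<-
NULL
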