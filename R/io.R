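# ---- I/O surface -----------------------------------------------------------
#
# Plain-text dialects: UTF-8, header row, NA token "NA"; matrices as TSV
# with the probe/gene id in the first column, tables as CSV/TSV. Numeric
# values are written with 17 significant digits so read(write(x)) == x.

.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.writeMatrixTsv <- function(x, file, idCol) {
  df <- data.frame(rownames(x), apply(x, 2, .fmtNum),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(idCol, colnames(x))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.readMatrixTsv <- function(file, idCol) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != idCol)
    stop("expected first column '", idCol, "' in ", file, ", found '",
         names(df)[1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

.checkSchema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  extra <- setdiff(names(df), required)
  if (length(missing))
    stop(what, " is missing columns: ", paste(missing, collapse = ", "),
         if (length(extra)) paste0(" (unexpected: ",
                                   paste(extra, collapse = ", "), ")")
         else "")
  invisible(df)
}

#' Read and write beta-value matrices
#'
#' A beta matrix and its detection-p matrix travel as a pair of TSV files
#' (`<stem>.beta.tsv`, `<stem>.detp.tsv`) with probes in rows and a
#' `probe_id` first column.
#'
#' @param stem file stem (paths are `<stem>.beta.tsv` / `<stem>.detp.tsv`).
#' @param mset a [MethylSet-class] (for writing).
#' @param manifest,sampleSheet passed to [MethylSet()] when reading.
#' @return `writeBetaMatrix` returns the stem invisibly; `readBetaMatrix`
#'   returns a [MethylSet-class].
#' @export
writeBetaMatrix <- function(mset, stem) {
  .writeMatrixTsv(betaValues(mset), paste0(stem, ".beta.tsv"), "probe_id")
  .writeMatrixTsv(detectionP(mset), paste0(stem, ".detp.tsv"), "probe_id")
  invisible(stem)
}

#' @rdname writeBetaMatrix
#' @export
readBetaMatrix <- function(stem, manifest, sampleSheet = NULL) {
  beta <- .readMatrixTsv(paste0(stem, ".beta.tsv"), "probe_id")
  detp <- .readMatrixTsv(paste0(stem, ".detp.tsv"), "probe_id")
  MethylSet(beta, detp, manifest, sampleSheet)
}

#' Read and write sample sheets, manifests and eGFR series
#'
#' Sample sheets and probe manifests travel as CSV; longitudinal eGFR
#' series as CSV with columns `subject_id`, `time_years`, `egfr`. Schema
#' violations (missing columns, duplicated ids, non-increasing visit times,
#' out-of-range fibrosis) are errors.
#'
#' @param x object to write.
#' @param file path.
#' @return readers return `data.frame`s; writers return `file` invisibly.
#' @export
writeSampleSheet <- function(x, file) {
  num <- vapply(x, is.numeric, TRUE) &
    !vapply(x, is.integer, TRUE)
  x[num] <- lapply(x[num], .fmtNum)
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("sample sheet is missing column: sample_id")
  stopIfNotUnique(df$sample_id, "sample_id")
  if ("fibrosis_pct" %in% names(df)) {
    f <- df$fibrosis_pct
    if (any(f < 0 | f > 100, na.rm = TRUE))
      stop("fibrosis_pct must lie in [0, 100]")
  }
  df
}

#' @rdname writeSampleSheet
#' @export
writeManifest <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname writeSampleSheet
#' @export
readManifest <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  .checkSchema(df, .manifestCols, "manifest")
  stopIfNotUnique(df$probe_id, "probe_id")
  if (any(df$pos < 1)) stop("manifest positions must be >= 1")
  df
}

#' @rdname writeSampleSheet
#' @export
writeEgfrSeries <- function(x, file) {
  x$time_years <- .fmtNum(x$time_years)
  x$egfr <- .fmtNum(x$egfr)
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname writeSampleSheet
#' @export
readEgfrSeries <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  .checkSchema(df, c("subject_id", "time_years", "egfr"), "eGFR series")
  if (any(df$egfr <= 0)) stop("egfr values must be positive")
  .checkSeries(df)
  df
}

#' Read and write expression matrices with TSS tables
#'
#' Expression travels as TSV (`gene_id` first column); the TSS table as CSV
#' with `gene_id, chrom, tss_pos, strand`.
#'
#' @param expr genes-by-samples matrix.
#' @param tss TSS table.
#' @param stem file stem (`<stem>.expr.tsv`, `<stem>.tss.csv`).
#' @return reader returns `list(expr, tss)`.
#' @export
writeExpressionMatrix <- function(expr, tss, stem) {
  .writeMatrixTsv(expr, paste0(stem, ".expr.tsv"), "gene_id")
  utils::write.csv(tss, paste0(stem, ".tss.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(stem)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(stem) {
  expr <- .readMatrixTsv(paste0(stem, ".expr.tsv"), "gene_id")
  tss <- utils::read.csv(paste0(stem, ".tss.csv"), stringsAsFactors = FALSE)
  .checkSchema(tss, c("gene_id", "chrom", "tss_pos", "strand"), "TSS table")
  if (!all(rownames(expr) %in% tss$gene_id))
    stop("every expression gene needs a TSS record")
  list(expr = expr, tss = tss)
}

#' Read and write chromatin-state BED files
#'
#' Standard BED conventions (0-based half-open on disk, 1-based GRanges in
#' memory; the conversion lives only here). The state label is the BED name
#' column; the tissue either comes from the `tissue` argument (one BED per
#' tissue) or a fifth `tissue` column in a BED-like TSV dialect.
#'
#' @param states [GenomicRanges::GRanges] with `state` (and `tissue`)
#'   metadata.
#' @param file path.
#' @param tissue tissue label for single-tissue BED files.
#' @return reader returns a [GenomicRanges::GRanges].
#' @export
writeStateBed <- function(states, file, tissue = NULL) {
  if (!is.null(tissue)) states <- states[states$tissue == tissue]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(states)),
    start = GenomicRanges::start(states) - 1L,
    end = GenomicRanges::end(states),
    state = states$state,
    tissue = if ("tissue" %in% names(S4Vectors::mcols(states)))
      states$tissue else tissue)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname writeStateBed
#' @export
readStateBed <- function(file, tissue = NULL) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4)
    stop("state BED needs at least chrom, start, end, name columns")
  names(df)[1:4] <- c("chrom", "start", "end", "state")
  if (any(df$start >= df$end))
    stop("BED intervals must satisfy start < end")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    state = df$state,
    tissue = if (ncol(df) >= 5) df[[5]] else tissue)
}

#' Manhattan/volcano-ready export of an association table
#'
#' Joins genomic coordinates onto an association result and adds the
#' -log10(p) column used by Manhattan plots (x = position) and volcano
#' plots (x = unadjusted Pearson r).
#'
#' @param result table from [probeAssociation()].
#' @param manifest probe manifest.
#' @return `data.frame(probe_id, chrom, pos, neg_log10_p, r, q)`.
#' @export
manhattanExport <- function(result, manifest) {
  idx <- match(result$probe_id, manifest$probe_id)
  data.frame(probe_id = result$probe_id,
             chrom = manifest$chrom[idx], pos = manifest$pos[idx],
             neg_log10_p = -log10(result$p), r = result$r, q = result$q,
             stringsAsFactors = FALSE)
}

#' Write an association-result table
#'
#' @param x result `data.frame` (association, augmentation, enrichment or
#'   eQTM table).
#' @param file path; tab-separated, full numeric precision.
#' @export
writeResultsTsv <- function(x, file) {
  num <- vapply(x, is.numeric, TRUE) & !vapply(x, is.integer, TRUE)
  x[num] <- lapply(x[num], .fmtNum)
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}
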