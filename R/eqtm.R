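#' Enumerate cis probe-gene pairs
#'
#' Pairs every probe with every gene whose transcription start site lies
#' within `window` bp of the probe position on the same chromosome
#' (inclusive boundary). The signed distance is strand-aware: positive
#' downstream of the TSS relative to the gene's strand; the unsigned
#' magnitude is what the window tests.
#'
#' @param manifest probe manifest (or any `data.frame` with `probe_id`,
#'   `chrom`, `pos`).
#' @param tss `data.frame(gene_id, chrom, tss_pos, strand)`; genes with a
#'   missing TSS are skipped with a warning.
#' @param window cis window in bp (default 500 kb).
#' @return `data.frame(probe_id, gene_id, distance)`.
#' @export
#' @examples
#' man <- data.frame(probe_id = "p1", chrom = "chr1", pos = 1e6)
#' tss <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
#'                   tss_pos = c(1.4e6, 1.6e6), strand = "+")
#' cisPairs(man, tss)  # only g1 is within 500 kb
cisPairs <- function(manifest, tss, window = 5e5) {
  bad <- is.na(tss$tss_pos) | is.na(tss$chrom)
  if (any(bad)) {
    warning(sum(bad), " gene(s) without a TSS record skipped: ",
            paste(utils::head(tss$gene_id[bad], 3), collapse = ", "))
    tss <- tss[!bad, , drop = FALSE]
  }
  probes <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1L))
  genes <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = tss$tss_pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(probes, genes,
                                      maxgap = as.integer(window))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  raw <- manifest$pos[qi] - tss$tss_pos[si]
  dist <- ifelse(tss$strand[si] == "-", -raw, raw)
  keep <- abs(raw) <= window
  data.frame(probe_id = manifest$probe_id[qi][keep],
             gene_id = tss$gene_id[si][keep],
             distance = dist[keep], stringsAsFactors = FALSE)
}

#' Single probe-gene association
#'
#' Simple least-squares regression of expression on the probe M-value, with
#' the two-sided p-value on the slope and the Pearson correlation (the
#' unadjusted effect usually displayed for eQTM hits).
#'
#' @param m M-values of one probe across samples.
#' @param expression expression of one gene across the same samples.
#' @return `data.frame(coefficient, se, t, p, r, n_used)`.
#' @export
pairAssociation <- function(m, expression) {
  ok <- stats::complete.cases(m, expression)
  if (sum(ok) < 10)
    stop("need at least 10 paired samples")
  x <- m[ok]; y <- expression[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector; association undefined")
  n <- length(x)
  bx <- stats::cov(x, y) / stats::var(x)
  res <- y - mean(y) - bx * (x - mean(x))
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  tval <- bx / se
  data.frame(coefficient = bx, se = se, t = tval,
             p = 2 * stats::pt(-abs(tval), n - 2),
             r = stats::cor(x, y), n_used = n)
}

# t statistics for a set of pairs given a column ordering of the
# expression matrix; mz/ez are row-standardized (mean 0, sd 1) matrices
.pairT <- function(mz, ez, pi, gi, ord, n) {
  r <- rowSums(mz[pi, , drop = FALSE] * ez[gi, ord, drop = FALSE]) / (n - 1)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  r * sqrt((n - 2) / (1 - r^2))
}

.rowStandardize <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  (x - mu) / s
}

# all permutations of 1..n (n small), identity first
.allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPerms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (j in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = j)
    }
  }
  out
}

#' Permutation significance for cis eQTM pairs
#'
#' Computes the per-pair regression t statistic, then builds a permutation
#' null by shuffling the sample labels of the expression matrix jointly
#' across genes. In the default pooled mode the |t| statistics of all pairs
#' and permutations form one shared null, giving the empirical p-values the
#' resolution needed for a stringent cutoff (8e-5) at a practical number of
#' permutations; `pooled = FALSE` restricts each pair to its own null.
#' `exhaustive = TRUE` enumerates all n! label permutations (identity
#' included) per pair, for small n.
#'
#' @param pairs `data.frame(probe_id, gene_id)` from [cisPairs()].
#' @param m probes-by-samples M-value matrix.
#' @param expression genes-by-samples expression matrix (same samples).
#' @param nPerm number of permutations (>= 100 unless exhaustive). A
#'   warning is issued when the pooled null is smaller than `10 / cutoff`.
#' @param cutoff significance cutoff on the empirical p-value.
#' @param pooled share the null across pairs.
#' @param exhaustive enumerate all permutations (n <= 8).
#' @param seed RNG seed.
#' @return `data.frame(probe_id, gene_id, coefficient, t, p_nominal,
#'   p_empirical, significant)` with null diagnostics in
#'   `attr(, "null_size")`.
#' @export
permutationSignificance <- function(pairs, m, expression, nPerm = 1000L,
                                    cutoff = 8e-5, pooled = TRUE,
                                    exhaustive = FALSE, seed = NULL) {
  samples <- intersect(colnames(m), colnames(expression))
  n <- length(samples)
  m <- m[, samples, drop = FALSE]
  expression <- expression[, samples, drop = FALSE]
  if (exhaustive && n > 8)
    stop("exhaustive enumeration is limited to 8 samples")
  if (!exhaustive && nPerm < 100L)
    stop("nPerm must be at least 100")
  pi <- match(pairs$probe_id, rownames(m))
  gi <- match(pairs$gene_id, rownames(expression))
  if (anyNA(pi) || anyNA(gi))
    stop("pairs reference probes or genes absent from the matrices")
  mz <- .rowStandardize(m)
  ez <- .rowStandardize(expression)
  tObs <- .pairT(mz, ez, pi, gi, seq_len(n), n)
  coefs <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- m[pi[k], ]; y <- expression[gi[k], ]
    stats::cov(x, y) / stats::var(x)
  }, 0)
  pNominal <- 2 * stats::pt(-abs(tObs), n - 2)

  if (exhaustive) {
    perms <- .allPerms(n)
    nullT <- vapply(perms, function(ord)
      .pairT(mz, ez, pi, gi, ord, n), numeric(nrow(pairs)))
    nullT <- matrix(nullT, nrow = nrow(pairs))
    pEmp <- vapply(seq_len(nrow(pairs)), function(k)
      mean(abs(nullT[k, ]) >= abs(tObs[k])), 0)
    nullSize <- length(perms)
  } else {
    nullT <- withSeed(seed, {
      vapply(seq_len(nPerm), function(b)
        .pairT(mz, ez, pi, gi, sample.int(n), n), numeric(nrow(pairs)))
    })
    nullT <- matrix(nullT, nrow = nrow(pairs))
    if (pooled) {
      pool <- sort(abs(as.numeric(nullT)))
      nullSize <- length(pool)
      if (nullSize < 10 / cutoff)
        warning("pooled null of ", nullSize, " statistics is small for a ",
                cutoff, " cutoff; empirical p-values are floor-limited")
      exceed <- nullSize - findInterval(abs(tObs) - 1e-12, pool)
      pEmp <- (1 + exceed) / (1 + nullSize)
    } else {
      nullSize <- nPerm
      pEmp <- (1 + rowSums(abs(nullT) >= abs(tObs) - 1e-12)) / (1 + nPerm)
    }
  }
  out <- data.frame(probe_id = pairs$probe_id, gene_id = pairs$gene_id,
                    coefficient = coefs, t = tObs, p_nominal = pNominal,
                    p_empirical = pEmp,
                    significant = pEmp < cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "null_size") <- nullSize
  attr(out, "cutoff") <- cutoff
  out
}
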