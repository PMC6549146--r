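#' Probe-wise covariate-adjusted association
#'
#' Fits, for every probe, an ordinary least-squares regression of the
#' M-value on the phenotype (percent interstitial fibrosis, or baseline
#' eGFR for the function-level variant) plus clinical covariates --
#' typically age, sex, race, diabetes, hypertension, batch, bisulfite
#' conversion efficiency and lymphocytic infiltrate. Samples with a missing
#' phenotype or covariate are dropped listwise. The reported coefficient is
#' the phenotype effect in M-units per unit phenotype; the unadjusted
#' Pearson correlation with the phenotype is reported alongside for
#' volcano-style displays.
#'
#' Probes without missing values share one design decomposition, so the
#' genome-wide fit is a single matrix operation; probes with masked entries
#' fall back to a per-probe fit on their complete cases.
#'
#' @param m probes-by-samples M-value matrix.
#' @param phenotype numeric phenotype, one value per sample (`NA` allowed).
#' @param covariates `data.frame` of per-sample covariates or `NULL`;
#'   character/factor columns are dummy-coded.
#' @param qLevel BH threshold used for the `significant` flag.
#' @return `data.frame` with one row per probe: `probe_id`, `b`, `se`, `t`,
#'   `p`, `q`, `direction`, `r`, `n_used`, `significant`.
#' @export
#' @examples
#' man <- simulateManifest(100, seed = 5)
#' sim <- simulateCohort(man, nSamples = 40, seed = 5)
#' m <- betaToM(betaValues(sim$mset))
#' res <- probeAssociation(m, sim$sampleSheet$fibrosis_pct,
#'                         sim$sampleSheet[, c("age", "sex")])
#' head(res)
probeAssociation <- function(m, phenotype, covariates = NULL,
                             qLevel = 0.05) {
  m <- as.matrix(m)
  n <- ncol(m)
  if (length(phenotype) != n)
    stop("phenotype length must equal the number of samples")
  df <- data.frame(.phenotype = as.numeric(phenotype))
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    df <- cbind(df, as.data.frame(covariates))
  keep <- stats::complete.cases(df)
  X <- stats::model.matrix(~ ., data = df[keep, , drop = FALSE])
  rank <- qr(X)$rank
  if (rank < ncol(X)) {
    piv <- qr(X)$pivot
    stop("collinear design; aliased columns: ",
         paste(colnames(X)[piv[(rank + 1):ncol(X)]], collapse = ", "))
  }
  if (sum(keep) < ncol(X) + 5L)
    stop("phenotype and covariates must be non-missing for at least ",
         ncol(X) + 5L, " samples")
  j <- which(colnames(X) == ".phenotype")
  Y <- t(m[, keep, drop = FALSE])
  phen <- df$.phenotype[keep]

  fitFull <- function(Xs, Ys) {
    # Ys: samples x probes, no missing values
    qrX <- qr(Xs)
    coefs <- qr.coef(qrX, Ys)
    res <- Ys - Xs %*% coefs
    dfres <- nrow(Xs) - ncol(Xs)
    sigma2 <- colSums(res^2) / dfres
    xtxinv <- chol2inv(chol(crossprod(Xs)))
    list(b = coefs[j, ], se = sqrt(sigma2 * xtxinv[j, j]), dfres = dfres)
  }

  b <- se <- tval <- p <- r <- rep(NA_real_, nrow(m))
  nUsed <- rep(0L, nrow(m))
  hasNA <- colSums(is.na(Y)) > 0
  if (any(!hasNA)) {
    f <- fitFull(X, Y[, !hasNA, drop = FALSE])
    b[!hasNA] <- f$b
    se[!hasNA] <- f$se
    tval[!hasNA] <- f$b / f$se
    p[!hasNA] <- 2 * stats::pt(-abs(tval[!hasNA]), f$dfres)
    nUsed[!hasNA] <- nrow(X)
    r[!hasNA] <- drop(stats::cor(phen, Y[, !hasNA, drop = FALSE]))
  }
  for (k in which(hasNA)) {
    ok <- !is.na(Y[, k])
    if (sum(ok) < ncol(X) + 5L) next
    Xi <- X[ok, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi)) next
    f <- fitFull(Xi, Y[ok, k, drop = FALSE])
    b[k] <- f$b; se[k] <- f$se
    tval[k] <- b[k] / se[k]
    p[k] <- 2 * stats::pt(-abs(tval[k]), f$dfres)
    nUsed[k] <- sum(ok)
    r[k] <- stats::cor(phen[ok], Y[ok, k])
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(probe_id = rownames(m), b = b, se = se, t = tval, p = p, q = q,
             direction = sign(b), r = r, n_used = nUsed,
             significant = !is.na(q) & q < qLevel,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment with discovery flags
#'
#' @param p vector of p-values in (0, 1].
#' @param qLevel discovery threshold on the adjusted values.
#' @return `data.frame(p, q, significant)` in input order.
#' @export
#' @examples
#' adjustFdr(c(0.001, 0.01, 0.02, 0.8))
adjustFdr <- function(p, qLevel = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = !is.na(q) & q < qLevel)
}

#' Cross-cohort replication with directional consistency
#'
#' Primary-cohort discoveries (BH q below `qLevel`) are looked up in the
#' replication-cohort results; probes absent there (removed by
#' replication-cohort QC) are recorded as excluded for poor data quality. A
#' probe replicates when its replication p-value is below `alpha` and the
#' direction of the methylation change agrees between cohorts.
#'
#' @param primary,replication association tables from [probeAssociation()].
#' @param alpha nominal replication threshold.
#' @param qLevel primary-cohort discovery threshold.
#' @return a [ReplicationReport-class].
#' @export
replicateProbes <- function(primary, replication, alpha = 0.05,
                            qLevel = 0.05) {
  if (!length(intersect(primary$probe_id, replication$probe_id)))
    stop("primary and replication results share no probes")
  prim <- primary[!is.na(primary$q) & primary$q < qLevel, , drop = FALSE]
  idx <- match(prim$probe_id, replication$probe_id)
  tested <- prim$probe_id[!is.na(idx)]
  excluded <- prim$probe_id[is.na(idx)]
  rep2 <- replication[idx[!is.na(idx)], , drop = FALSE]
  primTested <- prim[!is.na(idx), , drop = FALSE]
  hit <- !is.na(rep2$p) & rep2$p < alpha &
    rep2$direction == primTested$direction & rep2$direction != 0
  new("ReplicationReport",
      primarySignificant = prim$probe_id,
      tested = tested,
      replicated = tested[hit],
      combinedSignificant = character(),
      excluded = data.frame(
        probe_id = excluded,
        reason = rep("poor_data_quality", length(excluded)),
        stringsAsFactors = FALSE))
}

#' Pooled-cohort association
#'
#' Re-runs the probe-wise association on the primary and replication
#' cohorts pooled together, over the probes common to both. Samples present
#' in both cohorts are deduplicated (the primary copy is kept) and a cohort
#' indicator is added as a covariate so a cohort-level shift cannot
#' masquerade as a phenotype effect. When a replication report is supplied,
#' its `combinedSignificant` slot is filled with the replicated probes that
#' stay significant (BH within the full pooled probe set).
#'
#' @param mPrimary,mReplication M-value matrices.
#' @param phenotypePrimary,phenotypeReplication phenotype vectors.
#' @param covariatesPrimary,covariatesReplication covariate data frames
#'   (same columns in both cohorts).
#' @param report optional [ReplicationReport-class] to update.
#' @param qLevel BH threshold in the pooled analysis.
#' @param dedup drop replication copies of shared sample ids.
#' @return list with `result` (pooled association table) and `report`.
#' @export
combinedAssociation <- function(mPrimary, mReplication, phenotypePrimary,
                                phenotypeReplication, covariatesPrimary = NULL,
                                covariatesReplication = NULL, report = NULL,
                                qLevel = 0.05, dedup = TRUE) {
  shared <- intersect(rownames(mPrimary), rownames(mReplication))
  if (!length(shared)) stop("cohorts share no probes")
  keepRep <- rep(TRUE, ncol(mReplication))
  if (dedup)
    keepRep <- !(colnames(mReplication) %in% colnames(mPrimary))
  m <- cbind(mPrimary[shared, , drop = FALSE],
             mReplication[shared, keepRep, drop = FALSE])
  phen <- c(phenotypePrimary, phenotypeReplication[keepRep])
  cov <- NULL
  if (!is.null(covariatesPrimary)) {
    cov <- rbind(as.data.frame(covariatesPrimary),
                 as.data.frame(covariatesReplication)[keepRep, , drop = FALSE])
  }
  cov <- if (is.null(cov)) {
    data.frame(cohort = rep(c("primary", "replication"),
                            c(ncol(mPrimary), sum(keepRep))))
  } else {
    cov$cohort <- rep(c("primary", "replication"),
                      c(ncol(mPrimary), sum(keepRep)))
    cov
  }
  # a covariate can collapse to a single level once cohorts are pooled and
  # deduplicated (e.g. the cohort indicator itself); drop it rather than
  # passing a degenerate design column on
  constant <- vapply(cov, function(x) length(unique(x[!is.na(x)])) < 2, TRUE)
  cov <- cov[, !constant, drop = FALSE]
  if (ncol(cov) == 0) cov <- NULL
  res <- probeAssociation(m, phen, cov, qLevel = qLevel)
  if (!is.null(report)) {
    sig <- res$probe_id[res$significant]
    report@combinedSignificant <- intersect(report@replicated, sig)
    validObject(report)
  }
  list(result = res, report = report)
}
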