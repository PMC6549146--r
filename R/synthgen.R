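#' Simulate a 450k-style probe manifest
#'
#' Lays probes along a small set of autosomes (plus chrX for sex-chromosome
#' probes) with inter-probe spacing drawn uniformly between `minSpacing` and
#' `maxSpacing`, assigns Infinium design types and QC flags at the requested
#' fractions, and designates exactly ten bisulfite-conversion control probes
#' (six type I, four type II) as on the real array.
#'
#' @param nProbes number of probes (>= 20, so the ten controls can be placed
#'   among ordinary study probes).
#' @param fracTypeII fraction of type II probes.
#' @param fracSex fraction of probes on the sex chromosome.
#' @param fracCrossReactive fraction flagged as cross-reactive.
#' @param fracNearSnp fraction flagged as within 1 bp of a common SNP.
#' @param nChrom number of autosomes to spread probes over.
#' @param minSpacing,maxSpacing bounds (bp) on the gap between neighbouring
#'   probes on a chromosome.
#' @param seed RNG seed; a fixed seed gives an identical manifest.
#' @return `data.frame` with columns `probe_id`, `chrom`, `pos`,
#'   `design_type`, `is_sex_chrom`, `is_cross_reactive`,
#'   `is_bisulfite_control`, `near_snp`.
#' @export
#' @examples
#' man <- simulateManifest(500, seed = 1)
#' table(man$design_type)
simulateManifest <- function(nProbes, fracTypeII = 0.7, fracSex = 0.02,
                             fracCrossReactive = 0.01, fracNearSnp = 0.05,
                             nChrom = 4L, minSpacing = 2500, maxSpacing = 10000,
                             seed = NULL) {
  if (nProbes < 20)
    stop("nProbes must be >= 20 to place the 10 bisulfite controls ",
         "among ordinary study probes")
  withSeed(seed, {
    ids <- sprintf("cg%08d", seq_len(nProbes))
    nSex <- round(fracSex * nProbes)
    sexIdx <- if (nSex > 0) sample.int(nProbes, nSex) else integer()
    chrom <- sample(paste0("chr", seq_len(nChrom)), nProbes, replace = TRUE)
    chrom[sexIdx] <- "chrX"
    pos <- integer(nProbes)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      gaps <- round(stats::runif(length(i), minSpacing, maxSpacing))
      pos[i[order(i)]] <- as.integer(cumsum(gaps))
    }
    nII <- round(fracTypeII * nProbes)
    design <- rep("I", nProbes)
    design[sample.int(nProbes, nII)] <- "II"
    cross <- seq_len(nProbes) %in% sample.int(nProbes,
                                              round(fracCrossReactive * nProbes))
    snp <- seq_len(nProbes) %in% sample.int(nProbes,
                                            round(fracNearSnp * nProbes))
    # controls: clean autosomal probes, 6 type I + 4 type II
    clean <- !(seq_len(nProbes) %in% sexIdx) & !cross & !snp
    poolI <- which(clean & design == "I")
    poolII <- which(clean & design == "II")
    if (length(poolI) < 6 || length(poolII) < 4) {
      # force enough clean probes of each design type to host the controls
      need <- which(clean)
      if (length(need) < 10)
        stop("manifest too constrained to place the 10 bisulfite controls")
      design[need[1:6]] <- "I"
      design[need[7:10]] <- "II"
      poolI <- need[1:6]; poolII <- need[7:10]
    }
    ctrl <- c(sample(poolI, 6), sample(poolII, 4))
    data.frame(
      probe_id = ids, chrom = chrom, pos = pos, design_type = design,
      is_sex_chrom = seq_len(nProbes) %in% sexIdx,
      is_cross_reactive = cross,
      is_bisulfite_control = seq_len(nProbes) %in% ctrl,
      near_snp = snp, stringsAsFactors = FALSE)
  })
}

# clinical covariates drawn to mirror a nephrectomy DKD cohort: eGFR
# ~N(68, 26), age ~N(63, 11), 45% diabetic, 71% hypertensive, skewed
# fibrosis with mean ~12% and SD ~19%
.simulateSampleSheet <- function(nSamples, nBatches, missingFibrosis,
                                 idPrefix = "S") {
  fib <- pmin(stats::rgamma(nSamples, shape = 0.43, scale = 28.4), 100)
  data.frame(
    sample_id = sprintf("%s%03d", idPrefix, seq_len(nSamples)),
    age = round(pmax(stats::rnorm(nSamples, 63.5, 11.5), 20), 1),
    sex = sample(c("M", "F"), nSamples, replace = TRUE, prob = c(0.53, 0.47)),
    race = sample(c("asian", "caucasian", "african_american", "hispanic"),
                  nSamples, replace = TRUE, prob = c(0.05, 0.3, 0.45, 0.2)),
    diabetes = stats::rbinom(nSamples, 1, 0.45),
    hypertension = stats::rbinom(nSamples, 1, 0.71),
    batch = sample(paste0("slide", seq_len(nBatches)), nSamples,
                   replace = TRUE),
    bisulfite_efficiency = pmin(pmax(
      stats::rbeta(nSamples, 80, 2), 0.9), 0.999),
    lymphocytic_infiltrate = sample(0:3, nSamples, replace = TRUE,
                                    prob = c(0.4, 0.45, 0.1, 0.05)),
    fibrosis_pct = fib,
    baseline_egfr = round(pmax(stats::rnorm(nSamples, 68.2, 26), 8), 1),
    stringsAsFactors = FALSE)
}

#' Simulate a methylation cohort with planted fibrosis effects
#'
#' Generates a clinical sample sheet, a probes-by-samples beta/detection-p
#' matrix pair, and a ground-truth record. Probe baselines are drawn from a
#' bimodal two-component beta mixture with modes near 0.1 and 0.9; type II
#' probe baselines are attenuated toward 0.5 to emulate Infinium design bias.
#' Per-sample values are produced on the M scale as baseline + planted
#' fibrosis effect + batch effect + bisulfite-efficiency effect + Gaussian
#' noise, then mapped back to beta. Gap-signal probes are overwritten with
#' three well-separated genotype-like clusters (beta ~ 0.05 / 0.5 / 0.95);
#' bisulfite control probes track each sample's conversion efficiency.
#'
#' @param manifest probe manifest from [simulateManifest()].
#' @param nSamples cohort size (default 91, the primary-cohort size; use 85
#'   for a replication-style cohort).
#' @param fibrosisEffects `data.frame(probe_id, effect)` of causal probes;
#'   `effect` is in M-units per percent fibrosis. Effects on control probes
#'   are an error.
#' @param nGapProbes number of planted gap-signal probes (drawn from clean
#'   autosomal non-causal probes).
#' @param noiseSd per-entry Gaussian noise SD on the M scale.
#' @param batchSd SD of per-(probe, batch) M shifts.
#' @param bisulfiteSlope M-shift per unit of (conversion efficiency - 0.97),
#'   shared by all probes.
#' @param typeIIAttenuation shrinkage of type II baselines toward beta = 0.5
#'   (1 = no attenuation).
#' @param detectionFailRate fraction of matrix entries given a failing
#'   (> 0.01) detection p-value.
#' @param missingFibrosisFrac fraction of samples whose fibrosis score is
#'   masked to `NA` in the sample sheet (the latent value still drives the
#'   planted effects, as histology missingness is unrelated to methylation).
#' @param nBatches number of slide batches.
#' @param idPrefix prefix for generated sample ids; give distinct prefixes
#'   to cohorts meant to be disjoint (shared ids are treated as shared
#'   samples by the pooled-cohort analysis).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return list with elements `mset` (a [MethylSet-class]), `sampleSheet`,
#'   and `truth` (list: `fibrosis_effects`, `gap_probes`, `latent_fibrosis`,
#'   plus slots filled in by the trajectory/expression/state generators).
#' @export
#' @examples
#' man <- simulateManifest(300, seed = 2)
#' eff <- data.frame(probe_id = man$probe_id[1], effect = 0.03)
#' sim <- simulateCohort(man, nSamples = 40, fibrosisEffects = eff, seed = 2)
#' dim(betaValues(sim$mset))
simulateCohort <- function(manifest, nSamples = 91, fibrosisEffects = NULL,
                           nGapProbes = round(0.005 * nrow(manifest)),
                           noiseSd = 0.5, batchSd = 0.1, bisulfiteSlope = 2,
                           typeIIAttenuation = 0.7, detectionFailRate = 0.002,
                           missingFibrosisFrac = 0.08, nBatches = 3L,
                           idPrefix = "S", seed = NULL) {
  if (!is.null(fibrosisEffects)) {
    bad <- setdiff(fibrosisEffects$probe_id, manifest$probe_id)
    if (length(bad))
      stop("fibrosisEffects names probes absent from the manifest: ",
           paste(utils::head(bad, 3), collapse = ", "))
    ctrl <- manifest$probe_id[manifest$is_bisulfite_control]
    if (any(fibrosisEffects$probe_id %in% ctrl))
      stop("effects cannot be planted on bisulfite control probes")
  }
  withSeed(seed, {
    nP <- nrow(manifest)
    sheet <- .simulateSampleSheet(nSamples, nBatches, missingFibrosisFrac,
                                  idPrefix)
    latentFib <- sheet$fibrosis_pct
    nMiss <- round(missingFibrosisFrac * nSamples)
    if (nMiss > 0)
      sheet$fibrosis_pct[sample.int(nSamples, nMiss)] <- NA_real_

    # probe baseline betas: bimodal mixture, modes near 0.1 and 0.9
    comp <- stats::rbinom(nP, 1, 0.5)
    b0 <- ifelse(comp == 1, stats::rbeta(nP, 9, 81), stats::rbeta(nP, 81, 9))
    isII <- manifest$design_type == "II"
    b0[isII] <- 0.5 + typeIIAttenuation * (b0[isII] - 0.5)
    m0 <- betaToM(b0)

    eff <- numeric(nP)
    names(m0) <- manifest$probe_id
    if (!is.null(fibrosisEffects))
      eff[match(fibrosisEffects$probe_id, manifest$probe_id)] <-
        fibrosisEffects$effect

    batchShift <- matrix(stats::rnorm(nP * nBatches, 0, batchSd), nP,
                         dimnames = list(NULL, paste0("slide",
                                                      seq_len(nBatches))))
    M <- m0 + outer(eff, latentFib) +
      batchShift[, sheet$batch, drop = FALSE] +
      rep(bisulfiteSlope * (sheet$bisulfite_efficiency - 0.97),
          each = nP) +
      matrix(stats::rnorm(nP * nSamples, 0, noiseSd), nP)
    beta <- mToBeta(M)

    # planted gap-signal probes: three genotype-like clusters
    gapPool <- manifest$probe_id[!manifest$is_bisulfite_control &
                                   !manifest$is_sex_chrom &
                                   eff == 0]
    gapIds <- if (nGapProbes > 0) sample(gapPool, min(nGapProbes,
                                                      length(gapPool)))
              else character()
    for (g in match(gapIds, manifest$probe_id)) {
      geno <- sample(c(0.05, 0.5, 0.95), nSamples, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25))
      beta[g, ] <- pmin(pmax(geno + stats::rnorm(nSamples, 0, 0.01), 0), 1)
    }

    # control probes read out conversion efficiency directly
    ctrlIdx <- which(manifest$is_bisulfite_control)
    for (g in ctrlIdx)
      beta[g, ] <- pmin(pmax(sheet$bisulfite_efficiency +
                               stats::rnorm(nSamples, 0, 0.004), 0), 1)

    detp <- matrix(stats::runif(nP * nSamples, 0, 0.009), nP)
    nFail <- round(detectionFailRate * length(detp))
    if (nFail > 0)
      detp[sample.int(length(detp), nFail)] <- stats::runif(nFail, 0.011, 0.8)

    dimnames(beta) <- dimnames(detp) <- list(manifest$probe_id,
                                             sheet$sample_id)
    mset <- MethylSet(beta, detp, manifest, sheet)
    truth <- list(
      fibrosis_effects = if (is.null(fibrosisEffects))
        data.frame(probe_id = character(), effect = numeric())
      else fibrosisEffects,
      gap_probes = gapIds,
      latent_fibrosis = stats::setNames(latentFib, sheet$sample_id))
    list(mset = mset, sampleSheet = sheet, truth = truth)
  })
}

#' Simulate longitudinal eGFR trajectories
#'
#' Each subject receives a true slope
#' \deqn{s_i = \gamma_0 + \gamma_1 eGFR_i + \gamma_2 DM_i + \gamma_3 age_i +
#'   \sum_k \delta_k M_{ki} + u_i,\qquad u_i \sim N(0, \sigma_s^2)}
#' so that low baseline eGFR, diabetes and age drive faster decline, with
#' optional planted methylation-probe effects (`slopeEffects`, in
#' ml/min/1.73m2/yr per M-unit). Observed values are
#' `baseline + slope * t + visit noise`, at per-subject visit times drawn
#' uniformly over a random follow-up span with a minimum gap of 0.05 yr.
#'
#' @param sampleSheet sample sheet from [simulateCohort()].
#' @param mMatrix probes-by-samples M-value matrix (only needed when
#'   `slopeEffects` is non-empty).
#' @param slopeEffects `data.frame(probe_id, effect)` or `NULL`.
#' @param nSubjects number of subjects followed longitudinally (default 69);
#'   drawn at random from the sheet.
#' @param gammas named vector of fixed coefficients: `intercept`,
#'   `baseline_egfr`, `diabetes`, `age`.
#' @param subjectSd SD of the subject-level slope deviation (ml/min/yr).
#' @param visitNoiseSd SD of per-visit eGFR measurement noise (creatinine-
#'   based eGFR is noisy; 5 ml/min is typical lab-to-lab variation).
#' @param visitRange integer range of visit counts per subject; the default
#'   8--20 reflects clinical creatinine series, which typically hold several
#'   laboratory draws per follow-up year.
#' @param spanRange follow-up span range in years.
#' @param seed RNG seed.
#' @return list with `egfr` (`data.frame(subject_id, time_years, egfr)`) and
#'   `truth` (true slopes, coefficients, planted probe effects).
#' @export
simulateTrajectories <- function(sampleSheet, mMatrix = NULL,
                                 slopeEffects = NULL, nSubjects = 69,
                                 gammas = c(intercept = 3, baseline_egfr = 0.07,
                                            diabetes = -4, age = -0.18),
                                 subjectSd = 0.8, visitNoiseSd = 5,
                                 visitRange = c(8L, 20L),
                                 spanRange = c(1.5, 5),
                                 minGap = 0.05, seed = NULL) {
  nSubjects <- min(nSubjects, nrow(sampleSheet))
  withSeed(seed, {
    keep <- sort(sample.int(nrow(sampleSheet), nSubjects))
    sub <- sampleSheet[keep, , drop = FALSE]
    slope <- gammas[["intercept"]] +
      gammas[["baseline_egfr"]] * sub$baseline_egfr +
      gammas[["diabetes"]] * sub$diabetes +
      gammas[["age"]] * sub$age +
      stats::rnorm(nSubjects, 0, subjectSd)
    if (!is.null(slopeEffects) && nrow(slopeEffects)) {
      if (is.null(mMatrix))
        stop("mMatrix is required when slopeEffects are planted")
      miss <- setdiff(slopeEffects$probe_id, rownames(mMatrix))
      if (length(miss))
        stop("slopeEffects names probes absent from mMatrix: ",
             paste(utils::head(miss, 3), collapse = ", "))
      Msub <- mMatrix[slopeEffects$probe_id, sub$sample_id, drop = FALSE]
      slope <- slope + drop(crossprod(Msub, slopeEffects$effect))
    }
    recs <- lapply(seq_len(nSubjects), function(i) {
      k <- sample(seq(visitRange[1], visitRange[2]), 1)
      span <- stats::runif(1, spanRange[1], spanRange[2])
      for (try in 1:50) {
        tt <- c(0, sort(stats::runif(k - 1, minGap, span)))
        if (all(diff(tt) >= minGap)) break
      }
      if (any(diff(tt) < minGap))
        tt <- seq(0, span, length.out = k)
      e <- sub$baseline_egfr[i] + slope[i] * tt +
        stats::rnorm(k, 0, visitNoiseSd)
      data.frame(subject_id = sub$sample_id[i], time_years = tt,
                 egfr = pmax(e, 1), stringsAsFactors = FALSE)
    })
    list(
      egfr = do.call(rbind, recs),
      truth = list(
        true_slopes = stats::setNames(slope, sub$sample_id),
        gammas = gammas,
        slope_effects = if (is.null(slopeEffects))
          data.frame(probe_id = character(), effect = numeric())
        else slopeEffects))
  })
}

#' Simulate cis-linked gene expression
#'
#' Builds a TSS table anchored on manifest probe positions and a
#' genes-by-samples expression matrix. Each requested cis link places a gene
#' TSS at `probe pos + distance` (|distance| must be within the 500 kb cis
#' window, so the planted truth is discoverable) and generates expression
#' with the requested correlation to the probe's M-values; unlinked genes
#' are independent standard-normal noise at random probe-anchored positions.
#'
#' @param mMatrix probes-by-samples M-value matrix.
#' @param manifest probe manifest.
#' @param cisLinks `data.frame(probe_id, gene_id, distance, r)`; `distance`
#'   in bp (signed), `r` the target Pearson correlation.
#' @param nNullGenes number of unlinked background genes.
#' @param window cis window (bp) that links must respect.
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples matrix), `tss`
#'   (`data.frame(gene_id, chrom, tss_pos, strand)`) and `truth`
#'   (the realized link table).
#' @export
simulateExpression <- function(mMatrix, manifest, cisLinks = NULL,
                               nNullGenes = 50, window = 5e5, seed = NULL) {
  if (!is.null(cisLinks)) {
    if (any(abs(cisLinks$distance) > window))
      stop("cis link distance exceeds the ", window,
           " bp window; planted truth would not be discoverable")
    miss <- setdiff(cisLinks$probe_id, rownames(mMatrix))
    if (length(miss))
      stop("cisLinks names probes absent from mMatrix: ",
           paste(utils::head(miss, 3), collapse = ", "))
  }
  withSeed(seed, {
    nS <- ncol(mMatrix)
    linked <- if (is.null(cisLinks)) 0L else nrow(cisLinks)
    genes <- character(0); chrom <- character(0); tss <- integer(0)
    rows <- list()
    if (linked) {
      mi <- match(cisLinks$probe_id, manifest$probe_id)
      genes <- cisLinks$gene_id
      chrom <- manifest$chrom[mi]
      tss <- manifest$pos[mi] + cisLinks$distance
      for (k in seq_len(linked)) {
        z <- scale(mMatrix[cisLinks$probe_id[k], ])[, 1]
        r <- cisLinks$r[k]
        rows[[k]] <- r * z + sqrt(1 - r^2) * stats::rnorm(nS)
      }
    }
    if (nNullGenes > 0) {
      anchor <- sample.int(nrow(manifest), nNullGenes, replace = TRUE)
      genes <- c(genes, sprintf("gene_null%04d", seq_len(nNullGenes)))
      chrom <- c(chrom, manifest$chrom[anchor])
      tss <- c(tss, manifest$pos[anchor] +
                 round(stats::runif(nNullGenes, -window, window)))
      for (k in seq_len(nNullGenes))
        rows[[linked + k]] <- stats::rnorm(nS)
    }
    expr <- do.call(rbind, rows)
    dimnames(expr) <- list(genes, colnames(mMatrix))
    tssTab <- data.frame(gene_id = genes, chrom = chrom,
                         tss_pos = pmax(as.integer(tss), 1L),
                         strand = sample(c("+", "-"), length(genes),
                                         replace = TRUE),
                         stringsAsFactors = FALSE)
    list(expr = expr, tss = tssTab,
         truth = list(cis_links = if (is.null(cisLinks))
           data.frame(probe_id = character(), gene_id = character(),
                      distance = numeric(), r = numeric())
           else cisLinks))
  })
}

#' Simulate tissue chromatin-state maps with planted enhancer enrichment
#'
#' For each tissue, every probe's 1 kb neighbourhood is assigned a state:
#' enhancer with probability `enhancerCoverage` (times `factor` for causal
#' probes in the kidney map, emulating preferential localization of
#' disease-associated probes to kidney enhancers), otherwise promoter or
#' transcribed at their coverages, otherwise inactive (no interval emitted;
#' unannotated positions default to inactive). Because manifest probes are
#' spaced further apart than the interval width, intervals never overlap.
#'
#' @param manifest probe manifest.
#' @param tissues character vector of tissue labels; the first is treated as
#'   kidney (the enriched tissue).
#' @param causalProbes probe ids preferentially placed in kidney enhancers.
#' @param enhancerCoverage baseline probability that a probe lies in an
#'   enhancer.
#' @param promoterCoverage,transcribedCoverage analogous baseline coverages.
#' @param factor multiplier on `enhancerCoverage` for causal probes in the
#'   kidney map. `enhancerCoverage * factor` must not exceed 1.
#' @param width interval width in bp (must stay below the manifest's minimum
#'   probe spacing).
#' @param seed RNG seed.
#' @return [GenomicRanges::GRanges] with metadata columns `state` and
#'   `tissue`.
#' @export
simulateChromStates <- function(manifest,
                                tissues = c("kidney", "liver", "lung", "pmn"),
                                causalProbes = character(),
                                enhancerCoverage = 0.05,
                                promoterCoverage = 0.03,
                                transcribedCoverage = 0.1,
                                factor = 3, width = 1000, seed = NULL) {
  if (enhancerCoverage * factor > 1)
    stop("enhancerCoverage * factor exceeds 1; causal placement ",
         "probability is not a probability")
  withSeed(seed, {
    out <- list()
    for (ti in seq_along(tissues)) {
      tissue <- tissues[ti]
      pEnh <- rep(enhancerCoverage, nrow(manifest))
      if (ti == 1L)
        pEnh[manifest$probe_id %in% causalProbes] <- enhancerCoverage * factor
      u <- stats::runif(nrow(manifest))
      state <- rep(NA_character_, nrow(manifest))
      state[u < pEnh] <- "enhancer"
      rest <- is.na(state)
      state[rest & u >= pEnh &
              u < pEnh + promoterCoverage] <- "promoter"
      rest <- is.na(state)
      state[rest & u < pEnh + promoterCoverage +
              transcribedCoverage] <- "transcribed"
      keep <- which(!is.na(state))
      if (length(keep))
        out[[tissue]] <- GenomicRanges::GRanges(
          seqnames = manifest$chrom[keep],
          ranges = IRanges::IRanges(
            start = pmax(manifest$pos[keep] - width %/% 2, 1L),
            width = width),
          state = state[keep], tissue = tissue)
    }
    unname(do.call(c, unname(out)))
  })
}
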