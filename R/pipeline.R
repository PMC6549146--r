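#' Pipeline configuration
#'
#' Collects every threshold and mode flag of the end-to-end analysis with
#' the documented defaults: detection p 0.01 (probe removed when > 5% of
#' samples fail), gap threshold 0.05, discovery and replication q/alpha
#' 0.05, slope filters (3 observations, 0.25 yr span, |slope| <= 40),
#' 500 kb cis window, eQTM cutoff 8e-5, 10,000 enrichment draws. Values
#' outside their documented ranges are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `PipelineConfig` list.
#' @export
#' @examples
#' cfg <- pipelineConfig(qLevel = 0.1, seed = 7)
#' cfg$qLevel
pipelineConfig <- function(...) {
  cfg <- list(
    detectionThreshold = 0.01, detectionFraction = 0.05,
    gapThreshold = 0.05, gapOutlierMin = 3L, pcaKSd = 4,
    qLevel = 0.05, replicationAlpha = 0.05,
    minObs = 3L, minSpanYears = 0.25, slopeBound = 40,
    cisWindow = 5e5, eqtmCutoff = 8e-5, eqtmPermutations = 1000L,
    nDraws = 10000L,
    covariates = c("age", "sex", "race", "diabetes", "hypertension",
                   "batch", "bisulfite_efficiency",
                   "lymphocytic_infiltrate"),
    bloodCovariates = c("age", "sex", "diabetes_duration",
                        "mean_blood_pressure", "hba1c", "batch",
                        "bisulfite_efficiency", "cell_type_pc1"),
    forceHypertension = FALSE, bloodMode = FALSE, dedupCombined = TRUE,
    seed = 1L, outputDir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$detectionThreshold > 0, cfg$detectionThreshold < 1,
            cfg$gapThreshold > 0, cfg$gapThreshold < 1,
            cfg$qLevel >= 0, cfg$qLevel <= 1,
            cfg$replicationAlpha > 0, cfg$replicationAlpha <= 1,
            cfg$minObs >= 2, cfg$slopeBound > 0, cfg$cisWindow > 0,
            cfg$nDraws >= 100)
  structure(cfg, class = "PipelineConfig")
}

.stageLog <- function(report, stage, ...) {
  entry <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(entry), unlist(entry), sep = "=",
                        collapse = " ")))
  report[[stage]] <- entry
  report
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Generates a primary and a replication cohort, runs quality control and
#' BMIQ normalization, the fibrosis EWAS with directional replication and
#' the pooled-cohort pass, BLUP-adjusted slopes with the weighted
#' progression model and probe augmentation, chromatin-state enrichment and
#' cis eQTM mapping. Every stage is seeded from `config$seed`, so a rerun
#' with the same configuration reproduces the outputs byte for byte. When
#' `config$outputDir` is set, stage tables are written there as TSV/CSV.
#'
#' This driver exists for fixture-scale, fully synthetic runs; on real data
#' the stage functions are called individually with cohort-specific
#' covariate sets.
#'
#' @param config a [pipelineConfig()].
#' @param nProbes,nPrimary,nReplication,nSubjects problem sizes.
#' @param nCausal number of planted fibrosis probes; effect 0.03 M-units
#'   per percent fibrosis.
#' @param normalize apply BMIQ (slower; defaults off at fixture scale).
#' @return list of stage outputs plus a `report` with per-stage counts,
#'   parameters and the seed registry.
#' @export
runPipeline <- function(config = pipelineConfig(), nProbes = 1000L,
                        nPrimary = 91L, nReplication = 85L, nSubjects = 69L,
                        nCausal = 10L, normalize = FALSE) {
  seed <- config$seed
  report <- list()
  t0 <- Sys.time()

  # synth
  manifest <- simulateManifest(nProbes, seed = subSeed(seed, 1))
  pool <- manifest$probe_id[!manifest$is_bisulfite_control &
                              !manifest$is_sex_chrom &
                              !manifest$is_cross_reactive]
  causal <- withSeed(subSeed(seed, 2), sample(pool, nCausal))
  eff <- data.frame(probe_id = causal,
                    effect = rep(c(0.03, -0.03), length.out = nCausal))
  prim <- simulateCohort(manifest, nPrimary, fibrosisEffects = eff,
                         seed = subSeed(seed, 3))
  repl <- simulateCohort(manifest, nReplication, fibrosisEffects = eff,
                         seed = subSeed(seed, 4))
  report <- .stageLog(report, "synth", probes = nProbes,
                      primary = nPrimary, replication = nReplication,
                      causal = nCausal, seed = seed)

  # qc + normalization
  runOne <- function(sim) {
    qc <- runQc(sim$mset, config$detectionThreshold,
                config$detectionFraction,
                mode = if (config$bloodMode) "blood" else "kidney",
                gapThreshold = config$gapThreshold,
                outlierMin = config$gapOutlierMin, kSd = config$pcaKSd)
    mset <- if (normalize) bmiqNormalize(qc$mset) else qc$mset
    list(mset = mset, m = betaToM(betaValues(mset)), report = qc$report)
  }
  qcP <- runOne(prim); qcR <- runOne(repl)
  report <- .stageLog(report, "qc",
                      primary_probes = nrow(qcP$m),
                      replication_probes = nrow(qcR$m),
                      primary_samples = ncol(qcP$m),
                      replication_samples = ncol(qcR$m))

  # ewas + replication + combined
  covs <- function(qc) sampleSheet(qc$mset)[, config$covariates,
                                            drop = FALSE]
  phen <- function(qc) sampleSheet(qc$mset)$fibrosis_pct
  ewasP <- probeAssociation(qcP$m, phen(qcP), covs(qcP),
                            qLevel = config$qLevel)
  ewasR <- probeAssociation(qcR$m, phen(qcR), covs(qcR),
                            qLevel = config$qLevel)
  repReport <- replicateProbes(ewasP, ewasR, alpha = config$replicationAlpha,
                               qLevel = config$qLevel)
  comb <- combinedAssociation(qcP$m, qcR$m, phen(qcP), phen(qcR),
                              covs(qcP), covs(qcR), report = repReport,
                              qLevel = config$qLevel,
                              dedup = config$dedupCombined)
  repReport <- comb$report
  report <- .stageLog(report, "ewas",
                      primary_significant =
                        length(repReport@primarySignificant),
                      replicated = length(repReport@replicated),
                      combined = length(repReport@combinedSignificant))

  # slopes + progression
  traj <- simulateTrajectories(qcP$mset |> sampleSheet(), qcP$m,
                               nSubjects = nSubjects,
                               seed = subSeed(seed, 5))
  est <- filterSubjects(unadjustedSlopes(traj$egfr), config$minObs,
                        config$minSpanYears, config$slopeBound)
  included <- est$subject_id[est$included]
  blup <- blupAdjust(traj$egfr[traj$egfr$subject_id %in% included, ])
  sheet <- sampleSheet(qcP$mset)
  idx <- match(blup$subject_id, sheet$sample_id)
  cand <- data.frame(baseline_egfr = sheet$baseline_egfr[idx],
                     diabetes = sheet$diabetes[idx],
                     age = sheet$age[idx],
                     hypertension = sheet$hypertension[idx],
                     lymphocytic_infiltrate =
                       sheet$lymphocytic_infiltrate[idx])
  built <- buildProgressionModel(cand, blup$adjusted_slope, blup$weight,
                                 seed = subSeed(seed, 6),
                                 force = if (config$forceHypertension)
                                   "hypertension" else character())
  extra <- data.frame(batch = sheet$batch[idx],
                      bisulfite_efficiency =
                        sheet$bisulfite_efficiency[idx])
  aug <- featureAugmentation(built$model,
                             qcP$m[, blup$subject_id, drop = FALSE],
                             extraCovariates = extra,
                             qLevel = config$qLevel, onCollinear = "skip")
  report <- .stageLog(report, "progression",
                      subjects = length(included),
                      selected = paste(built$selected, collapse = "+"),
                      improving = sum(aug$improves))

  # regulatory enrichment
  sig <- repReport@replicated
  if (!length(sig)) sig <- utils::head(ewasP$probe_id[order(ewasP$p)], 0)
  states <- simulateChromStates(manifest, causalProbes = causal,
                                seed = subSeed(seed, 7))
  tissues <- unique(states$tissue)
  anns <- lapply(stats::setNames(tissues, tissues), function(ti)
    annotateProbes(manifest, states, ti))
  background <- ewasP$probe_id
  enr <- if (length(sig))
    fisherEnrichment(sig, background, anns[[1]], "enhancer")
  else NULL
  fold <- if (length(sig))
    resampleFoldChange(sig, background, anns, nDraws = config$nDraws,
                       seed = subSeed(seed, 8))
  else NULL
  report <- .stageLog(report, "regulatory",
                      significant = length(sig),
                      odds_ratio = if (is.null(enr)) NA else
                        round(enr$odds_ratio, 3))

  # eqtm
  sigMan <- manifest[manifest$probe_id %in%
                       (if (length(sig)) sig else character()), ,
                     drop = FALSE]
  eqtm <- NULL
  if (nrow(sigMan)) {
    links <- data.frame(probe_id = sigMan$probe_id,
                        gene_id = paste0("gene_", sigMan$probe_id),
                        distance = 10000, r = -0.6)
    exprSim <- simulateExpression(qcP$m, manifest, links,
                                  seed = subSeed(seed, 9))
    pairs <- cisPairs(sigMan, exprSim$tss, window = config$cisWindow)
    if (nrow(pairs))
      eqtm <- permutationSignificance(pairs, qcP$m, exprSim$expr,
                                      nPerm = config$eqtmPermutations,
                                      cutoff = config$eqtmCutoff,
                                      seed = subSeed(seed, 10))
  }
  report <- .stageLog(report, "eqtm",
                      pairs = if (is.null(eqtm)) 0L else nrow(eqtm),
                      significant = if (is.null(eqtm)) 0L else
                        sum(eqtm$significant))

  report$wall_time_sec <- as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))
  report$parameters <- unclass(config)

  out <- list(manifest = manifest, primary = qcP, replication = qcR,
              ewas_primary = ewasP, ewas_replication = ewasR,
              ewas_combined = comb$result, replication_report = repReport,
              slopes = est, blup = blup, progression = built,
              augmentation = aug, enrichment = enr, fold_change = fold,
              eqtm = eqtm, truth = list(primary = prim$truth,
                                        trajectories = traj$truth),
              report = report)
  if (!is.null(config$outputDir)) .writePipelineOutputs(out, config)
  out
}

.writePipelineOutputs <- function(out, config) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outputDir, f)
  writeManifest(out$manifest, p("manifest.csv"))
  writeResultsTsv(out$ewas_primary, p("ewas_primary.tsv"))
  writeResultsTsv(out$ewas_replication, p("ewas_replication.tsv"))
  writeResultsTsv(out$ewas_combined, p("ewas_combined.tsv"))
  writeResultsTsv(out$slopes, p("slopes.tsv"))
  writeResultsTsv(out$blup, p("blup.tsv"))
  writeResultsTsv(out$augmentation, p("augmentation.tsv"))
  if (!is.null(out$enrichment))
    writeResultsTsv(out$enrichment, p("enrichment.tsv"))
  if (!is.null(out$eqtm)) writeResultsTsv(out$eqtm, p("eqtm.tsv"))
  jsonlite::write_json(
    list(stages = out$report[setdiff(names(out$report),
                                     c("parameters"))],
         parameters = out$report$parameters),
    p("run_report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$outputDir)
}
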