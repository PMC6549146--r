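test_that("manifest generation is seeded, respects fractions and controls", {
  m1 <- simulateManifest(1000, seed = 1)
  m2 <- simulateManifest(1000, seed = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1, simulateManifest(1000, seed = 2)))

  expect_equal(sum(m1$is_sex_chrom), 20)  # 0.02 * 1000
  expect_equal(sum(m1$design_type == "II"), 700)
  expect_equal(sum(m1$is_bisulfite_control), 10)
  ctrl <- m1[m1$is_bisulfite_control, ]
  expect_equal(sum(ctrl$design_type == "I"), 6)
  expect_equal(sum(ctrl$design_type == "II"), 4)
  expect_false(anyDuplicated(m1$probe_id) > 0)
  expect_true(all(m1$pos >= 1))

  m3 <- simulateManifest(1000, fracSex = 0.05, seed = 1)
  expect_equal(sum(m3$is_sex_chrom), 50)
  expect_error(simulateManifest(15), "10 bisulfite controls")
})

test_that("cohort generation is deterministic and structurally sound", {
  man <- simulateManifest(300, seed = 3)
  s1 <- simulateCohort(man, nSamples = 30, seed = 4)
  s2 <- simulateCohort(man, nSamples = 30, seed = 4)
  expect_identical(betaValues(s1$mset), betaValues(s2$mset))
  expect_identical(s1$sampleSheet, s2$sampleSheet)

  b <- betaValues(s1$mset)
  dp <- detectionP(s1$mset)
  expect_identical(dim(b), dim(dp))
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(s1$sampleSheet$fibrosis_pct >= 0 &
                    s1$sampleSheet$fibrosis_pct <= 100, na.rm = TRUE))
  # detection p mostly passing
  expect_lt(mean(dp > 0.01), 0.01)
  # effects on control probes are rejected
  ctrl <- man$probe_id[man$is_bisulfite_control][1]
  expect_error(
    simulateCohort(man, 30, fibrosisEffects = data.frame(probe_id = ctrl,
                                                         effect = 0.03)),
    "control")
  expect_error(
    simulateCohort(man, 30,
                   fibrosisEffects = data.frame(probe_id = "cg_missing",
                                                effect = 0.03)),
    "absent")
})

test_that("planted fibrosis effect yields a strong signed partial signal", {
  fx <- makeEwasFixture(nProbes = 300, nSamples = 90, nCausal = 2,
                        effect = 0.03, seed = 21, missingFibrosisFrac = 0)
  fib <- fx$sheet$fibrosis_pct
  for (k in seq_len(2)) {
    r <- cor(fx$m[fx$causal[k], ], fib)
    expect_gt(abs(r), 0.4)
    expect_equal(sign(r), sign(fx$eff$effect[k]))
  }
})

test_that("with no planted effects probe-fibrosis p-values are calibrated", {
  fx <- makeEwasFixture(nProbes = 2000, nSamples = 90, nCausal = 0,
                        seed = 31, missingFibrosisFrac = 0)
  fib <- fx$sheet$fibrosis_pct
  p <- apply(fx$m, 1, function(x) cor.test(x, fib)$p.value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("noiseless planted effects are recovered exactly by per-probe OLS", {
  man <- simulateManifest(100, seed = 5)
  causal <- cleanProbes(man)[1:3]
  eff <- data.frame(probe_id = causal, effect = c(0.03, -0.02, 0.01))
  sim <- simulateCohort(man, nSamples = 40, fibrosisEffects = eff,
                        noiseSd = 0, batchSd = 0, bisulfiteSlope = 0,
                        nGapProbes = 0, missingFibrosisFrac = 0, seed = 6)
  m <- betaToM(betaValues(sim$mset))
  fib <- sim$sampleSheet$fibrosis_pct
  for (k in 1:3) {
    slope <- cov(m[causal[k], ], fib) / var(fib)
    expect_equal(slope, eff$effect[k], tolerance = 1e-10)
  }
})

test_that("trajectory generator plants slope structure and is seeded", {
  man <- simulateManifest(100, seed = 7)
  sim <- simulateCohort(man, nSamples = 80, nGapProbes = 0, seed = 8)
  m <- betaToM(betaValues(sim$mset))
  t1 <- simulateTrajectories(sim$sampleSheet, m, nSubjects = 69, seed = 9)
  t2 <- simulateTrajectories(sim$sampleSheet, m, nSubjects = 69, seed = 9)
  expect_identical(t1$egfr, t2$egfr)

  # per-subject times strictly increasing, egfr positive
  by <- split(t1$egfr, t1$egfr$subject_id)
  expect_true(all(vapply(by, function(d) all(diff(d$time_years) > 0), TRUE)))
  expect_true(all(t1$egfr$egfr > 0))

  # planted positive baseline-eGFR coefficient shows up in fitted slopes
  est <- unadjustedSlopes(t1$egfr)
  idx <- match(est$subject_id, sim$sampleSheet$sample_id)
  expect_gt(cor(sim$sampleSheet$baseline_egfr[idx], est$unadjusted_slope),
            0)

  # noiseless limit: OLS slope equals the true slope exactly (away from the
  # eGFR positivity floor, which kinks trajectories that would cross zero)
  t0 <- simulateTrajectories(sim$sampleSheet, m, nSubjects = 20,
                             visitNoiseSd = 0, seed = 10)
  est0 <- unadjustedSlopes(t0$egfr)
  floored <- tapply(t0$egfr$egfr, t0$egfr$subject_id, min)[est0$subject_id]
  off <- floored > 1.5
  expect_gt(sum(off), 10)
  truth <- t0$truth$true_slopes[est0$subject_id]
  expect_equal(est0$unadjusted_slope[off], unname(truth)[off],
               tolerance = 1e-8)
})

test_that("expression generator hits requested cis correlations", {
  man <- simulateManifest(200, seed = 12)
  sim <- simulateCohort(man, nSamples = 60, nGapProbes = 0, seed = 13)
  m <- betaToM(betaValues(sim$mset))
  probes <- cleanProbes(man)[1:3]
  links <- data.frame(probe_id = probes,
                      gene_id = paste0("g", 1:3),
                      distance = c(1e4, -2e5, 4e5), r = c(-0.6, 0.5, -0.4))
  ex <- simulateExpression(m, man, links, nNullGenes = 10, seed = 14)
  for (k in 1:3) {
    r <- cor(m[probes[k], ], ex$expr[links$gene_id[k], ])
    expect_lt(abs(r - links$r[k]), 0.15)
  }
  # link beyond the window is rejected
  badLinks <- data.frame(probe_id = probes[1], gene_id = "g9",
                         distance = 6e5, r = 0.5)
  expect_error(simulateExpression(m, man, badLinks, seed = 1), "window")
  # determinism
  ex2 <- simulateExpression(m, man, links, nNullGenes = 10, seed = 14)
  expect_identical(ex$expr, ex2$expr)
  # null genes do not correlate beyond chance
  exNull <- simulateExpression(m, man, NULL, nNullGenes = 200, seed = 15)
  rNull <- cor(t(exNull$expr), m[probes[1], ])
  expect_lt(max(abs(rNull)), 0.55)
})

test_that("chromatin-state generator plants kidney-enhancer enrichment", {
  man <- simulateManifest(4000, seed = 16)
  causal <- sample(cleanProbes(man), 200)
  st <- simulateChromStates(man, causalProbes = causal,
                            enhancerCoverage = 0.05, factor = 3, seed = 17)
  ann <- suppressWarnings(annotateProbes(man, st, "kidney"))
  rateCausal <- mean(ann[causal] == "enhancer")
  rateBg <- mean(ann[setdiff(names(ann), causal)] == "enhancer")
  expect_lt(abs(rateCausal - 0.15), 0.05)
  expect_lt(abs(rateBg - 0.05), 0.02)
  # non-kidney tissues are unenriched
  annLiver <- suppressWarnings(annotateProbes(man, st, "liver"))
  expect_lt(abs(mean(annLiver[causal] == "enhancer") - 0.05), 0.04)
  # intervals never overlap within a tissue
  for (ti in unique(st$tissue)) {
    sub <- st[st$tissue == ti]
    expect_equal(sum(GenomicRanges::countOverlaps(sub, sub) > 1), 0)
  }
  # factor = 1 is the null
  st1 <- simulateChromStates(man, causalProbes = causal, factor = 1,
                             seed = 18)
  ann1 <- suppressWarnings(annotateProbes(man, st1, "kidney"))
  expect_lt(abs(mean(ann1[causal] == "enhancer") -
                  mean(ann1 == "enhancer")), 0.04)
  expect_error(simulateChromStates(man, enhancerCoverage = 0.6, factor = 2),
               "exceed")
})
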