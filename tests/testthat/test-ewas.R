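test_that("probeAssociation matches an independent normal-equations oracle", {
  fx <- makeEwasFixture(nProbes = 60, nSamples = 50, nCausal = 2, seed = 61,
                        missingFibrosisFrac = 0)
  covs <- fx$sheet[, c("age", "sex", "diabetes")]
  res <- probeAssociation(fx$m, fx$sheet$fibrosis_pct, covs)
  X <- model.matrix(~ fib + age + sex + diabetes,
                    data = cbind(fib = fx$sheet$fibrosis_pct, covs))
  for (k in sample(nrow(fx$m), 20)) {
    beta <- olsOracle(fx$m[k, ], X)
    expect_equal(res$b[k], beta[2, 1], tolerance = 1e-8)
  }
})

test_that("planted effects are detected with the right sign and size", {
  fx <- makeEwasFixture(nProbes = 400, nSamples = 90, nCausal = 2,
                        effect = 0.03, seed = 62)
  covs <- fx$sheet[, fullCovariates]
  res <- probeAssociation(fx$m, fx$sheet$fibrosis_pct, covs)
  hit <- res[match(fx$causal, res$probe_id), ]
  expect_true(all(hit$p < 1e-4))
  expect_true(hit$b[1] > 0.01 && hit$b[1] < 0.05)
  expect_true(hit$b[2] > -0.05 && hit$b[2] < -0.01)
  expect_equal(hit$direction, c(1, -1))
  # listwise deletion of samples missing fibrosis
  expect_equal(unique(res$n_used), sum(!is.na(fx$sheet$fibrosis_pct)))
  # q >= p always
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("permuted phenotype gives uniform p-values", {
  fx <- makeEwasFixture(nProbes = 2000, nSamples = 90, nCausal = 0,
                        seed = 63, missingFibrosisFrac = 0)
  set.seed(64)
  phenPerm <- sample(fx$sheet$fibrosis_pct)
  res <- probeAssociation(fx$m, phenPerm,
                          fx$sheet[, c("age", "sex", "batch")])
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("without covariates the p-value equals the correlation test", {
  fx <- makeEwasFixture(nProbes = 30, nSamples = 40, nCausal = 0, seed = 65,
                        missingFibrosisFrac = 0)
  res <- probeAssociation(fx$m, fx$sheet$fibrosis_pct, NULL)
  for (k in 1:5) {
    ct <- cor.test(fx$m[k, ], fx$sheet$fibrosis_pct)
    expect_equal(res$p[k], ct$p.value, tolerance = 1e-10)
    expect_equal(res$r[k], unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("collinear designs fail loudly with the aliased column named", {
  fx <- makeEwasFixture(nProbes = 20, nSamples = 30, nCausal = 0, seed = 66,
                        missingFibrosisFrac = 0)
  covs <- data.frame(age = fx$sheet$age, age2 = fx$sheet$age * 2)
  expect_error(probeAssociation(fx$m, fx$sheet$fibrosis_pct, covs),
               "age2")
})

test_that("masked entries fall back to per-probe complete-case fits", {
  fx <- makeEwasFixture(nProbes = 40, nSamples = 50, nCausal = 1,
                        seed = 67, missingFibrosisFrac = 0)
  m <- fx$m
  m[3, 1:4] <- NA
  res <- probeAssociation(m, fx$sheet$fibrosis_pct,
                          fx$sheet[, c("age", "sex")])
  expect_equal(res$n_used[3], 46)
  ok <- !is.na(m[3, ])
  X <- model.matrix(~ fib + age + sex,
                    data = cbind(fib = fx$sheet$fibrosis_pct,
                                 fx$sheet[, c("age", "sex")]))[ok, ]
  expect_equal(res$b[3], olsOracle(m[3, ok], X)[2, 1], tolerance = 1e-8)
})

test_that("BH adjustment matches the hand enumeration", {
  out <- adjustFdr(c(0.001, 0.01, 0.02, 0.8))
  expect_equal(out$q, c(0.004, 0.02, 8 / 300, 0.8), tolerance = 1e-12)
  expect_equal(sum(out$significant), 3)
  expect_equal(adjustFdr(1)$q, 1)
  expect_equal(sum(adjustFdr(rep(1, 5))$significant), 0)
  expect_equal(adjustFdr(0.04)$q, 0.04)
  expect_error(adjustFdr(numeric()), "empty")
  expect_error(adjustFdr(c(0.5, 0)), "\\(0, 1\\]")
  # discoveries grow monotonically with the threshold
  set.seed(68)
  p <- runif(200)^2
  d1 <- adjustFdr(p, 0.01)$significant
  d2 <- adjustFdr(p, 0.05)$significant
  d3 <- adjustFdr(p, 0.2)$significant
  expect_true(all(d1 <= d2) && all(d2 <= d3))
})

test_that("replication applies the p-threshold and directional rule", {
  primary <- data.frame(
    probe_id = c("a", "b", "c", "d", "e"),
    b = c(-0.03, -0.03, 0.02, 0.01, -0.02),
    p = c(1e-6, 1e-5, 1e-5, 1e-4, 0.5),
    q = c(0.01, 0.01, 0.02, 0.03, 0.9),
    direction = c(-1, -1, 1, 1, -1))
  replication <- data.frame(
    probe_id = c("a", "b", "c"),
    b = c(-0.02, 0.02, 0.01),
    p = c(0.03, 0.03, 0.06),
    q = c(0.2, 0.2, 0.3),
    direction = c(-1, 1, 1))
  rep <- replicateProbes(primary, replication)
  expect_setequal(rep@primarySignificant, c("a", "b", "c", "d"))
  expect_setequal(rep@tested, c("a", "b", "c"))
  # a: p<0.05 same sign -> replicated; b: sign flip; c: p=0.06
  expect_identical(rep@replicated, "a")
  expect_equal(rep@excluded$probe_id, "d")
  expect_error(replicateProbes(primary,
                               data.frame(probe_id = "zz", b = 1, p = 0.1,
                                          q = 0.1, direction = 1)),
               "no probes")
})

test_that("replication funnel recovers planted probes across two cohorts", {
  man <- simulateManifest(1200, seed = 71)
  causal <- head(cleanProbes(man), 25)
  eff <- data.frame(probe_id = causal,
                    effect = rep(c(0.03, -0.03), length.out = 25))
  prim <- simulateCohort(man, 91, fibrosisEffects = eff, nGapProbes = 0,
                         detectionFailRate = 0, seed = 72)
  repl <- simulateCohort(man, 85, fibrosisEffects = eff, nGapProbes = 0,
                         detectionFailRate = 0, idPrefix = "R", seed = 73)
  run <- function(sim) {
    m <- betaToM(betaValues(sim$mset))
    probeAssociation(m, sim$sampleSheet$fibrosis_pct,
                     sim$sampleSheet[, fullCovariates])
  }
  resP <- run(prim); resR <- run(repl)
  rep <- replicateProbes(resP, resR)
  causalDiscovered <- intersect(rep@primarySignificant, causal)
  expect_gte(length(intersect(rep@replicated, causalDiscovered)) /
               length(causalDiscovered), 0.6)
  # combined-cohort pass: replicated causal probes stay significant
  comb <- combinedAssociation(
    betaToM(betaValues(prim$mset)), betaToM(betaValues(repl$mset)),
    prim$sampleSheet$fibrosis_pct, repl$sampleSheet$fibrosis_pct,
    prim$sampleSheet[, fullCovariates], repl$sampleSheet[, fullCovariates],
    report = rep)
  expect_true(all(comb$report@combinedSignificant %in% rep@replicated))
  expect_gte(length(comb$report@combinedSignificant),
             0.8 * length(intersect(rep@replicated, causal)))
})

test_that("combined analysis deduplicates shared samples", {
  fx <- makeEwasFixture(nProbes = 50, nSamples = 40, nCausal = 0, seed = 75,
                        missingFibrosisFrac = 0)
  # replication cohort literally shares 10 samples with the primary
  m2 <- fx$m[, c(1:10, 11:30)]
  comb <- combinedAssociation(fx$m, m2,
                              fx$sheet$fibrosis_pct,
                              fx$sheet$fibrosis_pct[c(1:10, 11:30)],
                              dedup = TRUE)
  expect_equal(unique(comb$result$n_used), 40)
  combNo <- combinedAssociation(fx$m, m2, fx$sheet$fibrosis_pct,
                                fx$sheet$fibrosis_pct[c(1:10, 11:30)],
                                dedup = FALSE)
  expect_equal(unique(combNo$result$n_used), 70)
})
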