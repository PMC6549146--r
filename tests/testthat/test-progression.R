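# shared fixture: a cohort with planted clinical slope effects
makeSlopeFixture <- function(seed, nSamples = 80, nSubjects = 69,
                             slopeEffects = NULL, m = NULL,
                             sheet = NULL) {
  if (is.null(sheet)) {
    man <- simulateManifest(60, seed = seed)
    sim <- simulateCohort(man, nSamples = nSamples, nGapProbes = 0,
                          seed = seed + 1)
    sheet <- sim$sampleSheet
    m <- betaToM(betaValues(sim$mset))
  }
  traj <- simulateTrajectories(sheet, m, slopeEffects = slopeEffects,
                               nSubjects = nSubjects, seed = seed + 2)
  est <- filterSubjects(unadjustedSlopes(traj$egfr))
  keep <- est$subject_id[est$included]
  # occasional optimizer-convergence warnings at this size are benign
  blup <- suppressWarnings(
    blupAdjust(traj$egfr[traj$egfr$subject_id %in% keep, ]))
  idx <- match(blup$subject_id, sheet$sample_id)
  list(sheet = sheet, m = m, traj = traj, blup = blup, idx = idx)
}

test_that("univariateScreen keeps signal and drops degenerate columns", {
  set.seed(91)
  slope <- rnorm(69)
  cand <- data.frame(strong = slope + rnorm(69, 0, 0.2),
                     flat = rep(1, 69),
                     noise = rnorm(69))
  expect_warning(out <- univariateScreen(cand, slope), "zero variance")
  expect_true(out$kept[out$variable == "strong"])
  expect_false(out$kept[out$variable == "flat"])
  # p matches the t-distribution oracle for the correlation test
  r <- cor(cand$noise, slope)
  tstat <- r * sqrt(67) / sqrt(1 - r^2)
  expect_equal(out$p[out$variable == "noise"], 2 * pt(-abs(tstat), 67),
               tolerance = 1e-12)
  expect_error(univariateScreen(data.frame(x = rnorm(5)), rnorm(5)),
               "at least 10")
})

test_that("independent noise passes the screen at about the nominal rate", {
  hits <- vapply(1:400, function(s) {
    set.seed(1000 + s)
    univariateScreen(data.frame(x = rnorm(69)), rnorm(69))$kept
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("lassoSelect keeps strong predictors and is seeded", {
  picks <- vapply(1:25, function(s) {
    set.seed(2000 + s)
    strong <- rnorm(69)
    y <- 0.7 * strong + rnorm(69, 0, sqrt(1 - 0.49))
    X <- data.frame(strong = strong,
                    n1 = rnorm(69), n2 = rnorm(69), n3 = rnorm(69),
                    n4 = rnorm(69), n5 = rnorm(69))
    "strong" %in% lassoSelect(X, y, seed = s)
  }, TRUE)
  expect_gte(mean(picks), 0.9)
  set.seed(3000)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- rnorm(50)
  # pure-noise candidates: empty selection with a warning, deterministically
  expect_warning(s1 <- lassoSelect(X, y, seed = 4), "zero")
  s2 <- suppressWarnings(lassoSelect(X, y, seed = 4))
  expect_identical(s1, s2)
  expect_identical(s1, character(0))
  expect_error(lassoSelect(X[, 1, drop = FALSE], y), "at least 2")
})

test_that("fitBaseModel is exact WLS with the documented AIC convention", {
  # intercept-only weighted mean
  d0 <- data.frame(y = c(0, 10))
  m0 <- fitBaseModel(d0, "y", character(), weights = c(1, 3))
  expect_equal(unname(m0$coefficients), 7.5)
  # equal weights reduce to OLS
  set.seed(92)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  mw <- fitBaseModel(d, "y", c("x1", "x2"), weights = rep(2, 40))
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(unname(mw$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  # arbitrary weights match the closed-form normal-equations oracle
  w <- runif(40, 0.2, 5)
  mfit <- fitBaseModel(d, "y", c("x1", "x2"), weights = w)
  X <- cbind(1, d$x1, d$x2)
  expect_equal(unname(mfit$coefficients), drop(wlsOracle(X, d$y, w)),
               tolerance = 1e-8)
  # AIC equals stats::AIC on the identical weighted lm
  expect_equal(mfit$aic, AIC(lm(y ~ x1 + x2, d, weights = w)))
  expect_error(fitBaseModel(cbind(d, x3 = d$x1), "y",
                            c("x1", "x2", "x3"), rep(1, 40)),
               "rank")
  expect_error(fitBaseModel(d, "y", "x1", rep(0, 40)), "positive")
})

test_that("featureAugmentation flags a planted probe and honours contracts", {
  fx <- makeSlopeFixture(seed = 93)
  sheet <- fx$sheet; idx <- fx$idx
  cand <- data.frame(baseline_egfr = sheet$baseline_egfr[idx],
                     diabetes = sheet$diabetes[idx], age = sheet$age[idx])
  base <- fitBaseModel(cbind(adjusted_slope = fx$blup$adjusted_slope, cand),
                       "adjusted_slope",
                       c("baseline_egfr", "diabetes", "age"),
                       fx$blup$weight)
  # features: planted = residual-correlated probe built from a real probe
  n <- nrow(cand)
  set.seed(94)
  planted <- fx$blup$adjusted_slope -
    fitted(base$fit) + rnorm(n, 0, 0.4 * sd(fx$blup$adjusted_slope))
  feats <- rbind(planted = planted,
                 null1 = rnorm(n), null2 = rnorm(n),
                 const = rep(1, n))
  colnames(feats) <- fx$blup$subject_id
  extra <- data.frame(batch = sheet$batch[idx],
                      bisulfite_efficiency = sheet$bisulfite_efficiency[idx])
  res <- featureAugmentation(base, feats, extra, onCollinear = "skip")
  expect_true(res$improves[res$feature_id == "planted"])
  expect_true(res$skipped[res$feature_id == "const"])
  expect_lt(res$aic[res$feature_id == "planted"], attr(res, "base_aic"))
  # feature equal to a base variable triggers the collinearity error
  copy <- rbind(copy = cand$baseline_egfr)
  colnames(copy) <- fx$blup$subject_id
  expect_error(featureAugmentation(base, copy, extra), "collinear")
  # one added parameter can lower AIC by at most 2 under the null
  nulls <- res[grepl("null", res$feature_id), ]
  expect_true(all(nulls$aic >= attr(res, "base_aic") - 2 - 1e-8))
})

test_that("unweighted augmentation equals the weighted path at unit weights", {
  fx <- makeSlopeFixture(seed = 95)
  sheet <- fx$sheet; idx <- fx$idx
  cand <- data.frame(baseline_egfr = sheet$baseline_egfr[idx],
                     age = sheet$age[idx])
  d <- cbind(adjusted_slope = fx$blup$adjusted_slope, cand)
  base <- fitBaseModel(d, "adjusted_slope", names(cand),
                       rep(1, nrow(d)))
  set.seed(96)
  feats <- matrix(rnorm(3 * nrow(d)), 3,
                  dimnames = list(paste0("f", 1:3), fx$blup$subject_id))
  res <- featureAugmentation(base, feats)
  for (k in 1:3) {
    fit <- lm(adjusted_slope ~ baseline_egfr + age + f,
              data = cbind(d, f = feats[k, ]))
    expect_equal(res$coefficient[k], unname(coef(fit)["f"]),
                 tolerance = 1e-10)
    expect_equal(res$p[k], summary(fit)$coefficients["f", 4],
                 tolerance = 1e-10)
  }
})

test_that("variancePartition matches Type II conditional sums of squares", {
  set.seed(97)
  d <- data.frame(y = rnorm(50), x1 = rnorm(50), x2 = rnorm(50))
  d$y <- d$y + 0.8 * d$x1 - 0.5 * d$x2
  w <- runif(50, 0.5, 2)
  model <- fitBaseModel(d, "y", c("x1", "x2"), w)
  vp <- variancePartition(model)
  # independent oracle: car::Anova Type II SS on the same weighted fit
  skip_if_not_installed("car")
  ca <- car::Anova(model$fit, type = 2)
  expect_equal(vp$ss[vp$variable == "x1"], ca["x1", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(vp$ss[vp$variable == "x2"], ca["x2", "Sum Sq"],
               tolerance = 1e-8)
  # single-predictor model: percent equals R^2 * 100
  m1 <- fitBaseModel(d, "y", "x1", w)
  vp1 <- variancePartition(m1)
  expect_equal(vp1$percent[vp1$variable == "x1"], 100 * m1$r_squared,
               tolerance = 1e-10)
  expect_true(all(vp$percent >= 0))
})

test_that("screen -> LASSO -> WLS chain recovers the planted base variables", {
  recovered <- vapply(1:12, function(s) {
    fx <- makeSlopeFixture(seed = 5000 + 7 * s)
    sheet <- fx$sheet; idx <- fx$idx
    cand <- data.frame(
      baseline_egfr = sheet$baseline_egfr[idx],
      diabetes = sheet$diabetes[idx],
      age = sheet$age[idx],
      hypertension = sheet$hypertension[idx],
      lymphocytic_infiltrate = sheet$lymphocytic_infiltrate[idx])
    built <- buildProgressionModel(cand, fx$blup$adjusted_slope,
                                   fx$blup$weight, seed = s)
    setequal(built$selected, c("baseline_egfr", "diabetes", "age"))
  }, TRUE)
  expect_gte(mean(recovered), 0.7)
})

test_that("forcing hypertension never enlarges the improving-feature set", {
  fx <- makeSlopeFixture(seed = 98)
  sheet <- fx$sheet; idx <- fx$idx
  cand <- data.frame(baseline_egfr = sheet$baseline_egfr[idx],
                     diabetes = sheet$diabetes[idx], age = sheet$age[idx],
                     hypertension = sheet$hypertension[idx])
  d <- cbind(adjusted_slope = fx$blup$adjusted_slope, cand)
  base <- fitBaseModel(d, "adjusted_slope",
                       c("baseline_egfr", "diabetes", "age"),
                       fx$blup$weight)
  forced <- fitBaseModel(d, "adjusted_slope",
                         c("baseline_egfr", "diabetes", "age",
                           "hypertension"), fx$blup$weight)
  feats <- fx$m[1:40, fx$blup$subject_id]
  resBase <- featureAugmentation(base, feats, onCollinear = "skip")
  resForced <- featureAugmentation(forced, feats, onCollinear = "skip")
  expect_true(all(resForced$feature_id[resForced$improves] %in%
                    resBase$feature_id[resBase$improves]))
  # the forced model has one more parameter; its AIC reference differs
  expect_equal(length(forced$coefficients), length(base$coefficients) + 1)
})
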