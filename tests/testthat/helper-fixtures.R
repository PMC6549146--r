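# shared fixtures, built in code; all seeded

fullCovariates <- c("age", "sex", "race", "diabetes", "hypertension",
                    "batch", "bisulfite_efficiency",
                    "lymphocytic_infiltrate")

# clean autosomal, non-control, non-flagged probe ids
cleanProbes <- function(manifest) {
  manifest$probe_id[!manifest$is_bisulfite_control &
                      !manifest$is_sex_chrom &
                      !manifest$is_cross_reactive & !manifest$near_snp]
}

# small cohort with planted fibrosis probes; returns everything tests need
makeEwasFixture <- function(nProbes = 400, nSamples = 60, nCausal = 4,
                            effect = 0.03, noiseSd = 0.5, seed = 11,
                            missingFibrosisFrac = 0.08) {
  man <- simulateManifest(nProbes, seed = seed)
  causal <- head(cleanProbes(man), nCausal)
  eff <- data.frame(probe_id = causal,
                    effect = rep(c(effect, -effect), length.out = nCausal))
  sim <- simulateCohort(man, nSamples = nSamples, fibrosisEffects = eff,
                        nGapProbes = 0, noiseSd = noiseSd,
                        missingFibrosisFrac = missingFibrosisFrac,
                        detectionFailRate = 0, seed = seed + 1)
  list(manifest = man, sim = sim, causal = causal, eff = eff,
       m = betaToM(betaValues(sim$mset)), sheet = sim$sampleSheet)
}

# independent normal-equations WLS oracle
wlsOracle <- function(X, y, w) {
  W <- diag(w)
  unname(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}

# independent simple-OLS oracle for one probe (QR-free, normal equations)
olsOracle <- function(y, X) {
  unname(solve(t(X) %*% X, t(X) %*% y))
}

# single-sample fixture with three methylation states where the type II
# modes are compressed relative to type I
makeBmiqFixture <- function(nI = 1500, nII = 3000, modesI = c(0.10, 0.5, 0.90),
                            modesII = c(0.25, 0.5, 0.75), seed = 51) {
  set.seed(seed)
  drawState <- function(n, modes) {
    st <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.1, 0.45))
    mu <- modes[st]
    conc <- 60
    rbeta(n, mu * conc, (1 - mu) * conc)
  }
  bI <- drawState(nI, modesI)
  bII <- drawState(nII, modesII)
  man <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(nI + nII)),
    chrom = "chr1", pos = seq_len(nI + nII) * 3000,
    design_type = rep(c("I", "II"), c(nI, nII)),
    is_sex_chrom = FALSE, is_cross_reactive = FALSE,
    is_bisulfite_control = FALSE, near_snp = FALSE,
    stringsAsFactors = FALSE)
  beta <- matrix(c(bI, bII), ncol = 1,
                 dimnames = list(man$probe_id, "s1"))
  list(beta = beta, manifest = man, isII = man$design_type == "II")
}

# exhaustive permutations of seq_len(n) as a list (independent of the
# package's internal generator)
oraclePerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oraclePerms(n - 1)) {
    for (pos in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = pos)
  }
  out
}
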