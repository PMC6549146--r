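---
title: "Kidney methylation, interstitial fibrosis and CKD progression: models and design"
author: "methylCKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kidney methylation, interstitial fibrosis and CKD progression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylCKD)
```

## The scientific problem

Diabetic kidney disease is defined structurally by tubulointerstitial
fibrosis and functionally by declining glomerular filtration. Cytosine
methylation in kidney tubule epithelium is a candidate mechanism linking
metabolic history to both: methylation marks are stable across cell
division, so they can record past exposure and potentially predict future
functional decline. methylCKD implements the full analysis chain for this
question on Illumina 450k-style beta matrices:

1. array quality control and normalization,
2. a probe-wise covariate-adjusted association of methylation with
   interstitial fibrosis (or baseline eGFR), with BH-FDR control and
   directional two-cohort replication,
3. BLUP-adjusted longitudinal eGFR slopes and an inverse-variance-weighted
   progression model, augmented one CpG probe (or gene) at a time under an
   AIC + FDR improvement criterion,
4. chromatin-state enrichment of significant probe sets, and
5. cis methylation-expression (eQTM) mapping with a permutation null.

Every stage can be exercised against a seeded synthetic-cohort generator
that plants known effects, so the statistical guarantees (FDR control,
replication sensitivity, selection behaviour, calibration of permutation
and resampling nulls) are tested as code, not assumed.

## Data model

The central container is the `MethylSet`, a `SummarizedExperiment` with
assays `beta` (methylation fraction in [0, 1]) and `detectionP`, the probe
manifest as `rowData` (position, Infinium design type, sex-chromosome /
cross-reactive / SNP-proximity flags, and the ten bisulfite-conversion
control probes: six type I, four type II) and the clinical sample sheet as
`colData`. Analyses run on M-values, `M = log2(beta / (1 - beta))`, which
are approximately homoscedastic; beta values are clipped to
`[1e-6, 1 - 1e-6]` before the logit so M is always finite. The
transformation is exact and invertible away from the clipping bounds
(round-trip error below 1e-12 in the tests).

## Quality control

Probe filters apply in a fixed precedence (`control > sex_chrom >
cross_reactive > near_snp / gap_signal > detection`), so every removed
probe carries exactly one reason and re-running QC on already-filtered data
removes nothing. Specific choices:

* **Detection.** The array-level rule is "detection p > 0.01 fails"; a
  probe is removed when more than 5% of its samples fail (the matrix-level
  fraction is a package decision -- 5% is the conventional choice), and
  failing entries of retained probes are set to missing. Downstream
  regression handles masked entries by per-probe complete-case fits; the
  probe-augmentation stage skips masked features instead, because changing
  `n` would break AIC comparability.
* **Gap signal.** A probe whose sorted beta values split at gaps larger
  than 0.05 into at least two groups of at least three samples is treated
  as genotype-driven and removed (kidney cohorts). The absolute group
  minimum (3) rather than a fraction reflects cohort sizes near 90, where
  fractional rules degenerate. The blood-cohort profile replaces gap
  hunting with the SNP-proximity flag (probes within 1 bp of a common
  variant), as a covariate/filter profile rather than a code fork. Note a
  subtlety: flagging is not globally monotone in the gap threshold,
  because a low threshold can fragment a cluster into sub-minimum pieces
  that only become countable groups when the threshold rises; on cleanly
  clustered data the intuitive monotonicity holds and is tested.
* **Bisulfite conversion.** Per sample, the median beta of the ten control
  probes; it joins the sample sheet and every association model as a
  covariate.
* **Sample outliers.** Samples whose Euclidean distance from the centroid
  in the (PC1, PC2) plane exceeds `median + 4 * MAD` are flagged. The rule
  is deliberately robust (a gross outlier cannot inflate its own
  threshold); with k = 4 a homogeneous Gaussian cohort of 90 is flagged
  free in roughly nine tenths of seeds, so the default errs slightly
  toward sensitivity.

## Beta-mixture quantile normalization

Infinium type II probes have a compressed dynamic range relative to type I
probes. Per sample, three-state (unmethylated / hemimethylated /
methylated) beta mixtures are fitted by EM to each design type; the M-step
is moment-matching (component shapes recovered from responsibility-weighted
means and variances), with k-means initialization, a relative
log-likelihood tolerance of 1e-6 and a 500-iteration cap (non-convergence
is an error naming the sample). Type II probes are assigned to states by
maximum posterior along a monotone grid; U- and M-state values map through
beta CDF matching onto the corresponding type I components, and H-state
values are linearly interpolated between the mapped boundaries. The map is
monotone, so within-sample type II rank order is preserved exactly; when
the two designs already agree the map is the identity to within EM
estimation error (< 0.02 in the tests); on synthetic two-design mixtures
the type I / type II Kolmogorov-Smirnov distance drops by far more than
half.

## EWAS and replication

For each probe the model is ordinary least squares of M on the phenotype
(percent interstitial fibrosis, or baseline eGFR for the function-level
variant) plus age, sex, race, diabetes, hypertension, batch, bisulfite
conversion efficiency and lymphocytic infiltrate. M is the outcome and the
phenotype the exposure -- the standard EWAS orientation, consistent with
reported per-percent-fibrosis effect sizes near 0.03 M-units. Samples with
missing phenotype are dropped listwise. Probes sharing a complete design
are fitted in a single QR decomposition; the per-probe coefficient, its
t-based two-sided p, BH q, the sign of the effect, and the unadjusted
Pearson correlation (for volcano displays) are reported.

Replication follows the two-cohort funnel: primary discoveries (q < 0.05)
are looked up in an independent cohort; probes absent there are recorded
as excluded for poor data quality; a probe replicates when its replication
p < 0.05 *and* the direction of effect agrees. The pooled-cohort pass
re-runs the association on both cohorts combined. Where the two cohorts
share samples the duplicate copies are dropped (primary kept) and a cohort
indicator joins the covariates; whether the original analysis deduplicated
its shared samples is not documented, so deduplication is the package's
default with `dedup = FALSE` available. A covariate that collapses to a
single level after pooling (the cohort indicator itself, in the fully
shared edge case) is dropped rather than passed on as a degenerate design
column.

## Longitudinal slopes and BLUP adjustment

Per-subject eGFR slopes come from least squares across all available
measures; subjects need at least 3 estimations spanning at least 0.25
years (three months, to wash out acute peri-nephrectomy changes), and
slopes beyond +/-40 ml/min/1.73m2/yr are excluded as implausible. The
`ckdEpi()` helper implements the 2009 creatinine equation for synthetic
use; real pipelines may supply eGFR directly.

Raw slopes are noisy, so the analysis slope is the best linear unbiased
predictor from the mixed model

$$ eGFR_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t_{ij} +
\epsilon_{ij}, $$

fitted by REML with correlated random intercept and slope (an uncorrelated
fallback engages on failed or singular fits and is flagged). The subject's
adjusted slope is $\tilde s_i = \beta_1 + \hat b_{1i}$ and its variance
$v_i$ is the conditional (posterior) variance of the random slope only --
excluding fixed-effect uncertainty, because $1/v_i$ serves as a *relative*
weight and a constant shift would rescale all weights equally. No
covariates beyond time enter the BLUP model. `blupAdjust()` also accepts
fixed variance components and then evaluates the mixed-model equations
directly; in a balanced design with effectively free intercepts this
reproduces the textbook shrinkage
$\tilde s_i = \beta_1 + \lambda_i (s_i - \beta_1)$ with
$\lambda_i = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2 / \Sigma_j (t_{ij} -
\bar t_i)^2)$ to 1e-6, which the tests use as an independent oracle.

One behaviour worth knowing: because intercept and slope are modelled
jointly, the BLUP leans on the intercept (baseline eGFR) when visit data
are sparse. Slope components correlated with the intercept survive
shrinkage almost untouched while orthogonal components (e.g. a diabetes
effect) are attenuated toward the reliability of the raw slope. This is a
property of the estimator, not a bug, and it drives several fixture
choices below.

## The progression model

Candidates that pass a univariate Pearson screen (p < 0.05 against the
adjusted slope) enter a gaussian LASSO; the penalty is chosen by seeded
10-fold cross-validation at minimum CV error, and nonzero-coefficient
variables form the base model, fitted by weighted least squares with
$w_i = 1/v_i$. The LASSO stage itself is unweighted (weights enter only
the final WLS; a weighted variant is available by flag). AIC uses the
weighted Gaussian log-likelihood with weights treated as known precisions
and k = parameters + 1, matching `stats::AIC` on the identical weighted
`lm`; absolute AIC values therefore depend on this convention and only
differences are meaningful. Hypertension (or anything else) can be forced
into the base model as a configuration, mirroring the sensitivity analysis
in which forcing hypertension shrinks but does not empty the improving
probe set.

Augmentation adds each feature individually to the base model together
with batch and bisulfite efficiency, refits with the same weights, and
flags `improves = (q < 0.05 AND AIC < base AIC)` with BH computed across
features (ties at equal p resolve by stable feature order). Because the
augmented model carries the feature plus the technical covariates, the AIC
hurdle is roughly eight likelihood units; a feature must earn |t| near
three just to clear it, and the null bound "AIC can drop by at most 2 for
one spurious parameter" is tested directly. Variance is partitioned by
Type II conditional sums of squares -- RSS(model without the variable)
minus RSS(full), as a percent of total weighted SS -- verified in the
tests against `car::Anova(type = 2)` on the identical fit.

## Regulatory enrichment

Probes map to chromatin states (promoter / enhancer / transcribed /
inactive) by interval containment, ties resolved promoter > enhancer >
transcribed > inactive, no overlap meaning inactive. Enrichment of a
significant set against the analysis background uses the two-sided Fisher
exact test on the 2x2 table with the significant set removed from the
background cells (keeping the table disjoint; at realistic sizes the
effect of this convention is negligible), odds ratio `ad/bc`, and the
Woolf log-interval for the 95% CI. The resampling view draws sets of the
same size from the background (without replacement, 10,000 draws by
default), computes `fold = observed / draw_count` per draw -- draws with
zero in-state probes are excluded from quantiles and counted -- and
summarizes by median, quartiles and 1.5 IQR whiskers. Per-draw division is
used (rather than dividing by the median draw count) because it yields the
distribution that such figures display. With a 65-probe set at 5%
enhancer coverage the in-state count is a small binomial, so a single null
set's median fold is coarse; calibration checks therefore average the
median fold over independent null sets.

## cis eQTM

Probe-gene pairs within 500 kb of the TSS (inclusive boundary; distance
signed by gene strand, magnitude used for windowing) are tested by simple
regression of expression on M. Significance uses a permutation null:
expression sample labels are permuted jointly across genes, and the |t|
statistics of all pairs and permutations pool into one shared null, which
is what gives empirical p-values resolution below the stringent 8e-5
cutoff at a practical permutation count (the per-pair, non-pooled mode is
available). With six samples the implementation can enumerate all 720
label permutations, and the tests require exact agreement with an
independently coded enumeration oracle. The empirical p for sampled
permutations is `(1 + exceedances) / (1 + null size)`, so it can never be
zero; a warning notes when the pooled null is too small for the requested
cutoff.

## The synthetic-data generator

`simulateManifest()` lays probes along a few chromosomes with 2.5-10 kb
spacing, assigns design types and QC flags at requested fractions, and
designates the ten bisulfite controls. `simulateCohort()` draws clinical
covariates matching a nephrectomy DKD cohort (baseline eGFR ~ N(68, 26),
age ~ N(63.5, 11.5), 45% diabetic, 71% hypertensive, gamma-skewed fibrosis
with mean ~12% and SD ~19%, ~8% missing fibrosis scores), probe baselines
from a bimodal beta mixture with modes near 0.1 and 0.9, type II baselines
attenuated toward 0.5 by a factor 0.7, and per-entry values on the M scale:
baseline + planted fibrosis effect + per-(probe, batch) shift (SD 0.1) +
a global bisulfite-efficiency term + Gaussian noise. Gap probes are
overwritten with three genotype-like clusters (beta 0.05 / 0.5 / 0.95,
Hardy-Weinberg-like 1:2:1 weights); control probes track each sample's
conversion efficiency.

Two noise scales are used deliberately. Association fixtures use `noiseSd
= 0.5` M-units -- the regime in which an 0.03 M-unit-per-percent fibrosis
effect produces the intended partial correlations near 0.7 at n = 90. QC
fixtures (gap detection, BMIQ identity behaviour) use `noiseSd = 0.15`,
the array-technical scale at which unimodal probes form the tight clusters
(beta SD 0.02-0.03) that real arrays show; at the association scale,
mid-range probes are wide enough that the gap rule occasionally splits
their tails, which matches the large probe mass the gap filter removes in
practice but makes a "zero false positive" expectation meaningless.

`simulateTrajectories()` builds true slopes as
$\gamma_0 + \gamma_1\,eGFR + \gamma_2\,DM + \gamma_3\,age + \Sigma_k
\delta_k M_k + u_i$ and observes `baseline + slope * t + visit noise` at
per-subject visit times. The defaults are calibrated to the cohort this
package emulates: coefficients (3, 0.07, -4, -0.18) with subject SD 0.8
give a mean slope near -5.5 ml/min/1.73m2/yr and reproduce the
reported asymmetric variance-explained pattern (baseline eGFR explaining
the largest share, diabetes and age moderate ones); visit noise SD 5
reflects creatinine-based eGFR lab variation, and 8-20 visits over 1.5-5
years reflects clinical laboratory series, which typically hold several
draws per follow-up year. Under sparser schedules the BLUP intercept
leaning described above attenuates diabetes and age below reliable
detectability at n = 69 -- the dense default is what makes the
screen-then-LASSO stage recover the planted clinical trio in the large
majority of seeds, as the original analysis did. The positivity floor
(eGFR >= 1) kinks noiseless trajectories that would cross zero, so exact
noiseless recovery holds away from the floor.

`simulateExpression()` anchors gene TSSs on probe positions (planted links
must respect the 500 kb window, so the truth is discoverable) and
generates linked expression at a requested correlation; unlinked genes are
independent noise. `simulateChromStates()` assigns each probe's 1 kb
neighbourhood a state, with causal probes placed in kidney enhancers at
coverage x enrichment-factor, other tissues unenriched; because probe
spacing exceeds the interval width, state intervals never overlap.

What the generator does *not* emulate: raw IDAT intensities and probe
chemistry, realistic genome-wide probe density, cell-type composition
shifts with fibrosis, correlated CpG blocks (probes are independent given
covariates), non-Gaussian visit processes, and medication or
acute-illness effects on eGFR. Passing tests therefore demonstrate that
the machinery is correct and calibrated under the stated generative
assumptions, not that real kidney data satisfy those assumptions.

## Fixture strength for the augmentation check

The recovery checks size their planted signals against the reported
strength of real discoveries. A probe that "improves" the progression
model must clear both BH significance and the AIC hurdle described above;
the reported improving probes correspond to model AIC drops of 15-30,
i.e. |t| near 5-6. The acceptance fixture plants a slope effect of 1.75
ml/min/1.73m2/yr per M-unit on a fibrosis-variable probe, which lands the
augmentation t statistic in exactly that range; weaker plants (around 1
ml/min per M-unit) sit near |t| ~ 3 under every visit regime considered
and are flagged in only half to three quarters of seeds -- a power
statement about small effects at n = 69, not a defect of the machinery,
and the false-improvement rate on 2,000 null probes stays below 1%
throughout.

## Problem sizes and determinism

Every stochastic function takes a `seed` and is a pure function of
(arguments, seed); the end-to-end driver `runPipeline()` derives one
sub-seed per stage, and reruns are byte-identical down to the written
TSVs. The bundled checks use cohorts of 91/85/69 samples (the sizes this
design emulates) with 40-5,000 probes, 10-50 generator seeds per
property, 10,000 resampling draws and a few hundred permutations per
null; the complete test suite runs in roughly three minutes on one CPU.

## Known limitations

* BMIQ's moment-matching EM is robust on well-separated methylation
  mixtures but is not a maximum-likelihood fit; heavily skewed or
  single-mode samples can converge to degenerate H states (handled by the
  empty-class guard).
* The permutation eQTM pools null statistics across pairs; pairs with
  grossly different null distributions (extreme missingness imbalance)
  would need the per-pair mode.
* `variancePartition()` assumes an additive model; with interactions the
  conditional-SS logic would need marginality-aware refitting.
* The 2009 CKD-EPI equation (with its race coefficient) is implemented
  because it matches the era of the data this design emulates; it is not
  an endorsement for contemporary clinical use.
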