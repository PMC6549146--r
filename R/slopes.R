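#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' The creatinine-based 2009 CKD-EPI equation:
#' \deqn{eGFR = 141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot 1.018[F] \cdot
#'   1.159[black]}
#' with \eqn{\kappa = 0.7} and \eqn{\alpha = -0.329} for women,
#' \eqn{\kappa = 0.9} and \eqn{\alpha = -0.411} for men. All arguments are
#' vectorized.
#'
#' @param creatinine serum creatinine in mg/dL (> 0).
#' @param age age in years (> 0).
#' @param sex `"F"`/`"M"` (or logical `female`).
#' @param raceBlack logical; applies the 1.159 coefficient of the 2009
#'   equation.
#' @return eGFR in ml/min per 1.73 m^2.
#' @export
#' @examples
#' ckdEpi(0.7, 50, "F", FALSE)  # ~101
#' ckdEpi(1.2, 60, "M", TRUE)   # ~75.7
ckdEpi <- function(creatinine, age, sex, raceBlack = FALSE) {
  if (any(creatinine <= 0) || any(age <= 0))
    stop("creatinine and age must be positive")
  female <- if (is.logical(sex)) sex else toupper(as.character(sex)) == "F"
  n <- max(length(creatinine), length(age), length(female),
           length(raceBlack))
  creatinine <- rep_len(creatinine, n); age <- rep_len(age, n)
  female <- rep_len(female, n); raceBlack <- rep_len(raceBlack, n)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- creatinine / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(raceBlack, 1.159, 1)
}

.checkSeries <- function(series) {
  need <- c("subject_id", "time_years", "egfr")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("eGFR series is missing columns: ", paste(miss, collapse = ", "))
  bad <- vapply(split(series$time_years, series$subject_id),
                function(t) any(diff(sort(t)) <= 0) || anyDuplicated(t) > 0,
                TRUE)
  if (any(bad))
    stop("visit times must be strictly increasing per subject: ",
         paste(utils::head(names(bad)[bad], 3), collapse = ", "))
  invisible(series)
}

#' Per-subject unadjusted eGFR slopes
#'
#' Simple least-squares slope of eGFR on time across all available measures
#' of each subject, with observation count and follow-up span.
#'
#' @param series `data.frame(subject_id, time_years, egfr)` with strictly
#'   increasing times per subject.
#' @return `data.frame(subject_id, n_obs, span_years, unadjusted_slope)`;
#'   subjects with fewer than two observations carry `NA` slopes.
#' @export
#' @examples
#' s <- data.frame(subject_id = "a", time_years = 0:2, egfr = c(60, 55, 50))
#' unadjustedSlopes(s)  # slope -5
unadjustedSlopes <- function(series) {
  .checkSeries(series)
  out <- lapply(split(series, series$subject_id), function(d) {
    d <- d[order(d$time_years), ]
    slope <- if (nrow(d) >= 2)
      stats::cov(d$time_years, d$egfr) / stats::var(d$time_years)
    else NA_real_
    data.frame(subject_id = d$subject_id[1], n_obs = nrow(d),
               span_years = diff(range(d$time_years)),
               unadjusted_slope = slope, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclusion filters for slope subjects
#'
#' Applies, in order, the inclusion rules for the longitudinal analysis: a
#' minimum number of eGFR estimations, a minimum follow-up span (0.25 yr =
#' three months, to wash out acute peri-nephrectomy changes), and a bound on
#' physiologically implausible unadjusted slopes (|slope| > 40 ml/min per
#' 1.73 m^2 per year). Each excluded subject carries the first matching
#' reason.
#'
#' @param estimates output of [unadjustedSlopes()].
#' @param minObs minimum number of observations.
#' @param minSpanYears minimum first-to-last follow-up in years.
#' @param slopeBound absolute slope bound.
#' @return the input with `included` (logical) and `exclusion_reason`
#'   (`too_few_obs`, `short_span`, `slope_bound`, or `NA`).
#' @export
filterSubjects <- function(estimates, minObs = 3L, minSpanYears = 0.25,
                           slopeBound = 40) {
  reason <- rep(NA_character_, nrow(estimates))
  reason[estimates$n_obs < minObs] <- "too_few_obs"
  sel <- is.na(reason) & estimates$span_years < minSpanYears
  reason[sel] <- "short_span"
  sel <- is.na(reason) & !is.na(estimates$unadjusted_slope) &
    abs(estimates$unadjusted_slope) > slopeBound
  reason[sel] <- "slope_bound"
  estimates$included <- is.na(reason)
  estimates$exclusion_reason <- reason
  estimates
}

# BLUP machinery with variance components fixed: per-subject GLS and
# conditional moments of the random effects. G is the 2x2 random-effect
# covariance (intercept, slope); sigma the residual SD.
.blupFixedVar <- function(series, G, sigma) {
  split_ <- split(series, series$subject_id)
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  pre <- lapply(split_, function(d) {
    Z <- cbind(1, d$time_years)
    V <- Z %*% G %*% t(Z) + diag(sigma^2, nrow(Z))
    Vi <- solve(V)
    list(Z = Z, y = d$egfr, Vi = Vi)
  })
  for (p in pre) {
    XtVX <- XtVX + t(p$Z) %*% p$Vi %*% p$Z
    XtVy <- XtVy + t(p$Z) %*% p$Vi %*% p$y
  }
  beta <- solve(XtVX, XtVy)
  out <- lapply(names(pre), function(id) {
    p <- pre[[id]]
    resid <- p$y - p$Z %*% beta
    bi <- G %*% t(p$Z) %*% p$Vi %*% resid
    condVar <- G - G %*% t(p$Z) %*% p$Vi %*% p$Z %*% G
    data.frame(subject_id = id, adjusted_slope = beta[2] + bi[2],
               slope_variance = condVar[2, 2], stringsAsFactors = FALSE)
  })
  list(estimates = do.call(rbind, out), fixef = beta)
}

#' BLUP-adjusted eGFR slopes
#'
#' Fits the linear mixed model
#' \deqn{eGFR_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) t_{ij} +
#'   \epsilon_{ij}}
#' with correlated random intercept and slope by REML (via
#' \pkg{lme4}), and returns per subject the shrunken slope
#' \eqn{\tilde{s}_i = \beta_1 + BLUP(b_{1i})}, its conditional variance
#' \eqn{v_i} (the posterior variance of the random slope given the data,
#' which drives the inverse-variance weights \eqn{w_i = 1/v_i} of the
#' progression model), and the weight. If the correlated fit fails or is
#' singular, an uncorrelated random intercept/slope model is used and noted.
#' Supplying `varComp` skips estimation and computes the BLUPs at fixed
#' variance components (useful for noiseless and known-truth settings).
#'
#' @param series `data.frame(subject_id, time_years, egfr)` of included
#'   subjects (>= 10).
#' @param varComp optional list with `sdIntercept`, `sdSlope`, `corr`,
#'   `sigma` fixing the variance components.
#' @param fallbackUncorrelated retry without the intercept-slope correlation
#'   when the full fit fails.
#' @return `data.frame(subject_id, adjusted_slope, slope_variance, weight)`
#'   with the fixed effects in `attr(, "fixef")`.
#' @export
blupAdjust <- function(series, varComp = NULL, fallbackUncorrelated = TRUE) {
  .checkSeries(series)
  nSub <- length(unique(series$subject_id))
  if (is.null(varComp) && nSub < 10)
    stop("BLUP adjustment needs at least 10 subjects")
  if (!is.null(varComp)) {
    rho <- if (is.null(varComp$corr)) 0 else varComp$corr
    G <- matrix(c(varComp$sdIntercept^2,
                  rho * varComp$sdIntercept * varComp$sdSlope,
                  rho * varComp$sdIntercept * varComp$sdSlope,
                  varComp$sdSlope^2), 2)
    fit <- .blupFixedVar(series, G, varComp$sigma)
    res <- fit$estimates
    res$weight <- 1 / res$slope_variance
    attr(res, "fixef") <- fit$fixef
    rownames(res) <- NULL
    return(res)
  }
  series$subject_id <- factor(series$subject_id)
  fit <- tryCatch(
    lme4::lmer(egfr ~ time_years + (time_years | subject_id), data = series,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  usedFallback <- FALSE
  if (inherits(fit, "error") || lme4::isSingular(fit, tol = 1e-5)) {
    if (!fallbackUncorrelated && inherits(fit, "error"))
      stop("mixed-model fit failed (", conditionMessage(fit),
           "); consider the uncorrelated random-effects fallback")
    fit2 <- tryCatch(
      lme4::lmer(egfr ~ time_years + (time_years || subject_id),
                 data = series, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) e)
    if (!inherits(fit2, "error")) {
      fit <- fit2
      usedFallback <- TRUE
    } else if (inherits(fit, "error")) {
      stop("mixed-model fit failed (", conditionMessage(fit), ")")
    }
  }
  re <- lme4::ranef(fit, condVar = TRUE)$subject_id
  beta <- lme4::fixef(fit)
  pv <- attr(re, "postVar")
  slopeVar <- if (is.list(pv)) {
    # uncorrelated (||) fits store one array per term
    as.numeric(pv[["time_years"]])
  } else pv[2, 2, ]
  res <- data.frame(subject_id = rownames(re),
                    adjusted_slope = beta[["time_years"]] + re$time_years,
                    slope_variance = slopeVar,
                    stringsAsFactors = FALSE)
  res$weight <- 1 / res$slope_variance
  attr(res, "fixef") <- beta
  attr(res, "fallback_uncorrelated") <- usedFallback
  rownames(res) <- NULL
  res
}
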