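#' Univariate screen of progression candidates
#'
#' Two-sided Pearson correlation test of each candidate variable against the
#' BLUP-adjusted eGFR slope; variables with p below `alpha` pass to the
#' LASSO stage. Zero-variance variables are dropped with a warning.
#'
#' @param candidates `data.frame` of numeric candidate variables (one row
#'   per subject, aligned with `slopes`).
#' @param slopes adjusted eGFR slopes.
#' @param alpha screening threshold.
#' @return `data.frame(variable, r, p, kept)`.
#' @export
univariateScreen <- function(candidates, slopes, alpha = 0.05) {
  candidates <- as.data.frame(candidates)
  res <- lapply(names(candidates), function(v) {
    x <- as.numeric(candidates[[v]])
    ok <- stats::complete.cases(x, slopes)
    if (sum(ok) < 10)
      stop("need at least 10 paired observations for '", v, "'")
    if (stats::var(x[ok]) == 0) {
      warning("variable '", v, "' has zero variance; excluded from screen")
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        kept = FALSE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], slopes[ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               kept = ct$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' LASSO variable selection for the progression base model
#'
#' Gaussian-response L1 path over the screened candidates (standardized
#' internally by \pkg{glmnet}); the penalty is chosen by seeded k-fold
#' cross-validation at minimum CV error and the variables with nonzero
#' coefficients at that penalty are returned. The LASSO stage is unweighted;
#' inverse-variance weights enter only the final WLS fit.
#'
#' @param candidates `data.frame`/matrix of >= 2 numeric candidates.
#' @param slopes adjusted eGFR slopes.
#' @param cvFolds number of CV folds.
#' @param seed RNG seed controlling fold assignment.
#' @return character vector of selected variable names (may be empty, with
#'   a warning).
#' @export
lassoSelect <- function(candidates, slopes, cvFolds = 10L, seed = NULL) {
  X <- as.matrix(as.data.frame(candidates))
  if (ncol(X) < 2)
    stop("LASSO selection needs at least 2 candidate variables")
  ok <- stats::complete.cases(X, slopes)
  X <- X[ok, , drop = FALSE]
  y <- slopes[ok]
  withSeed(seed, {
    foldid <- sample(rep_len(seq_len(cvFolds), length(y)))
    cv <- glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                            standardize = TRUE)
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
    sel <- names(co)[co != 0]
    if (!length(sel))
      warning("all LASSO coefficients are zero at the selected penalty")
    sel
  })
}

#' Inverse-variance-weighted progression base model
#'
#' Weighted least squares of the adjusted eGFR slope on the selected
#' variables, with weights \eqn{w_i = 1/v_i} (the inverse conditional
#' variance of each subject's BLUP slope), so subjects with noisier slopes
#' count less. AIC is computed from the weighted Gaussian log-likelihood
#' with the weights treated as known precisions (k = parameters + 1 for the
#' residual variance); R-squared values are on the weighted scale.
#'
#' @param data `data.frame` holding the response and predictors.
#' @param response name of the response column.
#' @param variables character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param weights positive finite weights, one per row.
#' @return list of class `ProgressionModel`: `fit` (the `lm`), `variables`,
#'   `coefficients`, `aic`, `r_squared`, `adj_r_squared`, `n`, `weights`.
#' @export
fitBaseModel <- function(data, response, variables, weights) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  form <- stats::reformulate(if (length(variables)) variables else "1",
                             response = response)
  data <- as.data.frame(data)
  data$.w <- weights
  fit <- stats::lm(form, data = data, weights = .w)
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  structure(list(fit = fit, variables = variables,
                 coefficients = stats::coef(fit),
                 aic = stats::AIC(fit),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = nrow(data), weights = weights,
                 response = response, data = data),
            class = "ProgressionModel")
}

#' @export
print.ProgressionModel <- function(x, ...) {
  cat("Weighted CKD progression model:",
      deparse(stats::formula(x$fit)), "\n")
  cat(sprintf("  n = %d, AIC = %.2f, R2 = %.3f (adj %.3f)\n", x$n, x$aic,
              x$r_squared, x$adj_r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Per-feature augmentation of the progression model
#'
#' Adds each feature (CpG probe M-values, or gene expression) individually
#' to the base model together with the technical covariates (methylation
#' batch and bisulfite conversion efficiency), refits with the same
#' inverse-variance weights, and records the feature coefficient and
#' p-value, the augmented model's AIC, the BH-adjusted q across features,
#' and the `improves` flag: q below `qLevel` AND AIC below the base model's
#' AIC. All AICs share the weighted-Gaussian likelihood convention of
#' [fitBaseModel()], so the comparison against the base AIC is meaningful.
#'
#' @param base a `ProgressionModel` from [fitBaseModel()].
#' @param features features-by-subjects matrix aligned with the base-model
#'   rows by column name.
#' @param extraCovariates optional `data.frame` of technical covariates
#'   added alongside every feature (e.g. batch, bisulfite efficiency).
#' @param qLevel BH threshold entering the `improves` flag.
#' @param onCollinear `"error"` (default) stops when a feature is collinear
#'   with the design; `"skip"` flags and skips it.
#' @return `data.frame(feature_id, coefficient, p, q, aic, improves)` plus
#'   the reference AIC in `attr(, "base_aic")`.
#' @export
featureAugmentation <- function(base, features, extraCovariates = NULL,
                                qLevel = 0.05,
                                onCollinear = c("error", "skip")) {
  onCollinear <- match.arg(onCollinear)
  features <- as.matrix(features)
  data <- base$data
  ids <- rownames(data)
  byName <- !is.null(ids) && !is.null(colnames(features)) &&
    all(ids %in% colnames(features))
  if (byName) {
    features <- features[, ids, drop = FALSE]
  } else if (ncol(features) != nrow(data)) {
    # without shared ids the columns must already be in base-model row order
    stop("feature matrix columns must cover the base-model subjects ",
         "(match by column name or supply one column per model row)")
  }
  X0 <- stats::model.matrix(
    stats::reformulate(if (length(base$variables)) base$variables else "1"),
    data = data)
  if (!is.null(extraCovariates)) {
    extraCovariates <- as.data.frame(extraCovariates)
    Xe <- stats::model.matrix(stats::reformulate(names(extraCovariates)),
                              data = extraCovariates)[, -1, drop = FALSE]
    X0 <- cbind(X0, Xe)
  }
  y <- data[[base$response]]
  w <- base$weights
  n <- length(y)
  baseAic <- base$aic
  coefI <- ncol(X0) + 1L
  out <- lapply(rownames(features), function(fid) {
    f <- features[fid, ]
    # constant features carry no information; features with masked entries
    # would change n and break the AIC comparison, so both are skipped
    if (anyNA(f) || stats::var(f) == 0)
      return(data.frame(feature_id = fid, coefficient = NA_real_,
                        p = NA_real_, aic = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    X <- cbind(X0, feature = f)
    if (qr(X)$rank < ncol(X)) {
      if (onCollinear == "error")
        stop("feature '", fid, "' is collinear with the model design")
      return(data.frame(feature_id = fid, coefficient = NA_real_,
                        p = NA_real_, aic = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm.wfit(X, y, w)
    dfres <- n - fit$rank
    rw <- sqrt(w) * fit$residuals
    sigma2 <- sum(rw^2) / dfres
    XtWXinv <- chol2inv(chol(crossprod(sqrt(w) * X)))
    se <- sqrt(sigma2 * XtWXinv[coefI, coefI])
    tval <- fit$coefficients[coefI] / se
    data.frame(feature_id = fid, coefficient = fit$coefficients[coefI],
               p = 2 * stats::pt(-abs(tval), dfres),
               aic = .wlsAic(fit$residuals, w, fit$rank), skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- NA_real_
  ok <- !res$skipped
  # stable probe-id order breaks ties at equal p
  res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$improves <- !is.na(res$q) & res$q < qLevel & !is.na(res$aic) &
    res$aic < baseAic
  attr(res, "base_aic") <- baseAic
  res
}

# AIC of a weighted Gaussian fit with weights as known precisions; matches
# stats::AIC on an lm fitted with the same weights
.wlsAic <- function(residuals, w, rank) {
  n <- length(residuals)
  rss <- sum(w * residuals^2)
  ll <- 0.5 * (sum(log(w)) - n * (log(2 * pi) + 1 - log(n) + log(rss)))
  -2 * ll + 2 * (rank + 1)
}

#' Type II ANOVA variance partition
#'
#' Percent of the (weighted) total sum of squares attributable to each
#' model variable, computed from conditional sums of squares: for each
#' variable, SS = RSS(model without that variable) - RSS(full model), which
#' for an additive model is the Type II decomposition. Percentages need not
#' sum to 100; the residual share is reported alongside.
#'
#' @param model a `ProgressionModel`.
#' @return `data.frame(variable, ss, percent)` with the residual row last.
#' @export
variancePartition <- function(model) {
  fit <- model$fit
  data <- model$data
  w <- model$weights
  y <- data[[model$response]]
  terms <- attr(stats::terms(fit), "term.labels")
  rssFull <- sum(w * stats::residuals(fit)^2)
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  rows <- lapply(terms, function(v) {
    others <- setdiff(terms, v)
    form <- stats::reformulate(if (length(others)) others else "1",
                               response = model$response)
    red <- stats::lm(form, data = data, weights = w)
    ss <- sum(w * stats::residuals(red)^2) - rssFull
    data.frame(variable = v, ss = ss, percent = 100 * ss / tss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(variable = "residual", ss = rssFull,
               percent = 100 * rssFull / tss, stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Screen, select and fit the progression base model in one call
#'
#' Convenience wrapper chaining [univariateScreen()], [lassoSelect()] and
#' [fitBaseModel()], with an option to force additional variables (e.g.
#' hypertension) into the final model regardless of selection.
#'
#' @param candidates `data.frame` of candidate variables.
#' @param slopes adjusted eGFR slopes.
#' @param weights inverse-variance weights.
#' @param alpha univariate screening threshold.
#' @param cvFolds,seed passed to [lassoSelect()].
#' @param force variables forced into the model.
#' @return list with `screen`, `selected`, and `model`.
#' @export
buildProgressionModel <- function(candidates, slopes, weights, alpha = 0.05,
                                  cvFolds = 10L, seed = NULL,
                                  force = character()) {
  screen <- univariateScreen(candidates, slopes, alpha)
  kept <- screen$variable[screen$kept]
  selected <- if (length(kept) >= 2) {
    lassoSelect(candidates[, kept, drop = FALSE], slopes, cvFolds, seed)
  } else kept
  finalVars <- union(selected, force)
  data <- cbind(data.frame(adjusted_slope = slopes), candidates)
  model <- fitBaseModel(data, "adjusted_slope", finalVars, weights)
  list(screen = screen, selected = selected, model = model)
}
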