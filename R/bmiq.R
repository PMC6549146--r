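# ---- three-state beta-mixture EM ------------------------------------------
#
# Fits an unmethylated / hemimethylated / methylated (U/H/M) three-component
# beta mixture to one sample's beta values. The M-step is moment-matching:
# component shapes are recovered from the responsibility-weighted mean and
# variance, which is fast and stable for the well-separated mixtures that
# arise on methylation arrays. Components are kept ordered by mean.

.betaShapes <- function(mu, v) {
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  v <- pmin(pmax(v, 1e-6), mu * (1 - mu) * 0.999)
  common <- mu * (1 - mu) / v - 1
  list(a = mu * common, b = (1 - mu) * common)
}

.fitBetaMixture <- function(x, k = 3L, maxIter = 500L, tol = 1e-6) {
  x <- clipBeta(x[!is.na(x)], 1e-4)
  n <- length(x)
  # k-means initialization on beta values, clusters ordered by mean
  centers <- sort(stats::quantile(x, probs = seq(0.1, 0.9, length.out = k)))
  if (anyDuplicated(centers))
    centers <- centers + seq(0, 1e-4, length.out = k)
  km <- stats::kmeans(x, centers = centers, iter.max = 50)
  ord <- order(km$centers)
  cl <- match(km$cluster, ord)
  w <- as.numeric(table(factor(cl, levels = seq_len(k)))) / n
  mu <- vapply(seq_len(k), function(j) mean(x[cl == j]), 0)
  v <- vapply(seq_len(k), function(j) {
    xx <- x[cl == j]
    if (length(xx) > 1) stats::var(xx) else 1e-4
  }, 0)
  mu[is.na(mu)] <- seq(0.1, 0.9, length.out = k)[is.na(mu)]
  v[is.na(v) | v == 0] <- 1e-4
  sh <- .betaShapes(mu, v)
  ll0 <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dbeta(x, sh$a[j], sh$b[j]), numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    w <- colMeans(resp)
    w <- pmax(w, 1e-6); w <- w / sum(w)
    muOld <- mu
    mu <- colSums(resp * x) / colSums(resp)
    v <- colSums(resp * (x - rep(mu, each = n))^2) / colSums(resp)
    sh <- .betaShapes(mu, v)
    if ((is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) ||
        max(abs(mu - muOld)) < 1e-10) {
      return(list(w = w, a = sh$a, b = sh$b, mu = mu, loglik = ll,
                  iterations = it, converged = TRUE))
    }
    ll0 <- ll
  }
  stop("beta-mixture EM did not converge within ", maxIter, " iterations")
}

# posterior-argmax class boundaries on a fine grid; returns the two
# cutpoints separating U/H and H/M regions
.classCutpoints <- function(fit) {
  g <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  post <- vapply(1:3, function(j)
    fit$w[j] * stats::dbeta(g, fit$a[j], fit$b[j]), numeric(length(g)))
  cls <- max.col(post)
  # enforce monotone class sequence along the grid
  cls <- cummax(cls)
  t1 <- if (any(cls >= 2)) g[min(which(cls >= 2))] else 1 - 1e-4
  t2 <- if (any(cls == 3)) g[min(which(cls == 3))] else 1 - 1e-4
  c(t1, t2)
}

#' Beta-mixture quantile normalization of type II probes
#'
#' Corrects the compressed dynamic range of Infinium type II probes by
#' mapping their value distribution onto the type I distribution, one sample
#' at a time. Per sample, three-state (unmethylated / hemimethylated /
#' methylated) beta mixtures are fitted by EM separately to the type I and
#' type II probes. Type II probes are assigned to states by maximum
#' posterior; U-state and M-state values are re-expressed as quantiles of
#' the corresponding type II component and mapped through the inverse CDF of
#' the matching type I component, while H-state values are rescaled by
#' monotone linear interpolation between the mapped U/M boundaries. Type I
#' values are returned unchanged. The map is monotone within each sample,
#' so the rank order of type II probes is preserved.
#'
#' @param mset a [MethylSet-class] (or a beta matrix when `manifest` is
#'   supplied).
#' @param manifest probe manifest; taken from `mset` when omitted.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   tolerance; non-convergence is an error naming the sample.
#' @return object of the same class as the input with normalized beta
#'   values in \code{[0, 1]}.
#' @export
#' @examples
#' man <- simulateManifest(600, seed = 4)
#' sim <- simulateCohort(man, nSamples = 6, seed = 4)
#' norm <- bmiqNormalize(sim$mset)
bmiqNormalize <- function(mset, manifest = NULL, maxIter = 500L, tol = 1e-6) {
  isSet <- is(mset, "MethylSet")
  beta <- if (isSet) betaValues(mset) else as.matrix(mset)
  if (is.null(manifest)) {
    if (!isSet) stop("a manifest is required when normalizing a bare matrix")
    manifest <- probeManifest(mset)
  }
  manifest <- manifest[match(rownames(beta), manifest$probe_id), ]
  isII <- manifest$design_type == "II"
  if (!any(isII) || all(isII))
    stop("both Infinium design types must be present")
  out <- beta
  for (s in seq_len(ncol(beta))) {
    fitI <- tryCatch(.fitBetaMixture(beta[!isII, s], maxIter = maxIter,
                                     tol = tol),
                     error = function(e) stop("type I EM failed for sample ",
                                              colnames(beta)[s], ": ",
                                              conditionMessage(e)))
    fitII <- tryCatch(.fitBetaMixture(beta[isII, s], maxIter = maxIter,
                                      tol = tol),
                      error = function(e) stop("type II EM failed for sample ",
                                               colnames(beta)[s], ": ",
                                               conditionMessage(e)))
    out[isII, s] <- .bmiqMapSample(beta[isII, s], fitI, fitII)
  }
  if (isSet) {
    assays(mset)$beta <- out
    metadata(mset)$normalization <- list(method = "bmiq", tol = tol,
                                         maxIter = maxIter)
    mset
  } else out
}

.bmiqMapSample <- function(x, fitI, fitII) {
  cut2 <- .classCutpoints(fitII)
  t1 <- cut2[1]; t2 <- cut2[2]
  mapU <- function(v) stats::qbeta(stats::pbeta(clipBeta(v, 1e-4),
                                                fitII$a[1], fitII$b[1]),
                                   fitI$a[1], fitI$b[1])
  mapM <- function(v) stats::qbeta(stats::pbeta(clipBeta(v, 1e-4),
                                                fitII$a[3], fitII$b[3]),
                                   fitI$a[3], fitI$b[3])
  yL <- mapU(t1)
  yR <- mapM(t2)
  if (yR < yL) { mid <- (yL + yR) / 2; yL <- mid; yR <- mid }
  y <- x
  isU <- !is.na(x) & x < t1
  isM <- !is.na(x) & x >= t2
  isH <- !is.na(x) & !isU & !isM
  y[isU] <- pmin(mapU(x[isU]), yL)
  y[isM] <- pmax(mapM(x[isM]), yR)
  if (any(isH)) {
    if (t2 > t1) {
      y[isH] <- yL + (x[isH] - t1) / (t2 - t1) * (yR - yL)
    } else y[isH] <- (yL + yR) / 2
  }
  pmin(pmax(y, 0), 1)
}
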