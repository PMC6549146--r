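#' Logit-2 transform of beta values (M-values)
#'
#' Methylation beta values are heteroscedastic near 0 and 1; regression is
#' carried out on the M scale, \code{M = log2(beta / (1 - beta))}. Beta values
#' are clipped to \code{[1e-6, 1 - 1e-6]} before the transform so M is always
#' finite.
#'
#' @param beta numeric vector or matrix of beta values in \code{[0, 1]}.
#' @return M-values with the same shape as the input.
#' @seealso [mToBeta()] for the inverse transform.
#' @export
#' @examples
#' betaToM(c(0.2, 0.5, 0.8))  # -2 0 2
betaToM <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  log2(clipBeta(beta) / (1 - clipBeta(beta)))
}

#' Inverse logit-2 transform (M-values to beta values)
#'
#' @param m numeric vector or matrix of M-values.
#' @return beta values in \code{[0, 1]}.
#' @export
mToBeta <- function(m) {
  2^m / (1 + 2^m)
}

# clip beta away from {0, 1} so the logit is finite; bound matches the
# documented M-transform convention
clipBeta <- function(beta, eps = 1e-6) {
  pmin(pmax(beta, eps), 1 - eps)
}

# evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# stable sub-seed derivation: keeps derived seeds positive and < 2^31
subSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 7919L + as.integer(offset)) %% 2147483587L
}

stopIfNotUnique <- function(x, what) {
  if (anyDuplicated(x))
    stop("duplicated ", what, ": ",
         paste(unique(x[duplicated(x)])[seq_len(min(5, sum(duplicated(x))))],
               collapse = ", "))
  invisible(x)
}
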