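.statePriority <- c("promoter", "enhancer", "transcribed", "inactive")

#' Annotate probes with chromatin states
#'
#' Assigns each probe the regulatory state (promoter / enhancer /
#' transcribed / inactive) of the interval containing its position in the
#' requested tissue's chromatin-state map. Overlap ties are resolved by the
#' fixed priority promoter > enhancer > transcribed > inactive; probes on
#' chromosomes absent from the map, or covered by no interval, default to
#' inactive (a warning notes absent chromosomes).
#'
#' @param manifest probe manifest (1-based positions).
#' @param states [GenomicRanges::GRanges] with metadata columns `state` and
#'   (optionally) `tissue`, e.g. from [simulateChromStates()] or
#'   [readStateBed()].
#' @param tissue tissue label to subset `states` by; `NULL` uses all
#'   records.
#' @return named factor, probe id to state.
#' @export
annotateProbes <- function(manifest, states, tissue = NULL) {
  if (!is.null(tissue) && "tissue" %in% names(S4Vectors::mcols(states)))
    states <- states[states$tissue == tissue]
  probes <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1L))
  absent <- setdiff(unique(manifest$chrom),
                    as.character(unique(GenomicRanges::seqnames(states))))
  if (length(absent))
    warning("no state intervals on: ", paste(absent, collapse = ", "),
            "; probes there default to inactive")
  ann <- rep("inactive", nrow(manifest))
  hits <- GenomicRanges::findOverlaps(probes, states)
  if (length(hits)) {
    hitState <- states$state[S4Vectors::subjectHits(hits)]
    pr <- match(hitState, .statePriority)
    best <- tapply(seq_along(pr), S4Vectors::queryHits(hits),
                   function(i) i[which.min(pr[i])])
    ann[as.integer(names(best))] <- hitState[unlist(best)]
  }
  factor(stats::setNames(ann, manifest$probe_id), levels = .statePriority)
}

#' Fisher exact enrichment of a probe set in a chromatin state
#'
#' Builds the 2x2 table of significant vs background probes inside vs
#' outside the given state -- with the significant set removed from the
#' background cells so the table is disjoint -- and reports the odds ratio
#' `ad/bc`, its Woolf 95% confidence interval
#' \eqn{\exp(\ln OR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})}, and the
#' two-sided Fisher exact p-value.
#'
#' @param significant probe ids of the significant set (must be a subset of
#'   `background`).
#' @param background probe ids of all probes used in the association
#'   analysis.
#' @param annotation named state factor from [annotateProbes()].
#' @param state state to test (default `"enhancer"`).
#' @return one-row `data.frame`: `state, a, b, c, d, odds_ratio, ci_lo,
#'   ci_hi, p, degenerate`.
#' @export
#' @examples
#' ann <- factor(setNames(rep(c("enhancer", "inactive"), c(30, 970)),
#'                        paste0("p", 1:1000)), levels = .statePriority)
#' fisherEnrichment(paste0("p", 1:40), paste0("p", 1:1000), ann)
fisherEnrichment <- function(significant, background, annotation,
                             state = "enhancer") {
  if (!all(significant %in% background))
    stop("the significant set must be a subset of the background")
  bgOnly <- setdiff(background, significant)
  inState <- names(annotation)[annotation == state]
  a <- sum(significant %in% inState)
  b <- length(significant) - a
  cc <- sum(bgOnly %in% inState)
  d <- length(bgOnly) - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(data.frame(state = state, a = a, b = b, c = cc, d = d,
                      odds_ratio = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, p = 1, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  orr <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  data.frame(state = state, a = a, b = b, c = cc, d = d,
             odds_ratio = orr,
             ci_lo = exp(log(orr) - 1.96 * se),
             ci_hi = exp(log(orr) + 1.96 * se),
             p = p, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Resampling fold-change distribution across tissues
#'
#' For each tissue, compares the number of significant probes falling in
#' that tissue's enhancer regions against random draws of the same size
#' from the background: per draw, `fold = observed / draw_count` (draws
#' with zero enhancer probes are excluded from the quantiles and counted).
#' The boxplot-style summary is the median with quartiles and 1.5 x IQR
#' whiskers.
#'
#' @param significant significant probe ids (size k).
#' @param background background probe ids (k <= |background|; draws are
#'   without replacement).
#' @param annotations named list of state factors (one per tissue) from
#'   [annotateProbes()].
#' @param nDraws number of resampling draws (>= 100).
#' @param state state defining membership.
#' @param seed RNG seed.
#' @return `data.frame` per tissue: `tissue, observed, median_fold, q1, q3,
#'   whisker_lo, whisker_hi, n_zero_draws`; all draw-level folds are kept in
#'   `attr(, "draws")`.
#' @export
resampleFoldChange <- function(significant, background, annotations,
                               nDraws = 10000L, state = "enhancer",
                               seed = NULL) {
  if (nDraws < 100L)
    stop("nDraws must be at least 100 for stable quantiles")
  k <- length(significant)
  if (k > length(background))
    stop("significant set larger than the background")
  withSeed(seed, {
    drawsOut <- list()
    rows <- lapply(names(annotations), function(tissue) {
      ann <- annotations[[tissue]]
      member <- stats::setNames(ann == state, names(ann))
      observed <- sum(member[significant], na.rm = TRUE)
      counts <- vapply(seq_len(nDraws), function(i)
        sum(member[sample(background, k)], na.rm = TRUE), 0L)
      fold <- ifelse(counts == 0L, NA_real_, observed / counts)
      qs <- stats::quantile(fold, c(0.25, 0.5, 0.75), na.rm = TRUE,
                            names = FALSE)
      iqr <- qs[3] - qs[1]
      drawsOut[[tissue]] <<- fold
      data.frame(tissue = tissue, observed = observed, median_fold = qs[2],
                 q1 = qs[1], q3 = qs[3],
                 whisker_lo = qs[1] - 1.5 * iqr,
                 whisker_hi = qs[3] + 1.5 * iqr,
                 n_zero_draws = sum(counts == 0L),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "draws") <- drawsOut
    out
  })
}
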