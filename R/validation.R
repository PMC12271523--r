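# Statistical comparison machinery: reference normalization, the maximum
# visible spread (MVS) score with its significance thresholds, per-region
# length/proportion comparisons and projection-ratio reports.

#' Normalize values against a reference sample
#'
#' \code{V_norm(a) = (median(P_r) - V(a)) / sd(P_r)} — note the printed
#' orientation (reference median minus value), so the reference median maps
#' to 0 and a value one reference standard deviation *below* the median maps
#' to +1.
#'
#' @param values numeric vector to normalize.
#' @param reference the reference sample P_r.
#' @return normalized values.
#' @export
normalizeToReference <- function(values, reference) {
  s <- stats::sd(reference)
  if (!is.finite(s) || s == 0) stop("reference sample has zero standard deviation")
  (stats::median(reference) - values) / s
}

#' Maximum visible spread (MVS) score between two samples
#'
#' \code{|median(P) - median(Q)| / max(spread(P), spread(Q))} with spread =
#' half the 5th-95th percentile range (window configurable). When both
#' spreads are zero the score is 0 for equal medians and +Inf otherwise.
#' Smaller is more similar: < 0.1 flags strong significance (\code{"**"}),
#' < 0.5 non-randomness (\code{"*"}).
#'
#' @param p,q non-empty numeric samples.
#' @param probs percentile window for the spread.
#' @return the score (>= 0).
#' @export
mvsScore <- function(p, q, probs = c(0.05, 0.95)) {
  if (!length(p) || !length(q)) stop("empty sample")
  spread <- function(v) diff(stats::quantile(v, probs, names = FALSE)) / 2
  s <- max(spread(p), spread(q))
  dm <- abs(stats::median(p) - stats::median(q))
  if (s == 0) {
    if (dm == 0) 0 else Inf
  } else dm / s
}

#' Significance flag for an MVS score
#' @param mvs score from [mvsScore()].
#' @return "**" (strong, < 0.1), "*" (non-random, < 0.5) or "".
#' @export
mvsFlag <- function(mvs) {
  ifelse(mvs < 0.1, "**", ifelse(mvs < 0.5, "*", ""))
}

#' Compare per-region axon lengths between two populations
#'
#' For each region: the fraction of axons terminating there in each
#' population, the MVS score between the length distributions (over axons
#' with positive length in the region) with its significance flag, and the
#' total length normalized by population size.
#'
#' @param bio,synth stacked features ([stackPopulation()]) of the reference
#'   (biological) and test (synthesized) populations.
#' @param regions regions to report; default the union of both vocabularies.
#' @return data.frame with one row per region.
#' @export
compareRegionLengths <- function(bio, synth, regions = NULL) {
  tB <- SummarizedExperiment::assay(bio, "terminals")
  lB <- SummarizedExperiment::assay(bio, "lengths")
  tS <- SummarizedExperiment::assay(synth, "terminals")
  lS <- SummarizedExperiment::assay(synth, "lengths")
  if (is.null(regions)) regions <- sort(union(rownames(tB), rownames(tS)))
  rows <- lapply(regions, function(b) {
    vB <- if (b %in% rownames(lB)) lB[b, ] else numeric(ncol(lB))
    vS <- if (b %in% rownames(lS)) lS[b, ] else numeric(ncol(lS))
    nB <- if (b %in% rownames(tB)) sum(tB[b, ] > 0) else 0L
    nS <- if (b %in% rownames(tS)) sum(tS[b, ] > 0) else 0L
    pB <- vB[vB > 0]; pS <- vS[vS > 0]
    mvs <- if (length(pB) && length(pS)) mvsScore(pB, pS) else NA_real_
    data.frame(region = b,
               frac_bio = nB / ncol(tB), frac_synth = nS / ncol(tS),
               n_bio = nB, n_synth = nS,
               mvs = mvs, flag = if (is.na(mvs)) "" else mvsFlag(mvs),
               total_per_axon_bio = sum(vB) / ncol(lB),
               total_per_axon_synth = sum(vS) / ncol(lS))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Projection ratio per region
#'
#' The proportion of axons targeting each region (terminal count > 0).
#' Contralateral targets are separate vocabulary entries
#' (\code{"<acronym>_contra"}), so the ipsi/contra split is explicit.
#'
#' @param se stacked features from [stackPopulation()].
#' @param regions regions to report; default the full vocabulary.
#' @return data.frame: region, ratio, n_targeting, n_axons.
#' @export
projectionRatio <- function(se, regions = NULL) {
  tMat <- SummarizedExperiment::assay(se, "terminals")
  if (ncol(tMat) < 1L) stop("empty population")
  if (is.null(regions)) regions <- rownames(tMat)
  counts <- vapply(regions, function(b)
    if (b %in% rownames(tMat)) sum(tMat[b, ] > 0) else 0L, 0L)
  data.frame(region = regions, ratio = counts / ncol(tMat),
             n_targeting = counts, n_axons = ncol(tMat), row.names = NULL)
}

#' Write a comparison report as CSV + JSON
#' @param report data.frame from [compareRegionLengths()].
#' @param path base path (writes \code{<path>.csv} and \code{<path>.json}).
#' @export
writeComparisonReport <- function(report, path) {
  utils::write.csv(report, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(report, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
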