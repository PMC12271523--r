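# Reference bookkeeping tables of the isocortex long-range axon synthesis
# campaign: the published per-subregion counts of biological input axons and
# the morphology intake by data source with its exclusion counts. Shipped as
# data so totals are always recomputed from the printed tables rather than
# hard-coded.

#' Per-subregion counts of biological input axons (isocortex campaign)
#'
#' The number of reconstructed long-range axons used as clustering input for
#' each isocortex subregion in the reference whole-brain campaign.
#'
#' @return named integer vector, one entry per subregion acronym.
#' @export
isocortexInputAxonCounts <- function() {
  c(MOp = 159L, MOs = 393L, SSp = 488L, SSs = 97L, VISC = 8L, VIS = 83L,
    AUD = 26L, ECT = 4L, GU = 11L, ORB = 24L, ACA = 40L, RSP = 46L,
    FRP = 7L, PL = 8L, TEa = 10L, PTLp = 26L, AI = 42L)
}

#' Total biological input axons for the isocortex campaign
#' @return sum of [isocortexInputAxonCounts()].
#' @export
inputAxonTotal <- function() {
  sum(isocortexInputAxonCounts())
}

#' Morphology intake by source, with exclusion counts
#'
#' Counts of long-range axon reconstructions entering the workflow from its
#' three data sources, and the exclusions: morphologies that failed the
#' repair (sanitization) stage and morphologies that failed the axonal
#' projection analysis (out of bounds or faulty axons).
#'
#' @return list with \code{sources} (named integer vector),
#'   \code{repair_excluded} and \code{projection_excluded}.
#' @export
morphologyIntake <- function() {
  list(sources = c(mouselight = 1084L, whole_brain_set = 1741L,
                   collaboration_set = 800L),
       repair_excluded = 16L,
       projection_excluded = 8L)
}

#' Total morphologies used after exclusions
#' @return intake total minus repair and projection-analysis exclusions.
#' @export
usedMorphologyTotal <- function() {
  intake <- morphologyIntake()
  sum(intake$sources) - intake$repair_excluded - intake$projection_excluded
}
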