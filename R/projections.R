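# Per-axon projection features: terminal counts and path lengths per target
# region, grouped by source region.

#' Compute the projection features of one axon
#'
#' Terminal counts \code{t}: the number of axon leaves whose position maps to
#' each region at the chosen hierarchy level. Path lengths \code{l}: summed
#' arc length of axon segments whose midpoints map to each region (segment
#' membership by midpoint; no splitting at voxel boundaries), restricted by
#' default to termination regions (regions with at least one terminal) —
#' pass-through length is discarded, configurably included. Contralateral
#' targets (terminal on the opposite hemisphere from the soma) are encoded by
#' suffixing the acronym with \code{"_contra"} so ipsi/contra targeting
#' survives clustering.
#'
#' @param m a \linkS4class{Morphology} with an axon.
#' @param atlas a \linkS4class{BrainAtlas}; the soma must be inside it.
#' @param level hierarchy depth or "leaf".
#' @param contra tag contralateral regions with a "_contra" suffix.
#' @param includePassThrough keep length in regions without terminals.
#' @param includeSomaRegion count terminals landing in the soma's own
#'   (ipsilateral) region.
#' @return a list of class \code{ProjectionFeatures} with elements
#'   \code{neuronId}, \code{sourceRegion}, \code{somaHemisphere},
#'   \code{vocab}, \code{terminals}, \code{lengths}, \code{level}; or
#'   \code{NULL} (with a warning) when the soma is outside the atlas, so
#'   population code can log and skip such cells.
#' @export
computeProjectionFeatures <- function(m, atlas, level = "leaf", contra = TRUE,
                                      includePassThrough = FALSE,
                                      includeSomaRegion = TRUE) {
  soma <- somaCenter(m)
  sourceRegion <- regionAt(atlas, soma, level)
  if (is.na(sourceRegion)) {
    warning("soma of '", neuronId(m), "' outside the annotated atlas; axon excluded")
    return(NULL)
  }
  somaHemi <- hemisphereOf(atlas, soma)
  leaves <- neuriteLeaves(m, "axon")
  if (!nrow(leaves)) stop("morphology '", neuronId(m), "' has no axon")
  labels <- regionLabels(atlas, as.matrix(leaves[, c("x", "y", "z")]), level,
                         somaHemi, contra)
  labels <- labels[!is.na(labels)]
  tTab <- table(labels)
  if (!includeSomaRegion) tTab <- tTab[names(tTab) != sourceRegion]
  terminationRegions <- names(tTab)

  segs <- axonSegments(m)
  segLabels <- regionLabels(atlas, as.matrix(segs[, c("mx", "my", "mz")]), level,
                            somaHemi, contra)
  keep <- !is.na(segLabels)
  lenTab <- tapply(segs$len[keep], segLabels[keep], sum)
  if (!includePassThrough) lenTab <- lenTab[names(lenTab) %in% terminationRegions]

  vocab <- sort(unique(c(terminationRegions,
                         if (includePassThrough) names(lenTab))))
  terminals <- stats::setNames(integer(length(vocab)), vocab)
  terminals[names(tTab)] <- as.integer(tTab)
  lengths <- stats::setNames(numeric(length(vocab)), vocab)
  lengths[names(lenTab)] <- as.numeric(lenTab)
  structure(list(neuronId = neuronId(m), sourceRegion = sourceRegion,
                 somaHemisphere = somaHemi, vocab = vocab,
                 terminals = terminals, lengths = lengths, level = level),
            class = "ProjectionFeatures")
}

# Region acronyms with hemisphere suffixing relative to the soma hemisphere.
regionLabels <- function(atlas, xyz, level, somaHemi, contra) {
  acr <- regionAt(atlas, xyz, level)
  if (!contra) return(acr)
  ok <- !is.na(acr)
  if (any(ok)) {
    hemi <- hemisphereOf(atlas, xyz[ok, , drop = FALSE])
    acr[ok] <- ifelse(hemi == somaHemi, acr[ok], paste0(acr[ok], "_contra"))
  }
  acr
}

# Axon segments of a morphology: endpoints, midpoint, length, arc position of
# the segment start along its section, and section id. The stem segment from
# the soma to the axon root is excluded (consistent with morphometrics).
axonSegments <- function(m, type = SWC_AXON) {
  nodes <- morphNodes(m)
  nr <- neuriteRows(nodes, type)
  if (!length(nr$rows)) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                      mx = numeric(0), my = numeric(0), mz = numeric(0),
                      len = numeric(0), radius = numeric(0),
                      arc = numeric(0), section = integer(0)))
  }
  parentIdx <- match(nodes$parent, nodes$id)
  rows <- setdiff(nr$rows, nr$roots)      # child node of each segment
  p <- parentIdx[rows]
  secs <- neuriteSections(nodes, type)
  secOf <- integer(nrow(nodes))
  for (s in seq_along(secs$chains)) {
    ch <- secs$chains[[s]]
    secOf[ch[-1L]] <- s                    # first chain element is upstream node
  }
  pd <- neuritePathDistances(nodes, type)
  data.frame(x1 = nodes$x[p], y1 = nodes$y[p], z1 = nodes$z[p],
             x2 = nodes$x[rows], y2 = nodes$y[rows], z2 = nodes$z[rows],
             mx = (nodes$x[p] + nodes$x[rows]) / 2,
             my = (nodes$y[p] + nodes$y[rows]) / 2,
             mz = (nodes$z[p] + nodes$z[rows]) / 2,
             len = sqrt((nodes$x[rows] - nodes$x[p])^2 +
                          (nodes$y[rows] - nodes$y[p])^2 +
                          (nodes$z[rows] - nodes$z[p])^2),
             radius = nodes$radius[rows],
             arc = pd[p], section = secOf[rows])
}

#' Stack a population of projection features into a SummarizedExperiment
#'
#' The region vocabulary is the fixed-order union of the regions observed
#' across the population of one source region; missing entries are 0. The
#' result has assays \code{terminals} (counts) and \code{lengths}
#' (micrometres), rows = regions, columns = axons, with the source region
#' and soma hemisphere in \code{colData}.
#'
#' @param features list of \code{ProjectionFeatures} (NULL entries, from
#'   excluded axons, are dropped).
#' @param source optional source-region filter; with the default NULL all
#'   features must share one source region (mixed sources are an error).
#' @return a \code{SummarizedExperiment}.
#' @export
stackPopulation <- function(features, source = NULL) {
  features <- Filter(Negate(is.null), features)
  if (!is.null(source)) {
    features <- Filter(function(f) f$sourceRegion == source, features)
  }
  if (!length(features)) stop("empty population")
  sources <- vapply(features, `[[`, "", "sourceRegion")
  if (length(unique(sources)) > 1L) {
    stop("mixed source regions: ", paste(unique(sources), collapse = ", "),
         "; stack one source region at a time")
  }
  levels <- unique(lapply(features, `[[`, "level"))
  if (length(levels) > 1L) stop("features computed at different hierarchy levels")
  vocab <- sort(unique(unlist(lapply(features, `[[`, "vocab"))))
  n <- length(features)
  tMat <- matrix(0L, length(vocab), n, dimnames = list(vocab, NULL))
  lMat <- matrix(0, length(vocab), n, dimnames = list(vocab, NULL))
  for (j in seq_len(n)) {
    f <- features[[j]]
    tMat[f$vocab, j] <- f$terminals
    lMat[f$vocab, j] <- f$lengths
  }
  ids <- vapply(features, `[[`, "", "neuronId")
  colnames(tMat) <- colnames(lMat) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(terminals = tMat, lengths = lMat),
    colData = S4Vectors::DataFrame(
      neuron_id = ids,
      source_region = sources,
      soma_hemisphere = vapply(features, `[[`, "", "somaHemisphere"),
      row.names = ids),
    metadata = list(level = levels[[1L]]))
}

#' Export / import stacked projection features as wide CSV + JSON vocabulary
#'
#' One row per axon; feature columns are \code{t.<region>} and
#' \code{l.<region>}. A JSON sidecar records the vocabulary and level.
#'
#' @param se a SummarizedExperiment from [stackPopulation()].
#' @param path CSV path; the sidecar is \code{<path>.vocab.json}.
#' @export
writeProjectionFeatures <- function(se, path) {
  tMat <- SummarizedExperiment::assay(se, "terminals")
  lMat <- SummarizedExperiment::assay(se, "lengths")
  cd <- SummarizedExperiment::colData(se)
  df <- data.frame(neuron_id = cd$neuron_id, source_region = cd$source_region,
                   soma_hemisphere = cd$soma_hemisphere,
                   t(rbind(tMat, lMat)), check.names = FALSE)
  names(df)[-(1:3)] <- c(paste0("t.", rownames(tMat)), paste0("l.", rownames(lMat)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(vocab = rownames(tMat),
                            level = S4Vectors::metadata(se)$level),
                       paste0(path, ".vocab.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProjectionFeatures
#' @export
readProjectionFeatures <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".vocab.json"), simplifyVector = TRUE)
  vocab <- side$vocab
  tMat <- t(as.matrix(df[, paste0("t.", vocab), drop = FALSE]))
  lMat <- t(as.matrix(df[, paste0("l.", vocab), drop = FALSE]))
  rownames(tMat) <- rownames(lMat) <- vocab
  colnames(tMat) <- colnames(lMat) <- df$neuron_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(terminals = tMat, lengths = lMat),
    colData = S4Vectors::DataFrame(neuron_id = df$neuron_id,
                                   source_region = df$source_region,
                                   soma_hemisphere = df$soma_hemisphere,
                                   row.names = df$neuron_id),
    metadata = list(level = side$level))
}
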