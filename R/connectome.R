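# Proximity-based connectivity: touch detection between axon and dendrite
# segments (spatial-hash accelerated, identical to the all-pairs
# computation), inter-bouton filtering, density pruning and aggregation to
# neuron adjacency / region projectome.

#' Detect axo-dendritic touches by segment proximity
#'
#' All (axon segment, dendrite segment) pairs of distinct neurons whose
#' minimal segment-segment distance is at most the touch distance. The touch
#' point is the midpoint of the closest-approach segment. Candidate pairs
#' are generated with a uniform spatial hash over segment midpoints, with a
#' cell size guaranteeing the result is identical to the brute-force
#' all-pairs computation (verified by the test-suite oracle).
#'
#' @param preMorphs list of presynaptic \linkS4class{Morphology} (axons).
#' @param postMorphs list of postsynaptic \linkS4class{Morphology}
#'   (dendrites: basal + apical).
#' @param touchDistance threshold, micrometres; the default \code{NULL} uses
#'   per-pair \code{r_axon + r_dendrite + 1}.
#' @return data.frame of candidate touches: pre, post, x, y, z, arc (axon
#'   arc-length position), branch (axon section), dist.
#' @export
detectTouches <- function(preMorphs, postMorphs, touchDistance = NULL) {
  preSegs <- do.call(rbind, lapply(preMorphs, function(m) {
    s <- axonSegments(m, SWC_AXON)
    if (nrow(s)) s$neuron <- neuronId(m)
    s
  }))
  postSegs <- do.call(rbind, lapply(postMorphs, function(m) {
    s <- rbind(axonSegments(m, SWC_BASAL), axonSegments(m, SWC_APICAL))
    if (nrow(s)) s$neuron <- neuronId(m)
    s
  }))
  if (is.null(preSegs) || is.null(postSegs) || !nrow(preSegs) || !nrow(postSegs)) {
    return(emptyTouches())
  }
  dmax <- if (is.null(touchDistance))
    max(preSegs$radius) + max(postSegs$radius) + 1 else touchDistance
  cell <- dmax + max(preSegs$len, postSegs$len)
  key <- function(s) {
    floor(cbind(s$mx, s$my, s$mz) / cell)
  }
  kPre <- key(preSegs); kPost <- key(postSegs)
  postKeyStr <- paste(kPost[, 1], kPost[, 2], kPost[, 3])
  postBuckets <- split(seq_len(nrow(postSegs)), postKeyStr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pairsPre <- integer(0); pairsPost <- integer(0)
  for (o in seq_len(nrow(offs))) {
    kk <- sweep(kPre, 2L, offs[o, ], "+")
    hit <- postBuckets[paste(kk[, 1], kk[, 2], kk[, 3])]
    lens <- lengths(hit)
    if (!any(lens > 0)) next
    pairsPre <- c(pairsPre, rep(seq_len(nrow(preSegs)), lens))
    pairsPost <- c(pairsPost, unlist(hit, use.names = FALSE))
  }
  if (!length(pairsPre)) return(emptyTouches())
  touchesFromPairs(preSegs, postSegs, pairsPre, pairsPost, touchDistance)
}

emptyTouches <- function() {
  data.frame(pre = character(0), post = character(0), x = numeric(0),
             y = numeric(0), z = numeric(0), arc = numeric(0),
             branch = integer(0), dist = numeric(0))
}

# Exact distance test on candidate (pre segment, post segment) index pairs.
touchesFromPairs <- function(preSegs, postSegs, pi, qi, touchDistance) {
  samecell <- preSegs$neuron[pi] == postSegs$neuron[qi]
  pi <- pi[!samecell]; qi <- qi[!samecell]
  if (!length(pi)) return(emptyTouches())
  P1 <- as.matrix(preSegs[pi, c("x1", "y1", "z1")])
  P2 <- as.matrix(preSegs[pi, c("x2", "y2", "z2")])
  Q1 <- as.matrix(postSegs[qi, c("x1", "y1", "z1")])
  Q2 <- as.matrix(postSegs[qi, c("x2", "y2", "z2")])
  cp <- segSegClosest(P1, P2, Q1, Q2)
  thr <- if (is.null(touchDistance))
    preSegs$radius[pi] + postSegs$radius[qi] + 1 else touchDistance
  keep <- cp$dist <= thr
  if (!any(keep)) return(emptyTouches())
  out <- data.frame(pre = preSegs$neuron[pi][keep],
                    post = postSegs$neuron[qi][keep],
                    x = cp$mid[keep, 1], y = cp$mid[keep, 2], z = cp$mid[keep, 3],
                    arc = preSegs$arc[pi][keep] + cp$s[keep] * preSegs$len[pi][keep],
                    branch = preSegs$section[pi][keep],
                    dist = cp$dist[keep])
  # one candidate pair can enter through several hash cells: dedupe
  dup <- duplicated(data.frame(pi = pi[keep], qi = qi[keep]))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force all-pairs touch detection (oracle)
#'
#' Same contract as [detectTouches()] but enumerating every segment pair;
#' used as the independent oracle in tests.
#'
#' @inheritParams detectTouches
#' @export
detectTouchesBruteForce <- function(preMorphs, postMorphs, touchDistance = NULL) {
  preSegs <- do.call(rbind, lapply(preMorphs, function(m) {
    s <- axonSegments(m, SWC_AXON)
    if (nrow(s)) s$neuron <- neuronId(m)
    s
  }))
  postSegs <- do.call(rbind, lapply(postMorphs, function(m) {
    s <- rbind(axonSegments(m, SWC_BASAL), axonSegments(m, SWC_APICAL))
    if (nrow(s)) s$neuron <- neuronId(m)
    s
  }))
  if (is.null(preSegs) || is.null(postSegs) || !nrow(preSegs) || !nrow(postSegs)) {
    return(emptyTouches())
  }
  idx <- expand.grid(pi = seq_len(nrow(preSegs)), qi = seq_len(nrow(postSegs)))
  touchesFromPairs(preSegs, postSegs, idx$pi, idx$qi, touchDistance)
}

# Vectorized closest approach between segment sets P1->P2 and Q1->Q2
# (standard clamped quadratic; Ericson, Real-Time Collision Detection).
segSegClosest <- function(P1, P2, Q1, Q2) {
  d1 <- P2 - P1; d2 <- Q2 - Q1; r <- P1 - Q1
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2); f <- rowSums(d2 * r)
  c_ <- rowSums(d1 * r); b <- rowSums(d1 * d2)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-12, pmin(1, pmax(0, (b * f - c_ * e) / denom)), 0)
  t <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  # clamp t, then recompute s for clamped t
  tC <- pmin(1, pmax(0, t))
  redo <- tC != t
  s <- ifelse(redo & a > 1e-12, pmin(1, pmax(0, (b * tC - c_) / a)), s)
  t <- tC
  cp1 <- P1 + d1 * s
  cp2 <- Q1 + d2 * t
  diff <- cp1 - cp2
  list(dist = sqrt(rowSums(diff * diff)), mid = (cp1 + cp2) / 2, s = s, t = t)
}

#' Enforce a minimum inter-bouton interval along each axon branch
#'
#' Greedy scan per (pre neuron, axon branch) in increasing arc length: a
#' touch is kept iff it lies at least \code{interval} beyond the last kept
#' touch.
#'
#' @param touches data.frame from [detectTouches()].
#' @param interval minimum inter-bouton interval, micrometres.
#' @return the filtered touches.
#' @export
filterInterbouton <- function(touches, interval = 5) {
  if (!nrow(touches) || interval <= 0) return(touches)
  grp <- paste(touches$pre, touches$branch)
  keep <- logical(nrow(touches))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    rows <- rows[order(touches$arc[rows])]
    last <- -Inf
    for (rI in rows) {
      if (touches$arc[rI] - last >= interval) {
        keep[rI] <- TRUE
        last <- touches$arc[rI]
      }
    }
  }
  touches[keep, , drop = FALSE]
}

#' Prune touches to a physiological synapse density
#'
#' Per postsynaptic neuron: when the candidate count exceeds
#' \code{density * dendritic length}, a uniform random subset of that size
#' is kept; reproducible per seed.
#'
#' @param touches data.frame of touches.
#' @param density synapses per micrometre of dendrite.
#' @param dendriticLengths named numeric vector: total dendritic length per
#'   post neuron.
#' @param seed optional integer seed.
#' @return the pruned touches (synapses).
#' @export
pruneToDensity <- function(touches, density, dendriticLengths, seed = NULL) {
  if (!nrow(touches)) return(touches)
  withSeed(seed, {
    keep <- logical(nrow(touches))
    for (p in unique(touches$post)) {
      rows <- which(touches$post == p)
      cap <- floor(density * dendriticLengths[[p]])
      if (length(rows) <= cap) keep[rows] <- TRUE
      else if (cap > 0) keep[sample(rows, cap)] <- TRUE
    }
    touches[keep, , drop = FALSE]
  })
}

#' Aggregate synapses into an AxonConnectome
#'
#' Builds the neuron adjacency (pre x post synapse counts) and the region
#' projectome (pre soma region -> synapse region, at the requested hierarchy
#' level).
#'
#' @param synapses data.frame of synapses (from the pruning step).
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param level hierarchy depth or "leaf".
#' @param preSomaRegions named character vector: soma region per pre neuron.
#' @return an \linkS4class{AxonConnectome}.
#' @export
buildConnectome <- function(synapses, atlas, level = "leaf", preSomaRegions) {
  postRegion <- if (nrow(synapses))
    regionAt(atlas, as.matrix(synapses[, c("x", "y", "z")]), level) else character(0)
  synapses$post_region <- postRegion
  preRegion <- preSomaRegions[synapses$pre]
  ok <- !is.na(preRegion) & !is.na(postRegion)
  if (any(!ok)) message(sum(!ok), " synapse(s) outside annotated voxels dropped")
  synapses <- synapses[ok, , drop = FALSE]
  preRegion <- preRegion[ok]; postRegion <- postRegion[ok]
  preNeurons <- sort(unique(synapses$pre))
  postNeurons <- sort(unique(synapses$post))
  adj <- Matrix::sparseMatrix(
    i = match(synapses$pre, preNeurons), j = match(synapses$post, postNeurons),
    x = rep(1, nrow(synapses)), dims = c(length(preNeurons), length(postNeurons)),
    dimnames = list(preNeurons, postNeurons))
  regs <- sort(unique(c(preRegion, postRegion)))
  proj <- Matrix::sparseMatrix(
    i = match(preRegion, regs), j = match(postRegion, regs),
    x = rep(1, nrow(synapses)), dims = c(length(regs), length(regs)),
    dimnames = list(regs, regs))
  new("AxonConnectome", synapses = synapses, adjacency = adj,
      projectome = proj, level = level)
}

#' Out-degree per presynaptic neuron
#'
#' By default the number of distinct postsynaptic partners; the synapse-count
#' variant returns total synapses instead.
#'
#' @param connectome an \linkS4class{AxonConnectome}.
#' @param variant "partners" (default) or "synapses".
#' @return named integer vector.
#' @export
outDegree <- function(connectome, variant = c("partners", "synapses")) {
  variant <- match.arg(variant)
  adj <- connectome@adjacency
  if (variant == "partners") Matrix::rowSums(adj > 0) else Matrix::rowSums(adj)
}

#' Connections per region versus border distance to a source region
#'
#' @param connectome an \linkS4class{AxonConnectome}.
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param sourceRegion acronym of the source region.
#' @return data.frame: region, connections, border_distance.
#' @export
connectionsVsBorderDistance <- function(connectome, atlas, sourceRegion) {
  syn <- connectome@synapses
  counts <- table(syn$post_region)
  data.frame(region = names(counts), connections = as.integer(counts),
             border_distance = vapply(names(counts), function(r)
               borderDistance(atlas, sourceRegion, stripContra(r)), 0),
             row.names = NULL)
}

#' Connections per region versus axon length in the region
#'
#' Synapse locations are absolute regions while feature rows are
#' soma-relative (contralateral targets carry a \code{"_contra"} suffix), so
#' feature rows are folded onto their base acronym before comparison.
#'
#' @param connectome an \linkS4class{AxonConnectome}.
#' @param se stacked projection features of the presynaptic axons.
#' @return data.frame: region, connections, axon_length.
#' @export
connectionsVsLength <- function(connectome, se) {
  lMat <- SummarizedExperiment::assay(se, "lengths")
  base <- stripContra(rownames(lMat))
  lens <- tapply(rowSums(lMat), base, sum)
  regions <- sort(unique(base))
  counts <- table(factor(connectome@synapses$post_region, levels = regions))
  data.frame(region = regions, connections = as.integer(counts),
             axon_length = as.numeric(lens[regions]), row.names = NULL)
}

#' Export a connectome as CSV + MTX + acronym index
#'
#' @param connectome an \linkS4class{AxonConnectome}.
#' @param dir output directory.
#' @export
writeConnectome <- function(connectome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(connectome@synapses, file.path(dir, "synapses.csv"),
                   row.names = FALSE)
  Matrix::writeMM(connectome@adjacency, file.path(dir, "adjacency.mtx"))
  Matrix::writeMM(connectome@projectome, file.path(dir, "projectome.mtx"))
  jsonlite::write_json(list(pre_neurons = rownames(connectome@adjacency),
                            post_neurons = colnames(connectome@adjacency),
                            regions = rownames(connectome@projectome)),
                       file.path(dir, "index.json"))
  invisible(dir)
}
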