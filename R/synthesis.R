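# Long-range axon synthesis: cluster assignment, target selection, trunk
# post-processing, barcode-driven tuft growth and whole-population synthesis.

#' Draw a GMM cluster for a source point
#'
#' Categorical draw over the mixture weights; reproducible per seed.
#'
#' @param model a \linkS4class{ProjectionGMM}.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return integer cluster indices.
#' @export
assignCluster <- function(model, n = 1L, seed = NULL) {
  withSeed(seed, sample.int(length(model@weights), n, replace = TRUE,
                            prob = model@weights))
}

#' Target-selection statistics of a clustered population
#'
#' For each (cluster, region): the probability of an axon targeting the
#' region (member axons with at least one terminal there, divided by the
#' cluster size) and the tuft-count statistics from the tuft library groups
#' (mean and standard deviation of per-axon tuft counts; a region without a
#' tuft group falls back to mean 1, sd 0).
#'
#' @param se stacked features from [stackPopulation()].
#' @param clusters named integer vector: cluster per neuron id (hard
#'   assignments, e.g. from [classifyAxons()]).
#' @param library a \code{TuftLibrary} from [buildTuftLibrary()].
#' @return data.frame with columns cluster, region, prob, mean_count,
#'   sd_count, n_members.
#' @export
targetStatistics <- function(se, clusters, library) {
  tMat <- SummarizedExperiment::assay(se, "terminals")
  ids <- colnames(tMat)
  cl <- clusters[ids]
  out <- list()
  for (c in sort(unique(cl))) {
    members <- which(cl == c)
    sizeC <- length(members)
    sub <- tMat[, members, drop = FALSE]
    nTargeting <- rowSums(sub > 0)
    for (b in rownames(sub)[nTargeting > 0]) {
      grp <- library$groups[library$groups$cluster == c & library$groups$region == b, ]
      out[[length(out) + 1L]] <- data.frame(
        cluster = c, region = b, prob = nTargeting[[b]] / sizeC,
        mean_count = if (nrow(grp)) grp$mean_count[1L] else 1,
        sd_count = if (nrow(grp)) sqrt(grp$var_count[1L]) else 0,
        n_members = sizeC)
    }
  }
  do.call(rbind, out)
}

#' Choose target regions and points for one axon
#'
#' Each candidate region of the assigned cluster is included independently
#' with its targeting probability; if no region is selected after
#' \code{retryBound} redraws, the highest-probability region is taken
#' deterministically. Per selected region, the number of target points is
#' drawn from Normal(mean, sd) of the group's tuft counts, rounded to the
#' nearest integer and clamped to >= 1, and the points are placed uniformly
#' inside the region (\code{"_contra"}-suffixed regions resolve to the
#' hemisphere opposite the soma).
#'
#' @param stats data.frame from [targetStatistics()] (any cluster mix).
#' @param cluster the assigned cluster.
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param somaHemisphere "left" or "right".
#' @param seed optional integer seed.
#' @param retryBound redraw bound before the deterministic fallback.
#' @return data.frame with columns region, cluster, x, y, z.
#' @export
chooseTargets <- function(stats, cluster, atlas, somaHemisphere,
                          seed = NULL, retryBound = 10L) {
  cand <- stats[stats$cluster == cluster, , drop = FALSE]
  if (!nrow(cand)) stop("cluster ", cluster, " has no member axons")
  withSeed(seed, {
    sel <- integer(0)
    for (try in seq_len(retryBound)) {
      sel <- which(stats::runif(nrow(cand)) < cand$prob)
      if (length(sel)) break
    }
    if (!length(sel)) sel <- which.max(cand$prob)
    out <- list()
    for (i in sel) {
      Tb <- max(1L, round(stats::rnorm(1L, cand$mean_count[i], cand$sd_count[i])))
      hemi <- regionHemisphere(cand$region[i], somaHemisphere)
      pts <- samplePointInRegion(atlas, stripContra(cand$region[i]), n = Tb,
                                 hemisphere = hemi)
      out[[length(out) + 1L]] <- data.frame(region = cand$region[i],
                                            cluster = cluster,
                                            x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }
    do.call(rbind, out)
  })
}

stripContra <- function(region) sub("_contra$", "", region)

isContra <- function(region) grepl("_contra$", region)

regionHemisphere <- function(region, somaHemisphere) {
  if (isContra(region)) {
    if (somaHemisphere == "left") "right" else "left"
  } else somaHemisphere
}

#' Post-process a Steiner trunk into a morphology with realistic curvature
#'
#' Each tree path is resampled at the given step. The direction emitted at
#' each point is the normalized blend
#' \code{(1 - n - r) * (direction to the next tree waypoint) + r * (previous
#' emitted direction) + n * (unit Gaussian noise)}: random noise roughens the
#' local geometry while local history smooths the curvature. Endpoints
#' (source, targets and branch points) are preserved exactly, so tortuosity
#' per section is >= 1 and grows with the noise weight.
#'
#' @param tree result of [steinerTree()].
#' @param sg the \code{SteinerGraph} the tree was computed on.
#' @param step resampling step, micrometres.
#' @param noiseWeight noise weight n (0 <= n, n + r < 1).
#' @param historyWeight history weight r.
#' @param seed optional integer seed.
#' @param radius constant radius for emitted nodes (diameter synthesis is
#'   out of scope).
#' @param atlas optional \linkS4class{BrainAtlas}: when given, each lattice
#'   waypoint chain is first straightened by greedy line-of-sight
#'   simplification (shortcuts kept only when the chord stays inside the
#'   brain), removing lattice discretization artifacts (zig-zag and
#'   snap-vertex doglegs) before resampling.
#' @return list with \code{morphology} (a \linkS4class{Morphology}: soma
#'   node at the source followed by the axon trunk), \code{targetNodes}
#'   (data.frame: vertex, node id, incoming direction).
#' @export
postprocessTrunk <- function(tree, sg, step = 50, noiseWeight = 0.1,
                             historyWeight = 0.2, seed = NULL, radius = 0.5,
                             atlas = NULL) {
  if (noiseWeight < 0 || historyWeight < 0 || noiseWeight + historyWeight >= 1) {
    stop("need 0 <= n, r and n + r < 1")
  }
  coords <- sg$coords
  parent <- tree$parent
  withSeed(seed, {
    # decompose the tree into root->leaf paths of waypoints between forks
    childMap <- split(as.integer(names(parent)[!is.na(parent)]),
                      parent[!is.na(parent)])
    nKids <- function(v) length(childMap[[as.character(v)]])
    src <- sg$sourceV
    nodes <- data.frame(id = 1L, parent = -1L, type = SWC_SOMA,
                        x = coords[src, 1], y = coords[src, 2], z = coords[src, 3],
                        radius = 5)
    nextId <- 2L
    targetNodes <- list()
    emit <- function(xyz, parentId) {
      nodes[nrow(nodes) + 1L, ] <<- list(nextId, parentId, SWC_AXON,
                                         xyz[1], xyz[2], xyz[3], radius)
      nextId <<- nextId + 1L
      nextId - 1L
    }
    # stack of (vertex, attached node id, incoming direction)
    stack <- list(list(v = src, node = 1L, dir = NULL))
    while (length(stack)) {
      e <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      kids <- childMap[[as.character(e$v)]]
      for (kv in kids) {
        # waypoint chain: kv, then follow single-child vertices
        chain <- kv
        # a chain ends at a fork, a leaf, or a target vertex (so every
        # target gets an attachment node even when the trunk runs through it)
        while (nKids(chain[length(chain)]) == 1L &&
               !(chain[length(chain)] %in% sg$targetV)) {
          chain <- c(chain, childMap[[as.character(chain[length(chain)])]])
        }
        way <- coords[c(e$v, chain), , drop = FALSE]
        if (!is.null(atlas)) way <- simplifyChain(way, atlas)
        res <- resamplePath(way, step, noiseWeight, historyWeight, e$dir)
        parentId <- e$node
        pts <- res$points
        for (q in seq(2L, nrow(pts))) {
          parentId <- emit(pts[q, ], parentId)
        }
        endV <- chain[length(chain)]
        if (endV %in% sg$targetV) {
          targetNodes[[length(targetNodes) + 1L]] <- data.frame(
            vertex = endV, node = parentId,
            dx = res$dir[1], dy = res$dir[2], dz = res$dir[3])
        }
        stack[[length(stack) + 1L]] <- list(v = endV, node = parentId, dir = res$dir)
      }
    }
    morph <- Morphology(nodes, "trunk")
    list(morphology = morph,
         targetNodes = if (length(targetNodes)) do.call(rbind, targetNodes) else
           data.frame(vertex = integer(0), node = integer(0), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0)))
  })
}

# Greedy line-of-sight simplification of a waypoint polyline: from each
# anchor, jump to the farthest waypoint whose connecting chord stays inside
# annotated brain voxels. Endpoints always survive.
simplifyChain <- function(way, atlas) {
  n <- nrow(way)
  if (n <= 2L) return(way)
  keep <- 1L
  a <- 1L
  while (a < n) {
    b <- n
    while (b > a + 1L && !chordInBrain(way[a, ], way[b, ], atlas)) b <- b - 1L
    keep <- c(keep, b)
    a <- b
  }
  way[keep, , drop = FALSE]
}

chordInBrain <- function(p, q, atlas) {
  nS <- max(2L, ceiling(vecNorm(q - p) / (atlas@voxelSize / 2)) + 1L)
  ts <- seq(0, 1, length.out = nS)
  pts <- cbind(p[1] + ts * (q[1] - p[1]), p[2] + ts * (q[2] - p[2]),
               p[3] + ts * (q[3] - p[3]))
  ids <- annotationAt(atlas, worldToVoxel(atlas, pts))
  !any(is.na(ids) | ids == 0L)
}

# Resample a waypoint polyline at the given step with noise + history
# blending; first and last waypoints preserved exactly.
resamplePath <- function(way, step, n, r, dirIn = NULL) {
  pos <- way[1L, ]
  pts <- rbind(pos)
  j <- 2L
  prevDir <- if (is.null(dirIn)) unitVector(way[2L, ] - pos) else dirIn
  nWay <- nrow(way)
  guard <- 0L
  maxSteps <- 50L * (sum(sqrt(rowSums(diff(way)^2))) / step + nWay + 10L)
  while (TRUE) {
    # advance the waypoint cursor past waypoints closer than one step
    while (j < nWay && vecNorm(way[j, ] - pos) < step) j <- j + 1L
    rem <- vecNorm(way[nWay, ] - pos)
    if (j == nWay && rem <= step) {
      pts <- rbind(pts, way[nWay, ])
      prevDir <- unitVector(way[nWay, ] - pos)
      break
    }
    aim <- unitVector(way[j, ] - pos)
    newDir <- unitVector((1 - n - r) * aim + r * prevDir + n * stats::rnorm(3L))
    pos <- pos + step * newDir
    pts <- rbind(pts, pos)
    prevDir <- newDir
    guard <- guard + 1L
    if (guard > maxSteps) {               # noise stalled progress: snap home
      pts <- rbind(pts, way[nWay, ])
      prevDir <- unitVector(way[nWay, ] - pts[nrow(pts) - 1L, ])
      break
    }
  }
  rownames(pts) <- NULL
  list(points = pts, dir = prevDir)
}

#' Grow a tuft from a persistence barcode
#'
#' Simplified barcode-driven growth: one active tip starts at the root and
#' walks with direction persistence plus Gaussian noise; when a tip passes
#' the birth path distance of an unassigned bar a sibling tip spawns there
#' (bar assigned), and a tip terminates exactly at its bar's death distance.
#' The resulting leaf count equals the bar count and terminal path distances
#' land within one step of the death values.
#'
#' @param barcode matrix with columns birth, death (micrometres).
#' @param root 3-vector, tuft root position.
#' @param initialDirection growth direction at the root (e.g. the incoming
#'   trunk direction at the target point).
#' @param step growth step, micrometres.
#' @param noise direction noise weight (>= 0).
#' @param seed optional integer seed.
#' @param radius constant node radius.
#' @param startId first node id to use (for grafting onto a trunk).
#' @param rootParent parent id of the root node (-1 for a free fragment).
#' @param inside optional predicate \code{function(xyz) -> logical}
#'   constraining growth to the target region: candidate directions whose
#'   next position leaves the region are redrawn (bounded tries, then the
#'   tip deterministically steers back towards the tuft root). Keeps leaf
#'   counts and terminal path distances unchanged.
#' @return a \linkS4class{Morphology} fragment rooted at \code{root} (or a
#'   plain node table when grafting, with \code{rootParent} set).
#' @export
growTuft <- function(barcode, root, initialDirection = c(1, 0, 0), step = 20,
                     noise = 0.3, seed = NULL, radius = 0.5, startId = 1L,
                     rootParent = -1L, inside = NULL) {
  barcode <- rbind(barcode)
  if (!nrow(barcode)) stop("empty barcode")
  if (any(barcode[, 2] <= barcode[, 1]) || any(barcode[, 1] < 0)) {
    stop("malformed barcode: need death > birth >= 0")
  }
  ord <- order(barcode[, 1], -barcode[, 2])
  bars <- barcode[ord, , drop = FALSE]
  if (bars[1L, 1] > 0) stop("malformed barcode: no bar born at distance 0")
  withSeed(seed, {
    nodes <- data.frame(id = startId, parent = rootParent, type = SWC_AXON,
                        x = root[1], y = root[2], z = root[3], radius = radius)
    nextId <- startId + 1L
    assigned <- logical(nrow(bars))
    emit <- function(xyz, parentId) {
      nodes[nrow(nodes) + 1L, ] <<- list(nextId, parentId, SWC_AXON,
                                         xyz[1], xyz[2], xyz[3], radius)
      nextId <<- nextId + 1L
      nextId - 1L
    }
    # direction proposal with optional region containment
    steer <- function(dir, pos, len, spread) {
      for (try in 1:8) {
        cand <- unitVector(dir + spread * stats::rnorm(3L))
        if (is.null(inside) || inside(pos + len * cand)) return(cand)
      }
      unitVector(root - pos)               # deterministic steer back inside
    }
    # branch stack: (bar index, current path distance, position, node, dir)
    assigned[1L] <- TRUE
    stack <- list(list(bar = 1L, pd = bars[1L, 1], pos = root, node = startId,
                       dir = unitVector(initialDirection)))
    while (length(stack)) {
      br <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      pd <- br$pd; pos <- br$pos; nodeId <- br$node; dir <- br$dir
      death <- bars[br$bar, 2]
      repeat {
        nb <- which(!assigned & bars[, 1] <= pd + step & bars[, 1] < death)
        if (length(nb)) {
          nb <- nb[1L]
          # advance exactly to the sibling's birth distance and fork there
          d <- bars[nb, 1] - pd
          if (d > 1e-9) {
            if (!is.null(inside) && !inside(pos + d * dir)) {
              dir <- unitVector(root - pos)
            }
            pos <- pos + d * dir
            pd <- bars[nb, 1]
            nodeId <- emit(pos, nodeId)
          }
          assigned[nb] <- TRUE
          sibDir <- steer(dir, pos, step, 1)
          stack[[length(stack) + 1L]] <- list(bar = nb, pd = pd, pos = pos,
                                              node = nodeId, dir = sibDir)
          next
        }
        if (pd + step >= death) {
          leg <- death - pd
          endp <- pos + leg * dir
          if (!is.null(inside) && leg > 1e-9 && !inside(endp)) {
            endp <- pos + leg * unitVector(root - pos)
          }
          emit(endp, nodeId)
          break
        }
        dir <- steer(dir, pos, step, noise)
        pos <- pos + step * dir
        pd <- pd + step
        nodeId <- emit(pos, nodeId)
      }
    }
    if (rootParent == -1L) Morphology(nodes, "tuft") else nodes
  })
}

#' Synthesize a population of long-range axons
#'
#' Per task (one pyramidal-cell soma): assign a GMM cluster, choose target
#' regions and points, route the trunk with the weighted Steiner tree on the
#' atlas lattice, post-process the trunk, then grow a tuft at every target
#' point, selecting the tuft from the library group (cluster, region) with
#' probability proportional to the representativity scores. A missing group
#' falls back to the nearest region among the cluster's groups (logged).
#'
#' @param somata matrix of soma positions (one per row) or data.frame with
#'   x, y, z (and optional neuron_id).
#' @param model a \linkS4class{ProjectionGMM} for the source region.
#' @param stats data.frame from [targetStatistics()].
#' @param library a \code{TuftLibrary}.
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param config list of synthesis parameters; see [synthesisConfig()].
#' @param seed master seed; per-neuron substreams are derived from it.
#' @return list with \code{morphologies} (list of \linkS4class{Morphology})
#'   and \code{manifest} (data.frame: neuron_id, cluster, n_targets,
#'   regions, seed).
#' @export
synthesizePopulation <- function(somata, model, stats, library, atlas,
                                 config = synthesisConfig(), seed = 1L) {
  somata <- as.data.frame(rbind(somata))
  names(somata)[1:3] <- c("x", "y", "z")
  if (is.null(somata$neuron_id)) {
    somata$neuron_id <- sprintf("synth_%04d", seq_len(nrow(somata)))
  }
  lattice <- makeLatticeGraph(atlas, config$latticeStep, config$alpha)
  morphologies <- list()
  manifest <- list()
  for (i in seq_len(nrow(somata))) {
    si <- deriveSeed(seed, "axon", i)
    soma <- as.numeric(somata[i, c("x", "y", "z")])
    res <- synthesizeAxon(soma, model, stats, library, atlas, config,
                          seed = si, lattice = lattice,
                          neuronId = somata$neuron_id[i])
    morphologies[[length(morphologies) + 1L]] <- res$morphology
    manifest[[length(manifest) + 1L]] <- data.frame(
      neuron_id = somata$neuron_id[i], cluster = res$cluster,
      n_targets = nrow(res$targets),
      regions = paste(unique(res$targets$region), collapse = ";"), seed = si)
  }
  list(morphologies = morphologies, manifest = do.call(rbind, manifest))
}

#' Default synthesis configuration
#'
#' @param latticeStep lattice stride, voxels.
#' @param alpha fiber-tract edge discount in (0, 1].
#' @param trunkStep trunk resampling step, micrometres.
#' @param noiseWeight,historyWeight trunk curvature weights (n + r < 1).
#' @param tuftStep,tuftNoise tuft growth step and direction noise.
#' @param radius constant neurite radius, micrometres.
#' @param retryBound target-selection redraw bound.
#' @return named list of parameters.
#' @export
synthesisConfig <- function(latticeStep = 2L, alpha = 0.5, trunkStep = 50,
                            noiseWeight = 0.1, historyWeight = 0.2,
                            tuftStep = 20, tuftNoise = 0.3, radius = 0.5,
                            retryBound = 10L) {
  list(latticeStep = latticeStep, alpha = alpha, trunkStep = trunkStep,
       noiseWeight = noiseWeight, historyWeight = historyWeight,
       tuftStep = tuftStep, tuftNoise = tuftNoise, radius = radius,
       retryBound = retryBound)
}

#' Synthesize one long-range axon
#'
#' @inheritParams synthesizePopulation
#' @param soma source point (3-vector).
#' @param lattice optional precomputed lattice graph.
#' @param neuronId identifier for the synthesized cell.
#' @param seed integer seed for all stages of this axon.
#' @return list: \code{morphology}, \code{cluster}, \code{targets}.
#' @export
synthesizeAxon <- function(soma, model, stats, library, atlas,
                           config = synthesisConfig(), seed = 1L,
                           lattice = NULL, neuronId = "synth") {
  somaHemi <- hemisphereOf(atlas, soma)
  cluster <- assignCluster(model, seed = deriveSeed(seed, "cluster"))
  targets <- chooseTargets(stats, cluster, atlas, somaHemi,
                           seed = deriveSeed(seed, "targets"),
                           retryBound = config$retryBound)
  sg <- buildSteinerGraph(atlas, soma, as.matrix(targets[, c("x", "y", "z")]),
                          config$latticeStep, config$alpha, lattice = lattice)
  tree <- steinerTree(sg)
  post <- postprocessTrunk(tree, sg, step = config$trunkStep,
                           noiseWeight = config$noiseWeight,
                           historyWeight = config$historyWeight,
                           seed = deriveSeed(seed, "trunk"),
                           radius = config$radius, atlas = atlas)
  nodes <- morphNodes(post$morphology)
  # move the soma to the true source point and keep trunk endpoints at the
  # snapped lattice geometry
  nodes$x[1L] <- soma[1]; nodes$y[1L] <- soma[2]; nodes$z[1L] <- soma[3]
  nextId <- max(nodes$id) + 1L
  for (ti in seq_len(nrow(targets))) {
    vert <- sg$targetV[ti]
    tn <- post$targetNodes[post$targetNodes$vertex == vert, , drop = FALSE]
    if (!nrow(tn)) next
    tuft <- pickTuft(library, targets$cluster[ti], targets$region[ti],
                     atlas, seed = deriveSeed(seed, "pick", ti))
    if (is.null(tuft)) next
    frag <- growTuft(tuft$barcode, root = as.numeric(targets[ti, c("x", "y", "z")]),
                     initialDirection = c(tn$dx[1L], tn$dy[1L], tn$dz[1L]),
                     step = config$tuftStep, noise = config$tuftNoise,
                     seed = deriveSeed(seed, "grow", ti), radius = config$radius,
                     startId = nextId, rootParent = tn$node[1L],
                     inside = regionContainment(atlas, targets$region[ti], somaHemi))
    fragNodes <- if (is.data.frame(frag)) frag else morphNodes(frag)
    nextId <- max(fragNodes$id) + 1L
    nodes <- rbind(nodes, fragNodes)
  }
  list(morphology = Morphology(nodes, neuronId), cluster = cluster,
       targets = targets)
}

# Containment predicate for tuft growth: inside the (hemisphere-resolved)
# target region subtree. Tufts are grown within their target region, the
# mitigation suggested for tufts extending beyond intended areas; it also
# guarantees every selected region retains at least one terminal.
regionContainment <- function(atlas, region, somaHemisphere) {
  base <- stripContra(region)
  hemi <- regionHemisphere(region, somaHemisphere)
  ids <- hierDescendants(atlas@hierarchy, acronymToId(atlas, base))
  function(p) {
    id <- annotationAt(atlas, worldToVoxel(atlas, p))
    if (is.na(id) || !(id %in% ids)) return(FALSE)
    (p[atlas@midlineAxis] >= atlas@midline) == (hemi == "right")
  }
}

# Sample a tuft for a (cluster, region) group with probability proportional
# to representativity; fall back to the nearest region in the cluster.
pickTuft <- function(library, cluster, region, atlas, seed = NULL) {
  idx <- library$index
  rows <- which(idx$cluster == cluster & idx$region == region)
  if (!length(rows)) {
    regions <- unique(idx$region[idx$cluster == cluster])
    if (!length(regions)) {
      rows <- seq_len(nrow(idx))          # degenerate library: any tuft
    } else {
      dists <- vapply(regions, function(r)
        tryCatch(borderDistance(atlas, stripContra(region), stripContra(r)),
                 error = function(e) Inf), 0)
      fallback <- regions[which.min(dists)]
      message("no tuft group for cluster ", cluster, " region ", region,
              "; falling back to ", fallback)
      rows <- which(idx$cluster == cluster & idx$region == fallback)
    }
  }
  if (!length(rows)) return(NULL)
  w <- idx$score[rows]
  if (all(w <= 0)) w <- rep(1, length(rows))
  pick <- withSeed(seed, sample(rows, 1L, prob = w))
  library$tufts[[idx$tuft[pick]]]
}
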