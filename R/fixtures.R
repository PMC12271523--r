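# Synthetic-data generators: toy atlases and axon populations with known
# clusters, tufts and projection structure, so every stage of the pipeline
# is testable without external data.

#' Demo toy atlas
#'
#' A 32 x 16 x 16 voxel volume (100 um isotropic) with mirrored hemispheres
#' along the first axis: a presubiculum-like source region "PRE" plus seven
#' target regions grouped under two mid-level parents, one region ("RA")
#' split into two layer-like leaf children to exercise hierarchy lifting, a
#' connected background ("BG") and fiber corridors from the source towards
#' two targets.
#'
#' @param voxelSize voxel edge, micrometres.
#' @return a \linkS4class{BrainAtlas}.
#' @export
demoToyAtlas <- function(voxelSize = 100) {
  spec <- list(
    dims = c(32L, 16L, 16L), voxel_size = voxelSize, origin = c(0, 0, 0),
    mirror_axis = 1L, background = "BG",
    regions = list(
      list(acronym = "CTX", parent = "root"),
      list(acronym = "SUB", parent = "root"),
      list(acronym = "PRE", parent = "CTX", box = rbind(c(2, 5), c(2, 7), c(2, 7))),
      list(acronym = "RA", parent = "CTX"),
      list(acronym = "RA1", parent = "RA", box = rbind(c(8, 11), c(2, 7), c(2, 4))),
      list(acronym = "RA2", parent = "RA", box = rbind(c(8, 11), c(2, 7), c(5, 7))),
      list(acronym = "RB", parent = "CTX", box = rbind(c(13, 16), c(2, 7), c(2, 7))),
      list(acronym = "RC", parent = "SUB", box = rbind(c(8, 11), c(10, 15), c(2, 7))),
      list(acronym = "RD", parent = "SUB", box = rbind(c(13, 16), c(10, 15), c(2, 7))),
      list(acronym = "RE", parent = "SUB", box = rbind(c(2, 5), c(10, 15), c(2, 7))),
      list(acronym = "RF", parent = "SUB", box = rbind(c(8, 11), c(2, 7), c(10, 15))),
      list(acronym = "RG", parent = "SUB", box = rbind(c(13, 16), c(10, 15), c(10, 15)))),
    fibers = list(list(from = "PRE", to = "RA", radius = 2L),
                  list(from = "PRE", to = "RC", radius = 2L)))
  buildToyAtlas(spec)
}

#' Demo population specification
#'
#' A presubiculum-like population: 59 axons from source "PRE" drawn from 5
#' clusters with distinct target-region menus and per-region mean tuft
#' counts, mirroring the scale of the reference clustering demonstration
#' (5 clusters imposed over 59 axons). Cluster 5 targets the contralateral
#' "RB" to exercise hemisphere-aware targeting.
#'
#' @param n number of axons.
#' @return a population spec list for [generatePopulation()].
#' @export
demoPopulationSpec <- function(n = 59L) {
  # jitter 10 um on 60 um trunk segments gives ~8% tortuosity, the scale
  # reported for reconstructed axons (straight chords would be unrealistic)
  list(source = "PRE", n = as.integer(n), soma_hemisphere = "left",
       tuft_scale = 150, count_noise = 0, jitter = 10,
       clusters = list(
         list(weight = 0.25, targets = list(RA = 3, RB = 2)),
         list(weight = 0.20, targets = list(RC = 3)),
         list(weight = 0.20, targets = list(RD = 2, RE = 2)),
         list(weight = 0.20, targets = list(RF = 3)),
         list(weight = 0.15, targets = list(RG = 2, RB_contra = 2))))
}

#' Generate a synthetic axon population with known projection structure
#'
#' Per axon: a cluster is drawn by weight; the soma is placed uniformly in
#' the source region; a piecewise-linear trunk runs from the soma to points
#' sampled inside each of the cluster's target regions; a Y-shaped tuft of
#' the given length scale is attached at each point (two terminals per
#' tuft). Tuft placement is retried (up to 20 times) until the tuft's
#' leaves land inside the intended region, so at zero count noise the
#' terminal counts are exactly 2 x (tuft count); residual misses are
#' recorded in the ground truth.
#'
#' @param spec population spec, see [demoPopulationSpec()] for the format:
#'   \code{source}, \code{n}, cluster list (weight + named target list of
#'   mean tuft counts), \code{tuft_scale} (um), \code{count_noise} (sd of
#'   the per-region tuft count), \code{jitter} (trunk point noise, um),
#'   \code{soma_hemisphere} ("left", "right" or "both").
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param seed integer seed.
#' @return list with \code{morphologies} and \code{truth} (data.frame:
#'   neuron_id, cluster, region, tufts, terminals).
#' @export
generatePopulation <- function(spec, atlas, seed = 1L) {
  weights <- vapply(spec$clusters, `[[`, 0, "weight")
  if (abs(sum(weights) - 1) > 1e-9) stop("cluster weights must sum to 1")
  if (spec$n < 1L) stop("need n >= 1 axons")
  tuftScale <- if (is.null(spec$tuft_scale)) 150 else spec$tuft_scale
  countNoise <- if (is.null(spec$count_noise)) 0 else spec$count_noise
  jitter <- if (is.null(spec$jitter)) 0 else spec$jitter
  hemiSpec <- if (is.null(spec$soma_hemisphere)) "left" else spec$soma_hemisphere
  morphs <- list(); truth <- list()
  for (i in seq_len(spec$n)) {
    si <- deriveSeed(seed, "fixture", i)
    res <- withSeed(si, {
      cl <- sample.int(length(weights), 1L, prob = weights)
      hemi <- if (hemiSpec == "both") sample(c("left", "right"), 1L) else hemiSpec
      soma <- samplePointInRegion(atlas, spec$source, hemisphere = hemi)[1L, ]
      generateAxon(soma, hemi, cl, spec$clusters[[cl]]$targets, atlas,
                   tuftScale, countNoise, jitter,
                   sprintf("bio_%03d", i))
    })
    morphs[[length(morphs) + 1L]] <- res$morphology
    truth[[length(truth) + 1L]] <- res$truth
  }
  list(morphologies = morphs, truth = do.call(rbind, truth))
}

# One fixture axon. The trunk is a greedy nearest-point insertion tree of
# straight polylines over {soma, tuft points} (each unconnected tuft point
# attaches by a chord to the nearest already-connected point), emulating a
# cable-minimizing branching trunk without touching the package's
# lattice/Steiner machinery; V tufts are attached at the tuft points.
generateAxon <- function(soma, somaHemi, cluster, targets, atlas, tuftScale,
                         countNoise, jitter, id, trunkStep = 60) {
  nodes <- data.frame(id = 1L, parent = -1L, type = SWC_SOMA,
                      x = soma[1], y = soma[2], z = soma[3], radius = 5)
  nextId <- 2L
  truth <- list()
  addPolyline <- function(from, to, parentId, type = SWC_AXON) {
    len <- vecNorm(to - from)
    nSeg <- max(1L, ceiling(len / trunkStep))
    for (q in seq_len(nSeg)) {
      p <- from + (to - from) * q / nSeg
      if (q < nSeg && jitter > 0) p <- p + stats::rnorm(3L, 0, jitter)
      nodes[nrow(nodes) + 1L, ] <<- list(nextId, parentId, type, p[1], p[2], p[3], 0.5)
      parentId <- nextId
      nextId <<- nextId + 1L
    }
    parentId
  }
  # sample tuft points (with fit retries) for every region first
  pts <- list()
  for (region in names(targets)) {
    k <- max(1L, round(stats::rnorm(1L, targets[[region]], countNoise)))
    placed <- 0L
    for (t in seq_len(k)) {
      hemi <- regionHemisphere(region, somaHemi)
      base <- stripContra(region)
      tp <- NULL; legs <- NULL
      for (try in 1:20) {                  # retry until the tuft fits the region
        cand <- samplePointInRegion(atlas, base, hemisphere = hemi)[1L, ]
        g <- yTuftGeometry(cand, tuftScale)
        labels <- regionAt(atlas, rbind(g$leaf1, g$leaf2), "leaf")
        h <- atlas@hierarchy
        lifted <- vapply(labels, function(a) {
          if (is.na(a)) return(NA_character_)
          anc <- hierAncestors(h, acronymToId(atlas, a))
          if (acronymToId(atlas, base) %in% anc) base else a
        }, "")
        if (!anyNA(lifted) && all(lifted == base)) {
          hemis <- hemisphereOf(atlas, rbind(g$leaf1, g$leaf2))
          if (all(hemis == hemi)) { tp <- cand; legs <- g; break }
        }
      }
      if (is.null(tp)) { tp <- samplePointInRegion(atlas, base, hemisphere = hemi)[1L, ]
                         legs <- yTuftGeometry(tp, tuftScale) }
      pts[[length(pts) + 1L]] <- list(region = region, point = tp, legs = legs)
      placed <- placed + 1L
    }
    truth[[length(truth) + 1L]] <- data.frame(
      neuron_id = id, cluster = cluster, region = region, tufts = placed,
      terminals = 2L * placed)
  }
  # greedy nearest-point insertion trunk: each unconnected tuft point
  # attaches by a chord to the nearest node of the existing trunk (branches
  # can sprout anywhere along the cable, as axon collaterals do)
  trunkRows <- 1L                          # soma row; grows with the trunk
  remaining <- seq_along(pts)
  while (length(remaining)) {
    pool <- as.matrix(nodes[trunkRows, c("x", "y", "z")])
    best <- NULL
    for (ri in remaining) {
      d2 <- rowSums(sweep(pool, 2L, pts[[ri]]$point)^2)
      j <- which.min(d2)
      if (is.null(best) || d2[j] < best$d2) best <- list(ri = ri, j = j, d2 = d2[j])
    }
    tp <- pts[[best$ri]]$point
    attachRow <- trunkRows[best$j]
    before <- nrow(nodes)
    tipId <- addPolyline(as.numeric(nodes[attachRow, c("x", "y", "z")]), tp,
                         nodes$id[attachRow])
    trunkRows <- c(trunkRows, seq(before + 1L, nrow(nodes)))
    legs <- pts[[best$ri]]$legs
    elbowId <- if (vecNorm(legs$elbow - tp) < 1e-9) tipId else
      addPolyline(tp, legs$elbow, tipId)
    addPolyline(legs$elbow, legs$leaf1, elbowId)
    addPolyline(legs$elbow, legs$leaf2, elbowId)
    remaining <- setdiff(remaining, best$ri)
  }
  list(morphology = Morphology(nodes, id), truth = do.call(rbind, truth))
}

# V-tuft geometry: two branches of scale/2 forking directly at the tuft
# point, so the terminals' common ancestor IS the sampled point (target
# points are tuft ancestors by definition).
yTuftGeometry <- function(root, scale) {
  dir <- randomUnitVector()
  perp <- unitVector(pracmaCross(dir, randomUnitVector()))
  b1 <- unitVector(dir + perp)
  b2 <- unitVector(dir - perp)
  list(elbow = root, leaf1 = root + b1 * scale / 2, leaf2 = root + b2 * scale / 2)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Generate a scene of postsynaptic neurons with stellate dendrites
#'
#' Neurons are placed uniformly in the brain (or a region) with stellate
#' dendrites: straight rays of equal share of the requested total length,
#' resampled at the given step. Deterministic per seed.
#'
#' @param n number of neurons.
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param totalLength total dendritic length per neuron, micrometres.
#' @param branches number of dendritic rays.
#' @param step node spacing, micrometres.
#' @param region optional region acronym to confine the somata.
#' @param seed integer seed.
#' @return list of \linkS4class{Morphology} with basal dendrites.
#' @export
generateScene <- function(n, atlas, totalLength = 1000, branches = 4L,
                          step = 25, region = NULL, seed = 1L) {
  withSeed(seed, {
    somata <- if (is.null(region)) {
      lin <- which(atlas@annotation > 0L)
      pick <- sample(lin, n, replace = TRUE)
      ijk <- arrayInd(pick, dim(atlas@annotation)) - 1L
      offs <- matrix(stats::runif(3L * n), ncol = 3L)
      sweep((ijk + offs) * atlas@voxelSize, 2L, atlas@origin, "+")
    } else samplePointInRegion(atlas, region, n = n)
    lapply(seq_len(n), function(i) {
      soma <- somata[i, ]
      nodes <- data.frame(id = 1L, parent = -1L, type = SWC_SOMA,
                          x = soma[1], y = soma[2], z = soma[3], radius = 5)
      nextId <- 2L
      rayLen <- totalLength / branches
      for (b in seq_len(branches)) {
        # dendrites stay in tissue: redraw the ray direction until the tip
        # lands in an annotated voxel (bounded tries)
        dir <- randomUnitVector()
        for (try in 1:20) {
          tip <- soma + dir * rayLen
          if (!is.na(regionAt(atlas, tip))) break
          dir <- randomUnitVector()
        }
        nSeg <- max(1L, round(rayLen / step))
        parentId <- 1L
        for (q in seq_len(nSeg)) {
          p <- soma + dir * rayLen * q / nSeg
          nodes[nrow(nodes) + 1L, ] <- list(nextId, parentId, SWC_BASAL,
                                            p[1], p[2], p[3], 0.5)
          parentId <- nextId
          nextId <- nextId + 1L
        }
      }
      Morphology(nodes, sprintf("post_%03d", i))
    })
  })
}
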