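#' @import methods
NULL

# SWC structure-type codes used throughout.
SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_BASAL <- 3L
SWC_APICAL <- 4L

#' Morphology: a rooted neuronal tree
#'
#' A neuron (or neurite fragment) as a table of 3D points with radii and
#' SWC structure types. Nodes are stored topologically sorted, so the parent
#' of every non-root node appears earlier in the table. Pass-through points
#' (nodes with exactly one child) are interior polyline geometry; sections are
#' derived as maximal unbranched chains, so the tree has no unifurcations at
#' the section level by construction.
#'
#' @slot nodes data.frame with columns \code{id}, \code{parent} (\code{-1} for
#'   the root), \code{type} (SWC codes: 1 soma, 2 axon, 3 basal, 4 apical
#'   dendrite), \code{x}, \code{y}, \code{z} (micrometres), \code{radius}
#'   (micrometres, positive).
#' @slot neuronId character scalar identifying the cell.
#' @export
setClass("Morphology", representation(nodes = "data.frame", neuronId = "character"))

setValidity("Morphology", function(object) {
  nd <- object@nodes
  need <- c("id", "parent", "type", "x", "y", "z", "radius")
  if (!all(need %in% names(nd))) {
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(nd) == 0L) return("morphology has no nodes")
  if (anyDuplicated(nd$id)) return("node ids are not unique")
  root <- nd$parent == -1L
  if (sum(root) != 1L) return("morphology must have exactly one root node")
  if (!all(nd$parent[!root] %in% nd$id)) return("parent of a non-root node is missing")
  if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")])))) {
    return("node coordinates must be finite")
  }
  if (any(nd$radius <= 0)) return("node radii must be positive")
  # topological sort invariant: parents precede children
  pos <- match(nd$parent, nd$id)
  if (any(pos[!root] >= seq_len(nrow(nd))[!root])) {
    return("nodes are not topologically sorted (parent after child)")
  }
  TRUE
})

#' Construct a Morphology
#'
#' Topologically sorts the node table (a cycle in the parent links is an
#' error) and validates the result.
#'
#' @param nodes node data.frame, see \linkS4class{Morphology}.
#' @param neuronId identifier for the cell.
#' @return a \linkS4class{Morphology}.
#' @export
Morphology <- function(nodes, neuronId = "neuron") {
  nodes <- as.data.frame(nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$type <- as.integer(nodes$type)
  ord <- topoOrderNodes(nodes)
  new("Morphology", nodes = nodes[ord, , drop = FALSE], neuronId = as.character(neuronId))
}

# Kahn topological sort over parent links; errors on cycles / multiple roots.
topoOrderNodes <- function(nodes) {
  n <- nrow(nodes)
  parentIdx <- match(nodes$parent, nodes$id)
  rootMask <- nodes$parent == -1L
  if (sum(rootMask) != 1L) stop("morphology must have exactly one root node")
  childList <- split(seq_len(n), factor(parentIdx, levels = seq_len(n)))
  order <- integer(n)
  queue <- which(rootMask)
  k <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    k <- k + 1L
    order[k] <- v
    kids <- childList[[v]]
    if (length(kids)) queue <- c(queue, kids)
  }
  if (k != n) stop("cyclic parent links in morphology")
  order
}

#' @rdname Morphology-class
#' @param object,x a \linkS4class{Morphology}.
#' @export
setGeneric("morphNodes", function(x) standardGeneric("morphNodes"))

#' @rdname Morphology-class
#' @export
setMethod("morphNodes", "Morphology", function(x) x@nodes)

#' @rdname Morphology-class
#' @export
setGeneric("neuronId", function(x) standardGeneric("neuronId"))

#' @rdname Morphology-class
#' @export
setMethod("neuronId", "Morphology", function(x) x@neuronId)

setMethod("show", "Morphology", function(object) {
  nd <- object@nodes
  types <- table(factor(nd$type, levels = 1:4,
                        labels = c("soma", "axon", "basal", "apical")))
  cat(sprintf("Morphology '%s': %d nodes (%s)\n", object@neuronId, nrow(nd),
              paste(sprintf("%s=%d", names(types), types), collapse = ", ")))
})

#' BrainAtlas: voxelized annotated brain volume
#'
#' An annotation raster (integer region id per voxel, 0 = outside the brain),
#' an Allen-style region hierarchy, and a boolean fiber-tract mask of the same
#' shape. World coordinates are micrometres; a world point maps to the voxel
#' \code{floor((xyz - origin)/voxelSize)} (0-based, half-open voxel ownership).
#' The two hemispheres are separated by a midline plane perpendicular to
#' \code{midlineAxis} at coordinate \code{midline}; points exactly on the
#' midline belong to the right hemisphere (documented tie-break).
#'
#' @slot annotation integer 3D array of region ids.
#' @slot voxelSize isotropic voxel edge length, micrometres.
#' @slot origin world coordinate of the corner of voxel (0,0,0).
#' @slot hierarchy data.frame with columns \code{id}, \code{acronym},
#'   \code{parent_id} (NA for the root) and \code{depth}.
#' @slot fiberMask logical 3D array marking fiber-tract voxels.
#' @slot midlineAxis axis index (1..3) perpendicular to the midline plane.
#' @slot midline world coordinate of the midline along that axis.
#' @export
setClass("BrainAtlas", representation(
  annotation = "array", voxelSize = "numeric", origin = "numeric",
  hierarchy = "data.frame", fiberMask = "array",
  midlineAxis = "integer", midline = "numeric"))

setValidity("BrainAtlas", function(object) {
  if (!identical(dim(object@annotation), dim(object@fiberMask))) {
    return("annotation and fiberMask must have identical shapes")
  }
  if (length(dim(object@annotation)) != 3L) return("annotation must be 3D")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (length(object@origin) != 3L) return("origin must be a 3-vector")
  h <- object@hierarchy
  if (!all(c("id", "acronym", "parent_id", "depth") %in% names(h))) {
    return("hierarchy needs columns id, acronym, parent_id, depth")
  }
  if (anyDuplicated(h$acronym)) return("hierarchy acronyms must be unique")
  if (sum(is.na(h$parent_id)) != 1L) return("hierarchy must have exactly one root")
  ids <- unique(as.vector(object@annotation))
  ids <- ids[ids != 0L]
  if (!all(ids %in% h$id)) return("annotation contains ids absent from the hierarchy")
  if (!(object@midlineAxis %in% 1:3)) return("midlineAxis must be 1, 2 or 3")
  TRUE
})

setMethod("show", "BrainAtlas", function(object) {
  d <- dim(object@annotation)
  cat(sprintf("BrainAtlas: %dx%dx%d voxels @ %g um, %d regions, %d fiber voxels\n",
              d[1], d[2], d[3], object@voxelSize,
              sum(!is.na(object@hierarchy$parent_id)),
              sum(object@fiberMask)))
})

#' @rdname BrainAtlas-class
#' @param x a \linkS4class{BrainAtlas}.
#' @export
setGeneric("regionHierarchy", function(x) standardGeneric("regionHierarchy"))

#' @rdname BrainAtlas-class
#' @export
setMethod("regionHierarchy", "BrainAtlas", function(x) x@hierarchy)

#' @rdname BrainAtlas-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname BrainAtlas-class
#' @export
setMethod("voxelSize", "BrainAtlas", function(x) x@voxelSize)

#' ProjectionGMM: per-source-region Gaussian mixture over projection features
#'
#' Mixture components live over an ordered region vocabulary; each component
#' has a weight, a mean vector and (by default) a single scalar variance
#' (spherical covariance). Per-cluster observed-region masks recorded at fit
#' time restrict virtual-axon sampling to regions seen in that cluster's
#' training members.
#'
#' @slot sourceRegion source-region acronym the model was fitted for.
#' @slot vocab ordered region vocabulary (feature dimensions).
#' @slot weights mixture weights, sum to 1.
#' @slot means C x B matrix of component means.
#' @slot variances list of length C: scalar (spherical) or length-B vector
#'   (diagonal) per component.
#' @slot covType "spherical" or "diagonal".
#' @slot masks logical C x B matrix of regions observed per cluster.
#' @slot logLik,bic fit log-likelihood and BIC (kappa*ln(n) - 2*logLik).
#' @slot n,nIter,seed fit metadata.
#' @slot llTrace per-iteration log-likelihood of the winning EM run.
#' @slot bicTrace data.frame (C, bic) from model selection (may be empty).
#' @export
setClass("ProjectionGMM", representation(
  sourceRegion = "character", vocab = "character", weights = "numeric",
  means = "matrix", variances = "list", covType = "character",
  masks = "matrix", logLik = "numeric", bic = "numeric",
  n = "integer", nIter = "integer", seed = "integer",
  llTrace = "numeric", bicTrace = "data.frame"))

setValidity("ProjectionGMM", function(object) {
  C <- length(object@weights)
  if (abs(sum(object@weights) - 1) > 1e-9) return("mixture weights must sum to 1")
  if (any(object@weights < 0)) return("mixture weights must be non-negative")
  if (nrow(object@means) != C) return("means must have one row per component")
  if (ncol(object@means) != length(object@vocab)) return("means/vocab dimension mismatch")
  if (length(object@variances) != C) return("variances must have one entry per component")
  if (any(unlist(object@variances) <= 0)) return("variances must be positive")
  if (!object@covType %in% c("spherical", "diagonal")) {
    return("covType must be 'spherical' or 'diagonal'")
  }
  TRUE
})

setMethod("show", "ProjectionGMM", function(object) {
  cat(sprintf(
    "ProjectionGMM for source '%s': C=%d (%s), B=%d regions, logLik=%.3f, BIC=%.3f\n",
    object@sourceRegion, length(object@weights), object@covType,
    length(object@vocab), object@logLik, object@bic))
})

#' @rdname ProjectionGMM-class
#' @param x a \linkS4class{ProjectionGMM}.
#' @export
setGeneric("clusterWeights", function(x) standardGeneric("clusterWeights"))

#' @rdname ProjectionGMM-class
#' @export
setMethod("clusterWeights", "ProjectionGMM", function(x) x@weights)

#' @rdname ProjectionGMM-class
#' @export
setGeneric("clusterMeans", function(x) standardGeneric("clusterMeans"))

#' @rdname ProjectionGMM-class
#' @export
setMethod("clusterMeans", "ProjectionGMM", function(x) x@means)

#' @rdname ProjectionGMM-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ProjectionGMM-class
#' @export
setMethod("nClusters", "ProjectionGMM", function(x) length(x@weights))

#' AxonConnectome: synapses with neuron- and region-level aggregations
#'
#' @slot synapses data.frame of synapses (pre, post, xyz, arc position,
#'   post region).
#' @slot adjacency sparse pre x post synapse-count matrix.
#' @slot projectome sparse region x region synapse-count matrix
#'   (direction pre -> post).
#' @slot level hierarchy depth used for the projectome.
#' @export
setClass("AxonConnectome", representation(
  synapses = "data.frame", adjacency = "Matrix",
  projectome = "Matrix", level = "ANY"))

setValidity("AxonConnectome", function(object) {
  n <- nrow(object@synapses)
  if (sum(object@adjacency) != n) return("adjacency totals must equal synapse count")
  if (sum(object@projectome) != n) return("projectome totals must equal synapse count")
  TRUE
})

setMethod("show", "AxonConnectome", function(object) {
  cat(sprintf("AxonConnectome: %d synapses, %d pre x %d post neurons, %d x %d regions\n",
              nrow(object@synapses), nrow(object@adjacency), ncol(object@adjacency),
              nrow(object@projectome), ncol(object@projectome)))
})

#' @rdname AxonConnectome-class
#' @param x an \linkS4class{AxonConnectome}.
#' @export
setGeneric("synapses", function(x) standardGeneric("synapses"))

#' @rdname AxonConnectome-class
#' @export
setMethod("synapses", "AxonConnectome", function(x) x@synapses)

#' @rdname AxonConnectome-class
#' @export
setGeneric("projectome", function(x) standardGeneric("projectome"))

#' @rdname AxonConnectome-class
#' @export
setMethod("projectome", "AxonConnectome", function(x) x@projectome)

#' @rdname AxonConnectome-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname AxonConnectome-class
#' @export
setMethod("adjacencyMatrix", "AxonConnectome", function(x) x@adjacency)
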