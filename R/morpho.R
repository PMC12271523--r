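# Morphology I/O, tree traversal, and morphometrics.

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; '#' comments).
#' The dialect accepted is the simplest one common readers emit: 1-based ids,
#' parent -1 for the root, single-point soma allowed. Multi-point somata are
#' collapsed to their centroid (children re-parented to the collapsed soma
#' node). Coordinates are taken verbatim, in micrometres. Unifurcation points
#' survive as polyline geometry inside sections (see
#' \linkS4class{Morphology}), so writing and re-reading preserves node count,
#' parent map and total length up to float formatting.
#'
#' @param path path to an SWC file.
#' @param neuronId identifier; default the file name without extension.
#' @param requireSoma error when the root is not a soma point. Disable for
#'   neurite fragments (tufts, trunk pieces).
#' @return a \linkS4class{Morphology} rooted at a soma node (unless
#'   \code{requireSoma = FALSE}).
#' @export
readSWC <- function(path, neuronId = NULL, requireSoma = TRUE) {
  lines <- readLines(path, warn = FALSE)
  dataIdx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(dataIdx)) stop("SWC file '", path, "' has no data lines")
  fields <- strsplit(trimws(lines[dataIdx]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop("malformed SWC line ", dataIdx[bad[1L]], " in '", path,
         "': expected 7 columns, got ", lengths(fields)[bad[1L]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  nas <- which(rowSums(is.na(m)) > 0L)
  if (length(nas)) {
    stop("malformed SWC line ", dataIdx[nas[1L]], " in '", path, "': non-numeric field")
  }
  nodes <- data.frame(id = as.integer(m[, 1]), parent = as.integer(m[, 7]),
                      type = as.integer(m[, 2]), x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6])
  nodes <- collapseSoma(nodes)
  if (is.null(neuronId)) neuronId <- sub("\\.[sS][wW][cC]$", "", basename(path))
  morph <- tryCatch(Morphology(nodes, neuronId), error = function(e) {
    stop("structure error in '", path, "': ", conditionMessage(e))
  })
  if (requireSoma && morphNodes(morph)$type[1L] != SWC_SOMA) {
    stop("structure error in '", path, "': root node is not a soma point")
  }
  morph
}

# Collapse a multi-point soma to its centroid; re-parent soma children.
collapseSoma <- function(nodes) {
  somaRows <- which(nodes$type == SWC_SOMA)
  if (length(somaRows) <= 1L) return(nodes)
  somaIds <- nodes$id[somaRows]
  keep <- somaRows[nodes$parent[somaRows] == -1L]
  if (length(keep) != 1L) keep <- somaRows[1L]
  nodes$x[keep] <- mean(nodes$x[somaRows])
  nodes$y[keep] <- mean(nodes$y[somaRows])
  nodes$z[keep] <- mean(nodes$z[somaRows])
  nodes$radius[keep] <- mean(nodes$radius[somaRows])
  nodes$parent[keep] <- -1L
  keepId <- nodes$id[keep]
  nodes$parent[nodes$parent %in% somaIds] <- keepId
  nodes <- nodes[-setdiff(somaRows, keep), , drop = FALSE]
  nodes$parent[nodes$id == keepId] <- -1L
  rownames(nodes) <- NULL
  nodes
}

#' Write a Morphology as SWC
#'
#' @param m a \linkS4class{Morphology}.
#' @param path output path.
#' @export
writeSWC <- function(m, path) {
  nd <- morphNodes(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC written by synaxon",
               "# columns: id type x y z radius parent"), con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent), con)
  invisible(path)
}

# ---- tree helpers ------------------------------------------------------

# Children row-indices per node row.
childRows <- function(nodes) {
  parentIdx <- match(nodes$parent, nodes$id)
  out <- vector("list", nrow(nodes))
  nz <- !is.na(parentIdx)
  if (any(nz)) {
    sp <- split(which(nz), parentIdx[nz])
    out[as.integer(names(sp))] <- sp
  }
  out
}

# Segment length from each node to its parent (0 for root).
segmentLengths <- function(nodes) {
  parentIdx <- match(nodes$parent, nodes$id)
  len <- numeric(nrow(nodes))
  nz <- !is.na(parentIdx)
  dx <- nodes$x[nz] - nodes$x[parentIdx[nz]]
  dy <- nodes$y[nz] - nodes$y[parentIdx[nz]]
  dz <- nodes$z[nz] - nodes$z[parentIdx[nz]]
  len[nz] <- sqrt(dx^2 + dy^2 + dz^2)
  len
}

#' Soma center of a morphology
#' @param m a \linkS4class{Morphology}.
#' @return world-coordinate 3-vector (micrometres). Falls back to the root
#'   node when there is no soma point (neurite fragments).
#' @export
somaCenter <- function(m) {
  nd <- morphNodes(m)
  rows <- which(nd$type == SWC_SOMA)
  if (!length(rows)) rows <- 1L
  c(mean(nd$x[rows]), mean(nd$y[rows]), mean(nd$z[rows]))
}

# Row indices of the neurite subtree(s) of a given SWC type. The neurite root
# is the highest node of that type (child of the soma, or the tree root for
# fragments). Returns list(rows = subtree rows, roots = neurite root rows).
neuriteRows <- function(nodes, type) {
  parentIdx <- match(nodes$parent, nodes$id)
  isType <- nodes$type == type
  roots <- which(isType & (is.na(parentIdx) | nodes$type[parentIdx] != type))
  if (!length(roots)) return(list(rows = integer(0), roots = integer(0)))
  kids <- childRows(nodes)
  rows <- integer(0)
  stack <- roots
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    rows <- c(rows, v)
    stack <- c(stack, kids[[v]])
  }
  list(rows = sort(rows), roots = roots)
}

# Path distance of every node to its neurite root (NA outside the neurite).
# The stem segment from the soma to the neurite root is excluded.
neuritePathDistances <- function(nodes, type) {
  nr <- neuriteRows(nodes, type)
  pd <- rep(NA_real_, nrow(nodes))
  if (!length(nr$rows)) return(pd)
  seg <- segmentLengths(nodes)
  parentIdx <- match(nodes$parent, nodes$id)
  pd[nr$roots] <- 0
  for (v in nr$rows) {                     # rows are topologically sorted
    if (!is.na(pd[v])) next
    pd[v] <- pd[parentIdx[v]] + seg[v]
  }
  pd
}

# Section decomposition of a neurite: maximal unbranched chains. Returns a
# data.frame (section, parentSection, order) plus a list of row-index chains;
# each chain starts at the section's first node (child of the fork/root) and
# ends at a fork or leaf. The chain includes the upstream fork/root node as
# its first element so section geometry is a complete polyline.
neuriteSections <- function(nodes, type) {
  nr <- neuriteRows(nodes, type)
  if (!length(nr$rows)) {
    return(list(table = data.frame(section = integer(0), parentSection = integer(0),
                                   order = integer(0)), chains = list()))
  }
  kids <- childRows(nodes)
  inNeurite <- logical(nrow(nodes))
  inNeurite[nr$rows] <- TRUE
  nKids <- vapply(kids, function(k) sum(inNeurite[k]), 0L)
  chains <- list(); parentSec <- integer(0); orders <- integer(0)
  # stack entries: (start row, parent section, order)
  stack <- lapply(nr$roots, function(r) list(start = r, parent = 0L, order = 0L))
  while (length(stack)) {
    e <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    chain <- e$start
    v <- e$start
    repeat {
      ks <- kids[[v]]; ks <- ks[inNeurite[ks]]
      if (length(ks) != 1L) break
      v <- ks
      chain <- c(chain, v)
    }
    sec <- length(chains) + 1L
    chains[[sec]] <- chain
    parentSec[sec] <- e$parent
    orders[sec] <- e$order
    ks <- kids[[v]]; ks <- ks[inNeurite[ks]]
    for (k in ks) {
      stack[[length(stack) + 1L]] <- list(start = k, parent = sec,
                                          order = e$order + 1L)
    }
  }
  # prepend the upstream node to each chain for complete polyline geometry
  parentIdx <- match(nodes$parent, nodes$id)
  chains <- lapply(seq_along(chains), function(i) {
    first <- chains[[i]][1L]
    up <- parentIdx[first]
    if (!is.na(up) && inNeurite[up]) c(up, chains[[i]]) else chains[[i]]
  })
  list(table = data.frame(section = seq_along(chains), parentSection = parentSec,
                          order = orders), chains = chains)
}

#' Compute morphometrics of one neurite
#'
#' Deterministic per-tree features: leaf count, section lengths, path
#' distances from each leaf to the neurite root (arc length along parents),
#' remote bifurcation angles (angle at a fork between the vectors to the
#' endpoints of its child sections), branch orders per section, and total
#' length. Angles are radians.
#'
#' @param m a \linkS4class{Morphology}.
#' @param neurite one of "axon", "basal_dendrite", "apical_dendrite", "soma",
#'   or an SWC type code.
#' @return a list with elements \code{number_of_leaves},
#'   \code{section_lengths}, \code{path_distances_to_root},
#'   \code{remote_bifurcation_angles}, \code{branch_orders},
#'   \code{total_length}, and \code{present} (FALSE when the neurite is
#'   absent, in which case all features are empty rather than an error).
#' @export
computeMorphometrics <- function(m, neurite = "axon") {
  type <- swcTypeCode(neurite)
  nodes <- morphNodes(m)
  nr <- neuriteRows(nodes, type)
  if (!length(nr$rows)) {
    return(list(number_of_leaves = 0L, section_lengths = numeric(0),
                path_distances_to_root = numeric(0),
                remote_bifurcation_angles = numeric(0),
                branch_orders = integer(0), total_length = 0, present = FALSE))
  }
  seg <- segmentLengths(nodes)
  kids <- childRows(nodes)
  inNeurite <- logical(nrow(nodes)); inNeurite[nr$rows] <- TRUE
  nKids <- vapply(kids, function(k) sum(inNeurite[k]), 0L)
  leaves <- nr$rows[nKids[nr$rows] == 0L]
  pd <- neuritePathDistances(nodes, type)
  secs <- neuriteSections(nodes, type)
  secLengths <- vapply(secs$chains, function(ch) {
    if (length(ch) < 2L) return(0)
    sum(seg[ch[-1L]])
  }, 0)
  # total length: all segments internal to the neurite (stem excluded)
  parentIdx <- match(nodes$parent, nodes$id)
  internal <- nr$rows[!(nr$rows %in% nr$roots)]
  totalLength <- sum(seg[internal])
  # remote bifurcation angles at every fork, all child-section pairs
  forks <- nr$rows[nKids[nr$rows] >= 2L]
  angles <- numeric(0)
  if (length(forks)) {
    secStart <- vapply(secs$chains, function(ch) if (length(ch) >= 2L) ch[2L] else ch[1L], 0L)
    secEnd <- vapply(secs$chains, function(ch) ch[length(ch)], 0L)
    for (f in forks) {
      childSecs <- which(secStart %in% kids[[f]])
      ends <- secEnd[childSecs]
      if (length(ends) < 2L) next
      pairs <- utils::combn(ends, 2L)
      for (j in seq_len(ncol(pairs))) {
        v1 <- c(nodes$x[pairs[1, j]] - nodes$x[f], nodes$y[pairs[1, j]] - nodes$y[f],
                nodes$z[pairs[1, j]] - nodes$z[f])
        v2 <- c(nodes$x[pairs[2, j]] - nodes$x[f], nodes$y[pairs[2, j]] - nodes$y[f],
                nodes$z[pairs[2, j]] - nodes$z[f])
        cosang <- sum(v1 * v2) / (vecNorm(v1) * vecNorm(v2))
        angles <- c(angles, acos(pmin(1, pmax(-1, cosang))))
      }
    }
  }
  list(number_of_leaves = length(leaves),
       section_lengths = secLengths,
       path_distances_to_root = unname(pd[leaves]),
       remote_bifurcation_angles = angles,
       branch_orders = secs$table$order,
       total_length = totalLength,
       present = TRUE)
}

swcTypeCode <- function(neurite) {
  if (is.numeric(neurite)) return(as.integer(neurite))
  switch(neurite,
         soma = SWC_SOMA, axon = SWC_AXON,
         basal_dendrite = SWC_BASAL, apical_dendrite = SWC_APICAL,
         stop("unknown neurite type: ", neurite))
}

#' Export morphometrics of several cells as a long-format table
#'
#' @param morphologies list of \linkS4class{Morphology}.
#' @param neurite neurite type, see [computeMorphometrics()].
#' @return data.frame with columns neuron_id, neurite, feature, value.
#' @export
morphometricsTable <- function(morphologies, neurite = "axon") {
  rows <- lapply(morphologies, function(m) {
    f <- computeMorphometrics(m, neurite)
    scalars <- list(number_of_leaves = f$number_of_leaves,
                    total_length = f$total_length)
    vecs <- f[c("section_lengths", "path_distances_to_root",
                "remote_bifurcation_angles", "branch_orders")]
    do.call(rbind, c(
      lapply(names(scalars), function(nm)
        data.frame(neuron_id = neuronId(m), neurite = neurite, feature = nm,
                   value = as.numeric(scalars[[nm]]))),
      lapply(names(vecs), function(nm) {
        v <- as.numeric(vecs[[nm]])
        if (!length(v)) return(NULL)
        data.frame(neuron_id = neuronId(m), neurite = neurite, feature = nm, value = v)
      })))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Axon terminal points of a morphology
#'
#' @param m a \linkS4class{Morphology}.
#' @param neurite neurite type.
#' @return data.frame with the node row index, id, coordinates and path
#'   distance to the neurite root of every leaf of the requested neurite.
#' @export
neuriteLeaves <- function(m, neurite = "axon") {
  type <- swcTypeCode(neurite)
  nodes <- morphNodes(m)
  nr <- neuriteRows(nodes, type)
  if (!length(nr$rows)) {
    return(data.frame(row = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), pathDistance = numeric(0)))
  }
  kids <- childRows(nodes)
  inNeurite <- logical(nrow(nodes)); inNeurite[nr$rows] <- TRUE
  nKids <- vapply(kids, function(k) sum(inNeurite[k]), 0L)
  leaves <- nr$rows[nKids[nr$rows] == 0L]
  pd <- neuritePathDistances(nodes, type)
  data.frame(row = leaves, id = nodes$id[leaves], x = nodes$x[leaves],
             y = nodes$y[leaves], z = nodes$z[leaves], pathDistance = pd[leaves])
}
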