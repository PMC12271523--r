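# Tuft extraction (terminal agglomeration up to common ancestors), topological
# barcodes, grouping by (GMM cluster, region) and representativity scores.

#' Extract tufts and the trunk of an axon
#'
#' Axon terminals are agglomerated by single linkage: two terminals may join
#' the same cluster iff their Euclidean distance is at most \code{radialMax}
#' AND their tree path distance is at most \code{pathMax} (clusters are the
#' connected components of this constraint graph, so every within-tuft
#' terminal pair is connected by a chain of merges satisfying both
#' thresholds). Each multi-terminal cluster becomes a tuft rooted at the
#' lowest common ancestor of its terminals; singleton terminals remain trunk
#' endpoints. The trunk is the axon with all tuft subtrees removed; the
#' common-ancestor node belongs to the tuft, so
#' \code{|trunk nodes| + sum |tuft nodes| = |axon nodes|} exactly.
#'
#' @param m a \linkS4class{Morphology} with an axon.
#' @param radialMax maximum clustering radius, micrometres (default 300).
#' @param pathMax maximum clustering path distance, micrometres (default 300).
#' @details The tuft subtree contains the ancestor plus the nodes below it
#'   whose descendant terminals all belong to the cluster: when the common
#'   ancestor sits on a through-going trunk, the downstream cable (leading
#'   to other terminals) stays in the trunk. The ancestor node is owned by
#'   the tuft (the trunk ends at it; a duplicate seam point appears when
#'   re-serialized); in the rare case of two clusters sharing an ancestor,
#'   only the first owns the node (\code{ownsAncestor}), keeping node
#'   conservation exact.
#' @return list with \code{trunk} (a Morphology: soma, dendrites and the
#'   axon minus tufts) and \code{tufts} (list of \code{Tuft} objects: lists
#'   with \code{neuronId}, \code{ancestorXYZ}, \code{ancestorId},
#'   \code{morphology} (fragment rooted at the ancestor), \code{barcode},
#'   \code{morphometrics}, \code{ownedNodes}, \code{ownsAncestor}).
#' @export
extractTufts <- function(m, radialMax = 300, pathMax = 300) {
  nodes <- morphNodes(m)
  leaves <- neuriteLeaves(m, "axon")
  if (!nrow(leaves)) stop("morphology '", neuronId(m), "' has no axon terminal")
  comp <- clusterTerminals(m, radialMax, pathMax)

  parentIdx <- match(nodes$parent, nodes$id)
  kids <- childRows(nodes)
  n <- nrow(nodes)
  # leaves below each node, total and per use below
  isLeaf <- logical(n); isLeaf[leaves$row] <- TRUE
  leavesBelow <- integer(n)
  for (v in rev(topoOrderNodes(nodes))) {
    leavesBelow[v] <- if (isLeaf[v]) 1L else sum(leavesBelow[kids[[v]]])
  }
  tufts <- list()
  claimedBy <- integer(n)                  # 0 = trunk
  multi <- which(tabulate(comp) >= 2L)
  for (i in seq_along(multi)) {
    rowsOf <- leaves$row[comp == multi[i]]
    anc <- Reduce(function(a, b) lcaRows(nodes, parentIdx, a, b), rowsOf)
    # count cluster leaves below each node, then keep pure nodes under anc
    inComp <- integer(n)
    for (v in rev(topoOrderNodes(nodes))) {
      inComp[v] <- if (isLeaf[v]) as.integer(v %in% rowsOf) else
        sum(inComp[kids[[v]]])
    }
    sub <- setdiff(subtreeRows(kids, anc), anc)
    pure <- sub[inComp[sub] == leavesBelow[sub] & claimedBy[sub] == 0L]
    claimedBy[pure] <- i
    # the ancestor joins the tuft unless already claimed or a soma point
    # (terminals of distinct stems can only meet at the soma, which must
    # stay in the trunk)
    ownsAncestor <- claimedBy[anc] == 0L && nodes$type[anc] != SWC_SOMA
    if (ownsAncestor) claimedBy[anc] <- i
    frag <- extractFragment(nodes, c(anc, pure), anc,
                            paste0(neuronId(m), "_tuft", length(tufts) + 1L))
    tuft <- list(neuronId = neuronId(m),
                 ancestorXYZ = c(nodes$x[anc], nodes$y[anc], nodes$z[anc]),
                 ancestorId = nodes$id[anc],
                 morphology = frag,
                 barcode = tuftBarcode(frag),
                 morphometrics = computeMorphometrics(frag, "axon"),
                 ownedNodes = length(pure) + as.integer(ownsAncestor),
                 ownsAncestor = ownsAncestor)
    class(tuft) <- "Tuft"
    tufts[[length(tufts) + 1L]] <- tuft
  }
  trunkRows <- which(claimedBy == 0L)
  trunkNodes <- nodes[trunkRows, , drop = FALSE]
  # a trunk node below a claimed ancestor re-attaches through the nearest
  # unclaimed ancestor (the through-going cable continues past the seam)
  for (q in seq_len(nrow(trunkNodes))) {
    p <- parentIdx[trunkRows[q]]
    while (!is.na(p) && claimedBy[p] != 0L) p <- parentIdx[p]
    trunkNodes$parent[q] <- if (is.na(p)) -1L else nodes$id[p]
  }
  trunkNodes$parent[1L] <- -1L
  trunk <- Morphology(trunkNodes, paste0(neuronId(m), "_trunk"))
  list(trunk = trunk, tufts = tufts)
}

# Connected components of the dual-threshold constraint graph on terminals.
clusterTerminals <- function(m, radialMax, pathMax) {
  nodes <- morphNodes(m)
  leaves <- neuriteLeaves(m, "axon")
  nL <- nrow(leaves)
  if (nL == 1L) return(1L)
  xyz <- as.matrix(leaves[, c("x", "y", "z")])
  euclid <- as.matrix(stats::dist(xyz))
  pathD <- terminalPathDistances(m, leaves)
  adj <- euclid <= radialMax & pathD <= pathMax
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Pairwise tree path distances between axon terminals.
terminalPathDistances <- function(m, leaves = neuriteLeaves(m, "axon")) {
  nodes <- morphNodes(m)
  parentIdx <- match(nodes$parent, nodes$id)
  pd <- neuritePathDistances(nodes, SWC_AXON)
  nL <- nrow(leaves)
  out <- matrix(0, nL, nL)
  for (i in seq_len(nL - 1L)) {
    for (j in (i + 1L):nL) {
      l <- lcaRows(nodes, parentIdx, leaves$row[i], leaves$row[j])
      lpd <- if (is.na(pd[l])) 0 else pd[l]
      out[i, j] <- out[j, i] <- leaves$pathDistance[i] + leaves$pathDistance[j] - 2 * lpd
    }
  }
  out
}

nodeDepths <- function(nodes, parentIdx) {
  depth <- integer(nrow(nodes))
  for (v in seq_len(nrow(nodes))) {
    p <- parentIdx[v]
    depth[v] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  depth
}

lcaRows <- function(nodes, parentIdx, a, b) {
  seen <- logical(nrow(nodes))
  v <- a
  while (!is.na(v)) { seen[v] <- TRUE; v <- parentIdx[v] }
  v <- b
  while (!is.na(v) && !seen[v]) v <- parentIdx[v]
  if (is.na(v)) stop("nodes share no ancestor")
  v
}

subtreeRows <- function(kids, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

# Build a Morphology fragment from node rows, rooted at `rootRow`.
extractFragment <- function(nodes, rows, rootRow, id) {
  sub <- nodes[rows, , drop = FALSE]
  sub$parent[sub$id == nodes$id[rootRow]] <- -1L
  # orphaned nodes (parent outside the fragment) attach to the root
  orphan <- sub$parent != -1L & !(sub$parent %in% sub$id)
  sub$parent[orphan] <- nodes$id[rootRow]
  Morphology(sub, id)
}

#' Persistence barcode of a tuft (path-distance filtration)
#'
#' Simplified topological descriptor: bars are (birth, death) pairs of path
#' distances from the tuft root. Each leaf contributes one bar whose death is
#' its path distance; at each bifurcation the child branch with the larger
#' maximal descendant path distance survives (elder rule) and every other
#' child is born there. The surviving branch of the root gives the bar
#' (0, max path distance).
#'
#' @param tuft a \code{Tuft} or a \linkS4class{Morphology} fragment.
#' @return matrix with columns \code{birth}, \code{death}; one row per leaf.
#' @export
tuftBarcode <- function(tuft) {
  m <- if (inherits(tuft, "Tuft")) tuft$morphology else tuft
  nodes <- morphNodes(m)
  type <- nodes$type[1L]
  if (type == SWC_SOMA) type <- SWC_AXON
  nr <- neuriteRows(nodes, type)
  if (!length(nr$rows)) stop("tuft fragment has no neurite nodes")
  kids <- childRows(nodes)
  pd <- neuritePathDistances(nodes, type)
  # max descendant terminal path distance per node (reverse topological order)
  maxDesc <- rep(-Inf, nrow(nodes))
  for (v in rev(nr$rows)) {
    ks <- kids[[v]]
    maxDesc[v] <- if (!length(ks)) pd[v] else max(maxDesc[ks])
  }
  bars <- list()
  for (root in nr$roots) {
    bars[[length(bars) + 1L]] <- c(0, maxDesc[root])
    stack <- root
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      ks <- kids[[v]]
      if (length(ks) >= 2L) {
        elder <- ks[which.max(maxDesc[ks])]
        for (c in setdiff(ks, elder)) {
          bars[[length(bars) + 1L]] <- c(pd[v], maxDesc[c])
        }
      }
      stack <- c(stack, ks)
    }
  }
  out <- do.call(rbind, bars)
  colnames(out) <- c("birth", "death")
  out
}

#' Group tufts by (cluster, ancestor region) with count statistics
#'
#' Groups are keyed by the GMM cluster of the tuft's parent neuron and the
#' region of its common ancestor. Per group, the mean and variance (population
#' variance, matching the MLE convention of the mixture module) of the
#' per-axon tuft counts are recorded, over the axons contributing at least
#' one tuft to the group.
#'
#' @param tufts list of \code{Tuft} objects.
#' @param clusters named integer vector: cluster per neuron id.
#' @param regions character vector: ancestor region per tuft (same order as
#'   \code{tufts}); compute with [tuftRegions()].
#' @return list with \code{index} (data.frame: tuft, neuron_id, cluster,
#'   region, group) and \code{groups} (data.frame: group, cluster, region,
#'   n_tufts, n_axons, mean_count, var_count).
#' @export
groupTufts <- function(tufts, clusters, regions) {
  if (length(regions) != length(tufts)) stop("one region per tuft required")
  ids <- vapply(tufts, `[[`, "", "neuronId")
  missing <- setdiff(unique(ids), names(clusters))
  if (length(missing)) stop("no cluster assignment for neuron(s): ",
                            paste(missing, collapse = ", "))
  cl <- clusters[ids]
  key <- paste(cl, regions, sep = "|")
  keys <- sort(unique(key))
  index <- data.frame(tuft = seq_along(tufts), neuron_id = ids,
                      cluster = as.integer(cl), region = regions,
                      group = match(key, keys))
  groups <- do.call(rbind, lapply(seq_along(keys), function(g) {
    rows <- index[index$group == g, ]
    counts <- table(rows$neuron_id)
    data.frame(group = g, cluster = rows$cluster[1L], region = rows$region[1L],
               n_tufts = nrow(rows), n_axons = length(counts),
               mean_count = mean(counts),
               var_count = mean((counts - mean(counts))^2))
  }))
  list(index = index, groups = groups)
}

#' Region acronym of each tuft's common ancestor
#'
#' Regions are hemisphere-tagged relative to the parent neuron's soma
#' (contralateral ancestors get the "_contra" suffix) so group keys align
#' with the projection-feature vocabulary.
#'
#' @param tufts list of \code{Tuft} objects.
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param level hierarchy depth or "leaf".
#' @param somaHemispheres named character vector: soma hemisphere per neuron.
#' @return character vector of region labels (NA outside the atlas).
#' @export
tuftRegions <- function(tufts, atlas, level = "leaf", somaHemispheres = NULL) {
  vapply(tufts, function(t) {
    acr <- regionAt(atlas, t$ancestorXYZ, level)
    if (is.na(acr)) return(NA_character_)
    if (!is.null(somaHemispheres)) {
      hemi <- hemisphereOf(atlas, t$ancestorXYZ)
      if (hemi != somaHemispheres[[t$neuronId]]) acr <- paste0(acr, "_contra")
    }
    acr
  }, "")
}

# Morphometric summary used for representativity: one row per tuft.
tuftFeatureMatrix <- function(tufts) {
  t(vapply(tufts, function(t) {
    f <- t$morphometrics
    c(total_length = f$total_length,
      number_of_leaves = as.numeric(f$number_of_leaves),
      max_path_distance = if (length(f$path_distances_to_root))
        max(f$path_distances_to_root) else 0,
      mean_section_length = if (length(f$section_lengths))
        mean(f$section_lengths) else 0)
  }, numeric(4L)))
}

#' Representativity scores of tufts within a group
#'
#' For each tuft, the per-feature deviation is the absolute distance to the
#' group median in units of the group spread (half the 5th-95th percentile
#' range, the same spread as the MVS machinery); the score is
#' \code{max(0, 1 - mean deviation)}, so the group-typical tuft scores near 1.
#' A zero-spread feature contributes 0 when the value equals the median and
#' forces a 0 score otherwise. Singleton groups score 1.
#'
#' @param tufts list of \code{Tuft} objects forming one group.
#' @param probs percentile window for the spread.
#' @return numeric vector of scores in \code{[0, 1]}.
#' @export
representativityScores <- function(tufts, probs = c(0.05, 0.95)) {
  n <- length(tufts)
  if (n == 0L) stop("empty tuft group")
  if (n == 1L) return(1)
  feats <- tuftFeatureMatrix(tufts)
  meds <- apply(feats, 2L, stats::median)
  spreads <- apply(feats, 2L, function(v) diff(stats::quantile(v, probs)) / 2)
  dev <- vapply(seq_len(ncol(feats)), function(j) {
    d <- abs(feats[, j] - meds[j])
    if (spreads[j] > 0) d / spreads[j] else ifelse(d == 0, 0, Inf)
  }, numeric(n))
  scores <- 1 - rowMeans(rbind(dev))
  pmin(1, pmax(0, scores))
}

#' Build the complete tuft library for a clustered population
#'
#' Extracts tufts from every morphology, locates their ancestors in the
#' atlas, groups them by (cluster, region), and attaches count statistics and
#' representativity scores. This is the object consumed by the synthesis
#' stage.
#'
#' @param morphologies list of \linkS4class{Morphology}.
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param clusters named integer vector: cluster per neuron id.
#' @param level hierarchy depth or "leaf".
#' @param radialMax,pathMax clustering thresholds (micrometres).
#' @return list of class \code{TuftLibrary}: \code{tufts}, \code{index}
#'   (with a \code{score} column), \code{groups}, \code{trunks}.
#' @export
buildTuftLibrary <- function(morphologies, atlas, clusters, level = "leaf",
                             radialMax = 300, pathMax = 300) {
  allTufts <- list(); trunks <- list(); hemis <- character(0)
  for (m in morphologies) {
    ex <- extractTufts(m, radialMax, pathMax)
    allTufts <- c(allTufts, ex$tufts)
    trunks[[neuronId(m)]] <- ex$trunk
    hemis[neuronId(m)] <- hemisphereOf(atlas, somaCenter(m))
  }
  if (!length(allTufts)) stop("no tufts extracted from the population")
  regions <- tuftRegions(allTufts, atlas, level, hemis)
  keep <- !is.na(regions)
  allTufts <- allTufts[keep]; regions <- regions[keep]
  grouped <- groupTufts(allTufts, clusters, regions)
  score <- numeric(length(allTufts))
  for (g in grouped$groups$group) {
    rows <- which(grouped$index$group == g)
    score[rows] <- representativityScores(allTufts[rows])
  }
  grouped$index$score <- score
  structure(list(tufts = allTufts, index = grouped$index,
                 groups = grouped$groups, trunks = trunks),
            class = "TuftLibrary")
}

#' Serialize / load a tuft library (SWC fragments + JSON index)
#'
#' @param library a \code{TuftLibrary}.
#' @param dir output directory.
#' @export
writeTuftLibrary <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(library$tufts)) {
    writeSWC(library$tufts[[i]]$morphology, file.path(dir, sprintf("tuft_%04d.swc", i)))
  }
  idx <- library$index
  idx$file <- sprintf("tuft_%04d.swc", idx$tuft)
  idx$ancestor <- lapply(library$tufts, `[[`, "ancestorXYZ")
  idx$barcode <- lapply(library$tufts, function(t)
    apply(t$barcode, 1L, as.numeric, simplify = FALSE))
  jsonlite::write_json(list(index = idx, groups = library$groups),
                       file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname writeTuftLibrary
#' @export
readTuftLibrary <- function(dir) {
  o <- jsonlite::read_json(file.path(dir, "index.json"))
  index <- do.call(rbind, lapply(o$index, function(r)
    data.frame(tuft = r$tuft, neuron_id = r$neuron_id, cluster = r$cluster,
               region = r$region, group = r$group, score = r$score)))
  groups <- do.call(rbind, lapply(o$groups, function(r)
    data.frame(group = r$group, cluster = r$cluster, region = r$region,
               n_tufts = r$n_tufts, n_axons = r$n_axons,
               mean_count = r$mean_count, var_count = r$var_count)))
  tufts <- lapply(seq_along(o$index), function(i) {
    r <- o$index[[i]]
    frag <- readSWC(file.path(dir, r$file), requireSoma = FALSE)
    bc <- do.call(rbind, lapply(r$barcode, as.numeric))
    colnames(bc) <- c("birth", "death")
    structure(list(neuronId = r$neuron_id,
                   ancestorXYZ = as.numeric(unlist(r$ancestor)),
                   ancestorId = NA_integer_, morphology = frag, barcode = bc,
                   morphometrics = computeMorphometrics(frag, "axon")),
              class = "Tuft")
  })
  structure(list(tufts = tufts, index = index, groups = groups,
                 trunks = list()), class = "TuftLibrary")
}
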