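# Weighted Steiner-tree machinery on a voxel lattice graph: graph
# construction with fiber-tract edge discounts, a 2-approximation heuristic
# (iterative nearest-terminal shortest-path insertion), and the exact
# Dreyfus-Wagner dynamic program used as the optimality oracle on small
# instances.

#' Build the in-brain lattice graph for trunk routing
#'
#' Vertices are the centers of in-brain voxels (annotation > 0) on a regular
#' sublattice at the given step; edges connect 26-neighbours on the lattice.
#' Edge weight = Euclidean length times the fiber discount \code{alpha} when
#' both endpoints lie in the fiber-tract mask, so trunks preferentially
#' follow fiber tracts. The lattice can be built once per atlas and reused
#' across axons via [buildSteinerGraph()].
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param latticeStep lattice stride in voxels (default 2).
#' @param alpha fiber-tract edge discount in (0, 1]; 1 disables the
#'   preference (default 0.5).
#' @return list with the igraph \code{graph}, vertex \code{coords} (matrix)
#'   and logical \code{fiber} flags.
#' @export
makeLatticeGraph <- function(atlas, latticeStep = 2L, alpha = 0.5) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  d <- dim(atlas@annotation)
  ii <- seq(1L, d[1], by = latticeStep)
  jj <- seq(1L, d[2], by = latticeStep)
  kk <- seq(1L, d[3], by = latticeStep)
  grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  lin <- grid[, 1] + d[1] * (grid[, 2] - 1L + d[2] * (grid[, 3] - 1L))
  inBrain <- atlas@annotation[lin] > 0L
  grid <- grid[inBrain, , drop = FALSE]
  lin <- lin[inBrain]
  nV <- nrow(grid)
  if (!nV) stop("no in-brain lattice vertices; check the atlas or the step")
  coords <- voxelCenter(atlas, grid - 1L)
  fiber <- atlas@fiberMask[lin]

  # index lookup on the sublattice
  li <- array(NA_integer_, c(length(ii), length(jj), length(kk)))
  gi <- match(grid[, 1], ii); gj <- match(grid[, 2], jj); gk <- match(grid[, 3], kk)
  li[cbind(gi, gj, gk)] <- seq_len(nV)

  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  offsets <- offsets[offsets[, 1] > 0 | (offsets[, 1] == 0 & offsets[, 2] > 0) |
                       (offsets[, 1] == 0 & offsets[, 2] == 0 & offsets[, 3] > 0),
                     , drop = FALSE]     # half of the 26 neighbours
  from <- integer(0); to <- integer(0)
  dims <- c(length(ii), length(jj), length(kk))
  for (o in seq_len(nrow(offsets))) {
    ni <- gi + offsets[o, 1]; nj <- gj + offsets[o, 2]; nk <- gk + offsets[o, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] & nk >= 1L & nk <= dims[3]
    tgt <- rep(NA_integer_, nV)
    tgt[ok] <- li[cbind(ni[ok], nj[ok], nk[ok])]
    keep <- !is.na(tgt)
    from <- c(from, which(keep)); to <- c(to, tgt[keep])
  }
  len <- sqrt(rowSums((coords[from, , drop = FALSE] - coords[to, , drop = FALSE])^2))
  w <- len * ifelse(fiber[from] & fiber[to], alpha, 1)
  g <- igraph::make_empty_graph(nV, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  igraph::E(g)$length <- len
  list(graph = g, coords = coords, fiber = fiber, alpha = alpha,
       latticeStep = latticeStep)
}

#' Build the Steiner graph for one axon
#'
#' Adds the source point and target points as vertices on top of the shared
#' lattice, each snapped (connected) to its nearest lattice vertex; checks
#' that every target is reachable from the source.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param source soma position (3-vector, micrometres).
#' @param targets matrix of target points (one per row).
#' @param latticeStep,alpha see [makeLatticeGraph()].
#' @param lattice optional precomputed lattice from [makeLatticeGraph()].
#' @return list of class \code{SteinerGraph}: igraph \code{graph}, vertex
#'   \code{coords}, \code{sourceV}, \code{targetV} (vertex indices).
#' @export
buildSteinerGraph <- function(atlas, source, targets, latticeStep = 2L,
                              alpha = 0.5, lattice = NULL) {
  if (is.null(lattice)) lattice <- makeLatticeGraph(atlas, latticeStep, alpha)
  targets <- rbind(targets)
  pts <- rbind(source, targets)
  if (any(is.na(annotationAt(atlas, worldToVoxel(atlas, pts))))) {
    stop("source or target outside the atlas raster")
  }
  g <- lattice$graph
  coords <- lattice$coords
  fiber <- lattice$fiber
  nL <- nrow(coords)
  nP <- nrow(pts)
  g <- igraph::add_vertices(g, nP)
  ptFiber <- {
    ijk <- worldToVoxel(atlas, pts)
    d <- dim(atlas@fiberMask)
    lin <- 1L + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
    atlas@fiberMask[lin]
  }
  for (p in seq_len(nP)) {
    d2 <- rowSums(sweep(coords, 2L, pts[p, ])^2)
    nearest <- which.min(d2)
    len <- sqrt(d2[nearest])
    w <- max(len, 1e-9) * ifelse(ptFiber[p] & fiber[nearest], lattice$alpha, 1)
    g <- igraph::add_edges(g, c(nL + p, nearest), weight = w, length = len)
  }
  allCoords <- rbind(coords, pts)
  sourceV <- nL + 1L
  targetV <- nL + 1L + seq_len(nP - 1L)
  comp <- igraph::components(g)$membership
  bad <- which(comp[targetV] != comp[sourceV])
  if (length(bad)) {
    stop("target(s) disconnected from the source: ",
         paste(apply(targets[bad, , drop = FALSE], 1L,
                     function(x) paste0("(", paste(round(x, 1), collapse = ","), ")")),
               collapse = ", "))
  }
  structure(list(graph = g, coords = allCoords, sourceV = sourceV,
                 targetV = targetV, nLattice = nL), class = "SteinerGraph")
}

#' Heuristic weighted Steiner tree
#'
#' Iterative nearest-terminal shortest-path insertion (a Prim-style
#' 2-approximation): starting from the source, repeatedly connect the
#' terminal with the cheapest weighted shortest path to the current tree.
#' The classical metric-closure construction (MST of the terminal distance
#' closure expanded to shortest paths) is built as a second candidate, and
#' both are refined by an MST over their vertex set with non-terminal
#' leaves pruned, followed by a key-path exchange local search (each tree
#' path between branch/terminal vertices is swapped for the true shortest
#' path between the two components it separates, until no swap helps). The
#' 2-approximation bound is preserved since no step increases the weight.
#' The result is verified to be a tree spanning the source and all targets.
#'
#' @param sg a \code{SteinerGraph} from [buildSteinerGraph()], or a plain
#'   list with \code{graph}, \code{sourceV}, \code{targetV}.
#' @return list with \code{edges} (2-column matrix of vertex indices),
#'   \code{vertices} (vertex indices used), \code{weight} (total edge
#'   weight) and \code{parent} (named parent map rooted at the source).
#' @export
steinerTree <- function(sg) {
  g <- sg$graph
  insertion <- insertionTreeEdges(g, sg$sourceV, sg$targetV)
  kmb <- kmbTreeEdges(g, sg$sourceV, sg$targetV)
  terminals <- c(sg$sourceV, sg$targetV)
  cand <- list(improveTreeEdges(g, insertion, terminals),
               improveTreeEdges(g, kmb, terminals))
  weights <- vapply(cand, function(e) edgeSetWeight(g, e), 0)
  edges <- cand[[which.min(weights)]]
  edges <- keyPathExchange(g, edges, terminals)
  w <- edgeSetWeight(g, edges)
  verts <- unique(as.integer(edges))
  if (length(verts) && nrow(edges) != length(verts) - 1L) {
    stop("internal error: Steiner result is not a tree")
  }
  parent <- rep(NA_integer_, length(verts))
  names(parent) <- verts
  # orient edges away from the source by BFS
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  visited <- as.character(sg$sourceV)
  queue <- sg$sourceV
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (u in adj[[as.character(v)]]) {
      cu <- as.character(u)
      if (!(cu %in% visited)) {
        visited <- c(visited, cu)
        parent[cu] <- v
        queue <- c(queue, u)
      }
    }
  }
  list(edges = edges, vertices = verts, weight = w, parent = parent)
}

edgeSetWeight <- function(g, edges) {
  if (!nrow(edges)) return(0)
  sum(igraph::E(g)$weight[igraph::get_edge_ids(g, t(edges))])
}

# Iterative nearest-terminal shortest-path insertion.
insertionTreeEdges <- function(g, sourceV, targetV) {
  inTree <- sourceV
  remaining <- targetV
  edges <- matrix(integer(0), 0L, 2L)
  while (length(remaining)) {
    dm <- igraph::distances(g, v = remaining, to = inTree)
    hit <- arrayInd(which.min(dm), dim(dm))
    term <- remaining[hit[1L]]
    attach <- inTree[hit[2L]]
    path <- as.integer(igraph::shortest_paths(g, from = attach, to = term,
                                              output = "vpath")$vpath[[1L]])
    firstContact <- max(which(path %in% inTree))
    path <- path[firstContact:length(path)]
    if (length(path) >= 2L) {
      edges <- rbind(edges, cbind(path[-length(path)], path[-1L]))
      inTree <- c(inTree, path[-1L])
    }
    remaining <- setdiff(remaining, term)
  }
  edges
}

# Classical metric-closure (KMB) construction: MST of the terminal distance
# closure, expanded back to shortest paths in g.
kmbTreeEdges <- function(g, sourceV, targetV) {
  terms <- c(sourceV, targetV)
  if (length(terms) < 2L) return(matrix(integer(0), 0L, 2L))
  dm <- igraph::distances(g, v = terms, to = terms)
  dm <- (dm + t(dm)) / 2                 # symmetrize float dust
  mc <- igraph::graph_from_adjacency_matrix(dm, weighted = TRUE,
                                            mode = "undirected")
  mcMst <- igraph::mst(mc)
  el <- igraph::as_edgelist(mcMst, names = FALSE)
  edges <- matrix(integer(0), 0L, 2L)
  for (q in seq_len(nrow(el))) {
    path <- as.integer(igraph::shortest_paths(g, from = terms[el[q, 1]],
                                              to = terms[el[q, 2]],
                                              output = "vpath")$vpath[[1L]])
    if (length(path) >= 2L) {
      edges <- rbind(edges, cbind(path[-length(path)], path[-1L]))
    }
  }
  unique(edges)
}

# Key-path exchange local search: remove one key path (a maximal tree path
# whose interior vertices have degree 2 and are not terminals) and
# reconnect the two components with the true shortest path between them;
# repeat until no exchange reduces the weight.
keyPathExchange <- function(g, edges, terminals, maxRounds = 25L) {
  for (round in seq_len(maxRounds)) {
    if (nrow(edges) < 2L) return(edges)
    vs <- as.integer(edges)
    deg <- table(vs)
    keyV <- union(terminals, as.integer(names(deg)[deg >= 3L]))
    paths <- splitKeyPaths(edges, keyV)
    improved <- FALSE
    for (pth in paths) {
      pEdges <- pth$edges
      wP <- edgeSetWeight(g, pEdges)
      rest <- edges[!edgeRowIn(edges, pEdges), , drop = FALSE]
      compA <- reachableFrom(rest, pth$endA, c(pth$endA, pth$endB))
      compB <- reachableFrom(rest, pth$endB, c(pth$endA, pth$endB))
      dm <- igraph::distances(g, v = compA, to = compB)
      best <- min(dm)
      if (best < wP - 1e-9) {
        hit <- arrayInd(which.min(dm), dim(dm))
        sp <- as.integer(igraph::shortest_paths(
          g, from = compA[hit[1L]], to = compB[hit[2L]],
          output = "vpath")$vpath[[1L]])
        # trim to the segment between the last A contact and first B contact
        lastA <- max(which(sp %in% compA))
        sp <- sp[lastA:length(sp)]
        firstB <- min(which(sp %in% compB))
        sp <- sp[1:firstB]
        if (length(sp) >= 2L) {
          edges <- rbind(rest, cbind(sp[-length(sp)], sp[-1L]))
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) return(edges)
  }
  edges
}

# Decompose a tree edge set into key paths between key vertices.
splitKeyPaths <- function(edges, keyV) {
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  paths <- list()
  seen <- character(0)
  for (kv in keyV) {
    for (nb in adj[[as.character(kv)]]) {
      chain <- c(kv, nb)
      prev <- kv
      cur <- nb
      while (!(cur %in% keyV)) {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        prev <- cur
        cur <- nxt[1L]
        chain <- c(chain, cur)
      }
      tag <- paste(min(chain[1L], chain[length(chain)]),
                   max(chain[1L], chain[length(chain)]),
                   paste(sort(chain), collapse = "-"))
      if (tag %in% seen) next
      seen <- c(seen, tag)
      paths[[length(paths) + 1L]] <- list(
        endA = chain[1L], endB = chain[length(chain)],
        edges = cbind(chain[-length(chain)], chain[-1L]))
    }
  }
  paths
}

edgeRowIn <- function(edges, sub) {
  key <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key(edges) %in% key(sub)
}

# Vertices reachable from `start` in an edge set (tree components).
reachableFrom <- function(edges, start, seeds) {
  if (!nrow(edges)) return(start)
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  out <- start
  queue <- start
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (u in adj[[as.character(v)]]) {
      if (!(u %in% out)) { out <- c(out, u); queue <- c(queue, u) }
    }
  }
  out
}

# Improvement shared by both constructions: minimum spanning tree over the
# used vertex set, then iterative pruning of non-terminal leaves. Never
# worse than the input edge set.
improveTreeEdges <- function(g, edges, terminals) {
  if (!nrow(edges)) return(edges)
  verts0 <- unique(c(terminals[1L], as.integer(edges)))
  gTag <- g
  igraph::V(gTag)$origId <- seq_len(igraph::vcount(gTag))
  sub <- igraph::induced_subgraph(gTag, verts0)
  mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
  keepIds <- igraph::V(mst)$origId
  mstEdges <- igraph::as_edgelist(mst, names = FALSE)
  mstEdges <- cbind(keepIds[mstEdges[, 1]], keepIds[mstEdges[, 2]])
  repeat {
    vs <- as.integer(mstEdges)
    deg <- table(factor(vs, levels = unique(vs)))
    leaves <- as.integer(names(deg)[deg == 1L])
    drop <- setdiff(leaves, terminals)
    if (!length(drop)) break
    keep <- !(mstEdges[, 1] %in% drop | mstEdges[, 2] %in% drop)
    mstEdges <- mstEdges[keep, , drop = FALSE]
  }
  mstEdges
}

#' Exact minimum Steiner tree weight (Dreyfus-Wagner dynamic program)
#'
#' Exponential in the number of terminals; intended as the independent
#' optimality oracle on small instances (tests and acceptance use at most 6
#' terminals on at most 60 vertices).
#'
#' @param g an igraph with edge weights.
#' @param terminals vertex indices to span.
#' @return the optimal total weight.
#' @export
exactSteinerWeight <- function(g, terminals) {
  terminals <- unique(as.integer(terminals))
  k <- length(terminals)
  if (k <= 1L) return(0)
  d <- igraph::distances(g)
  if (k == 2L) return(d[terminals[1L], terminals[2L]])
  n <- igraph::vcount(g)
  q <- terminals[k]
  ts <- terminals[-k]
  m <- k - 1L
  nSub <- bitwShiftL(1L, m) - 1L
  dp <- matrix(Inf, nSub, n)
  for (t in seq_len(m)) {
    dp[bitwShiftL(1L, t - 1L), ] <- d[ts[t], ]
  }
  sizes <- vapply(seq_len(nSub), function(S) sum(bitwAnd(S, bitwShiftL(1L, 0:(m - 1))) > 0), 0L)
  for (S in order(sizes)) {
    if (sizes[S] < 2L) next
    f <- rep(Inf, n)
    sub <- bitwAnd(S - 1L, S)            # iterate proper non-empty subsets of S
    while (sub > 0L) {
      comp <- bitwAnd(S, bitwNot(sub))
      if (comp > 0L && sub < comp) {      # each split once
        cand <- dp[sub, ] + dp[comp, ]
        f <- pmin(f, cand)
      }
      sub <- bitwAnd(sub - 1L, S)
    }
    # dp[S][v] = min_w (f[w] + d(w, v)), and allow pure subset merge at v
    merged <- apply(d + f, 2L, min)       # d symmetric: column v = min_w f[w]+d[w,v]
    dp[S, ] <- pmin(merged, f)
  }
  dp[nSub, q]
}
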