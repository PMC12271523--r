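# Independent oracles shared across test files. These deliberately avoid the
# package's internal code paths: parent-chain walks on raw node tables,
# explicit BFS components, exhaustive Steiner enumeration.

# Path distance between two axon node ids through the tree.
oraclePathDistance <- function(nd, idA, idB) {
  chain <- function(id) {
    out <- numeric(0); ids <- integer(0)
    cur <- id
    while (cur != -1L) {
      row <- match(cur, nd$id)
      ids <- c(ids, cur)
      p <- nd$parent[row]
      if (p != -1L) {
        prow <- match(p, nd$id)
        out <- c(out, sqrt(sum((c(nd$x[row], nd$y[row], nd$z[row]) -
                                  c(nd$x[prow], nd$y[prow], nd$z[prow]))^2)))
      }
      cur <- p
    }
    list(ids = ids, segs = out)
  }
  a <- chain(idA); b <- chain(idB)
  common <- intersect(a$ids, b$ids)[1]
  da <- sum(a$segs[seq_len(match(common, a$ids) - 1L)])
  db <- sum(b$segs[seq_len(match(common, b$ids) - 1L)])
  da + db
}

# Connected components of a boolean adjacency matrix by BFS.
oracleComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Brute-force verification that a tuft partition obeys the dual-threshold
# single-linkage rule; returns the oracle component labels of the terminals.
oracleTuftComponents <- function(m, radialMax, pathMax) {
  leaves <- neuriteLeaves(m, "axon")
  nd <- morphNodes(m)
  nL <- nrow(leaves)
  adj <- matrix(FALSE, nL, nL)
  if (nL > 1L) {
    for (i in seq_len(nL - 1L)) for (j in (i + 1L):nL) {
      eu <- sqrt(sum((unlist(leaves[i, c("x", "y", "z")]) -
                        unlist(leaves[j, c("x", "y", "z")]))^2))
      pd <- oraclePathDistance(nd, leaves$id[i], leaves$id[j])
      adj[i, j] <- adj[j, i] <- eu <= radialMax && pd <= pathMax
    }
  }
  oracleComponents(adj)
}

# Random connected weighted graph for Steiner oracle tests.
randomConnectedGraph <- function(n) {
  repeat {
    g <- igraph::sample_gnp(n, 3 / n)
    if (igraph::is_connected(g)) break
  }
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.5, 2)
  g
}

# Exhaustive minimum Steiner weight over all vertex subsets (tiny graphs).
bruteForceSteiner <- function(g, terminals) {
  n <- igraph::vcount(g)
  others <- setdiff(seq_len(n), terminals)
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    extra <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
    vs <- c(terminals, extra)
    sub <- igraph::induced_subgraph(g, vs)
    if (!igraph::is_connected(sub)) next
    best <- min(best, sum(igraph::E(igraph::mst(sub))$weight))
  }
  best
}
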