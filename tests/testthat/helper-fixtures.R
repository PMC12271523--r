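# Shared fixture builders: random trees, small atlases, tiny morphologies.

# Random rooted tree morphology: soma root, axon nodes attached to a random
# existing axon node, random-walk geometry. Radii positive, coordinates
# finite by construction.
randomTreeMorphology <- function(nNodes = 30L, seed = 1L, step = 50,
                                 id = "rand") {
  withr::with_seed(seed, {
    nodes <- data.frame(id = 1L, parent = -1L, type = 1L,
                        x = 0, y = 0, z = 0, radius = 5)
    for (i in 2:nNodes) {
      cand <- if (i == 2L) 1L else 2:(i - 1L)
      parentRow <- cand[sample.int(length(cand), 1L)]
      p <- c(nodes$x[parentRow], nodes$y[parentRow], nodes$z[parentRow])
      q <- p + stats::rnorm(3L) * step
      nodes[i, ] <- list(i, nodes$id[parentRow], 2L, q[1], q[2], q[3], 0.5)
    }
    Morphology(nodes, id)
  })
}

# Straight 3-point axon: soma -> (10,0,0) -> (20,0,0).
straightAxon <- function() {
  Morphology(data.frame(
    id = 1:3, parent = c(-1L, 1L, 2L), type = c(1L, 2L, 2L),
    x = c(0, 10, 20), y = 0, z = 0, radius = c(5, 0.5, 0.5)), "straight")
}

# Symmetric Y: stem to (0,10,0), branches to (10,10,0) and (-10,10,0):
# the two child sections meet at 90 degrees at the fork.
symmetricY <- function() {
  Morphology(data.frame(
    id = 1:5, parent = c(-1L, 1L, 2L, 3L, 3L), type = c(1L, rep(2L, 4)),
    x = c(0, 0, 0, 10, -10), y = c(0, 5, 10, 20, 20), z = 0,
    radius = c(5, rep(0.5, 4))), "ytree")
}

# Two-region toy atlas (plus background), no mirroring subtleties needed in
# most unit tests; regions A and B separated by 2 empty-background voxels.
twoRegionAtlas <- function(voxelSize = 100) {
  buildToyAtlas(list(
    dims = c(16L, 8L, 8L), voxel_size = voxelSize, origin = c(0, 0, 0),
    mirror_axis = 1L, background = "BG",
    regions = list(
      list(acronym = "A", parent = "root", box = rbind(c(2, 3), c(3, 6), c(3, 6))),
      list(acronym = "B", parent = "root", box = rbind(c(6, 7), c(3, 6), c(3, 6)))),
    fibers = list()))
}

# Deterministic per-test RNG guard.
localSeed <- function(seed) withr::local_seed(seed, .local_envir = parent.frame())

# Voxel centers of a region subtree, recomputed independently of the
# package's regionVoxels internals.
voxelCenterOf <- function(atlas, region) {
  h <- regionHierarchy(atlas)
  id <- h$id[match(region, h$acronym)]
  ids <- id
  frontier <- id
  while (length(frontier)) {
    frontier <- h$id[!is.na(h$parent_id) & h$parent_id %in% frontier]
    ids <- c(ids, frontier)
  }
  lin <- which(atlas@annotation %in% ids)
  ijk <- arrayInd(lin, dim(atlas@annotation)) - 1L
  (ijk + 0.5) * voxelSize(atlas)
}

# Total cable length of a morphology from the node table (all segments,
# including the soma-to-neurite stem), independent of the package's
# section decomposition.
cableLength <- function(m) {
  nd <- morphNodes(m)
  p <- match(nd$parent, nd$id)
  ok <- !is.na(p)
  sum(sqrt((nd$x[ok] - nd$x[p[ok]])^2 + (nd$y[ok] - nd$y[p[ok]])^2 +
             (nd$z[ok] - nd$z[p[ok]])^2))
}
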