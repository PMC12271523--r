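# Cluster assignment, target choice, trunk post-processing, tuft growth and
# population synthesis.

demoInputs <- function(n = 20L, seed = 5L) {
  atlas <- demoToyAtlas()
  pop <- generatePopulation(demoPopulationSpec(n), atlas, seed = seed)
  se <- stackPopulation(lapply(pop$morphologies, computeProjectionFeatures,
                               atlas = atlas, level = 2))
  X <- t(SummarizedExperiment::assay(se, "lengths"))
  model <- selectGMM(X, imposedC = min(5L, n), seed = 2, sourceRegion = "PRE")
  cl <- classifyAxons(model, X)
  names(cl) <- colnames(se)
  lib <- buildTuftLibrary(pop$morphologies, atlas, cl, level = 2)
  stats <- targetStatistics(se, cl, lib)
  list(atlas = atlas, se = se, model = model, clusters = cl, lib = lib,
       stats = stats)
}

test_that("cluster assignment follows the mixture weights", {
  d <- demoInputs(12)
  m1 <- d$model
  m1@weights <- c(1, rep(0, nClusters(m1) - 1))
  expect_true(all(assignCluster(m1, 50, seed = 1) == 1L))
  draws <- assignCluster(d$model, 10000L, seed = 3)
  freq <- table(factor(draws, levels = seq_len(nClusters(d$model)))) / 10000
  w <- clusterWeights(d$model)
  expect_true(all(abs(freq - w) <= 3 * sqrt(w * (1 - w) / 10000) + 1e-9))
  expect_identical(assignCluster(d$model, 10, seed = 7),
                   assignCluster(d$model, 10, seed = 7))
})

test_that("target selection respects probabilities and count statistics", {
  atlas <- demoToyAtlas()
  stats <- data.frame(cluster = 1L, region = c("RA", "RB"),
                      prob = c(1, 0.3), mean_count = c(2, 1), sd_count = 0,
                      n_members = 10L)
  # always-targeted region always selected; sd 0 gives the mean exactly
  hitsB <- 0L
  nTrial <- 400L
  for (s in seq_len(nTrial)) {
    t <- chooseTargets(stats, 1L, atlas, "left", seed = s)
    expect_true("RA" %in% t$region)
    expect_identical(sum(t$region == "RA"), 2L)
    if ("RB" %in% t$region) hitsB <- hitsB + 1L
  }
  expect_lt(abs(hitsB / nTrial - 0.3), 3 * sqrt(0.3 * 0.7 / nTrial))
  # empty selection falls back to the max-probability region
  statsLow <- data.frame(cluster = 1L, region = c("RA", "RB"),
                         prob = c(1e-9, 2e-9), mean_count = 1, sd_count = 0,
                         n_members = 10L)
  t <- chooseTargets(statsLow, 1L, atlas, "left", seed = 1)
  expect_identical(unique(t$region), "RB")
  # contra regions resolve to the opposite hemisphere
  statsC <- data.frame(cluster = 1L, region = "RB_contra", prob = 1,
                       mean_count = 2, sd_count = 0, n_members = 5L)
  tC <- chooseTargets(statsC, 1L, atlas, "left", seed = 2)
  expect_true(all(hemisphereOf(atlas, as.matrix(tC[, c("x", "y", "z")])) == "right"))
  expect_error(chooseTargets(stats, 99L, atlas, "left"), "99")
})

test_that("noise-free post-processing reproduces the tree geometry", {
  atlas <- twoRegionAtlas()
  src <- c(250, 450, 450)
  tgt <- rbind(c(650, 450, 450), c(250, 550, 550))
  sg <- buildSteinerGraph(atlas, src, tgt, latticeStep = 1L)
  tree <- steinerTree(sg)
  post <- postprocessTrunk(tree, sg, step = 40, noiseWeight = 0,
                           historyWeight = 0, seed = 1)
  nd <- morphNodes(post$morphology)
  # target endpoints preserved exactly
  for (ti in seq_len(nrow(tgt))) {
    tn <- post$targetNodes[post$targetNodes$vertex == sg$targetV[ti], ]
    expect_identical(nrow(tn), 1L)
    expect_equal(unlist(nd[nd$id == tn$node, c("x", "y", "z")], use.names = FALSE),
                 tgt[ti, ], tolerance = 1e-9)
  }
  # with zero noise the resampled length equals the waypoint length
  treeLen <- sum(igraph::E(sg$graph)$length[igraph::get_edge_ids(sg$graph,
                                                                 t(tree$edges))])
  expect_equal(cableLength(post$morphology), treeLen, tolerance = 1e-6)
  expect_error(postprocessTrunk(tree, sg, noiseWeight = 0.6, historyWeight = 0.5),
               "n \\+ r")
})

test_that("tortuosity grows with the trunk noise weight", {
  atlas <- twoRegionAtlas()
  src <- c(250, 450, 450)
  tgt <- rbind(c(1050, 450, 450))          # straight east run
  sg <- buildSteinerGraph(atlas, src, tgt, latticeStep = 1L)
  tree <- steinerTree(sg)
  tort <- function(nw) {
    mean(vapply(1:30, function(s) {
      post <- postprocessTrunk(tree, sg, step = 25, noiseWeight = nw,
                               historyWeight = 0.2, seed = s)
      cableLength(post$morphology) / sqrt(sum((tgt[1, ] - src)^2))
    }, 0))
  }
  t05 <- tort(0.05); t3 <- tort(0.3)
  expect_gte(t05, 1 - 1e-6)
  expect_gt(t3, t05)
})

test_that("tuft growth follows the barcode exactly", {
  # single bar: unbranched path of length L
  m <- growTuft(rbind(c(0, 100)), root = c(0, 0, 0),
                initialDirection = c(1, 0, 0), step = 20, noise = 0,
                seed = 1)
  f <- computeMorphometrics(m, "axon")
  expect_identical(f$number_of_leaves, 1L)
  expect_equal(f$total_length, 100, tolerance = 1e-9)
  # Y barcode: two leaves, fork at path distance 10
  y <- growTuft(rbind(c(0, 30), c(10, 30)), root = c(0, 0, 0),
                initialDirection = c(0, 0, 1), step = 4, noise = 0.2, seed = 2)
  fy <- computeMorphometrics(y, "axon")
  expect_identical(fy$number_of_leaves, 2L)
  expect_equal(sort(fy$path_distances_to_root), c(30, 30), tolerance = 1e-6)
  nd <- morphNodes(y)
  fork <- nd$id[duplicated(nd$parent) & nd$parent > 0]
  forkParent <- nd$parent[match(fork, nd$id)]
  pd <- fy$path_distances_to_root
  # the fork sits at path distance 10 (within one step)
  kids <- table(nd$parent)
  forkId <- as.integer(names(kids)[kids >= 2 & names(kids) != "-1"])
  # walk from the fork to the root accumulating length
  acc <- 0; cur <- forkId[1]
  while (nd$parent[match(cur, nd$id)] != -1L) {
    p <- nd$parent[match(cur, nd$id)]
    acc <- acc + sqrt(sum((unlist(nd[match(cur, nd$id), c("x", "y", "z")]) -
                             unlist(nd[match(p, nd$id), c("x", "y", "z")]))^2))
    cur <- p
  }
  expect_lte(abs(acc - 10), 4 + 1e-9)
  # random barcodes from real trees: leaf count = bar count, terminal path
  # distances within one step of the deaths
  for (s in 1:8) {
    src <- randomTreeMorphology(nNodes = sample(12:30, 1), seed = 400 + s)
    ex <- extractTufts(src, radialMax = 1e9, pathMax = 1e9)
    if (!length(ex$tufts)) next
    bc <- ex$tufts[[1]]$barcode
    grown <- growTuft(bc, root = c(0, 0, 0), initialDirection = c(1, 0, 0),
                      step = 15, noise = 0.3, seed = s)
    fg <- computeMorphometrics(grown, "axon")
    expect_identical(fg$number_of_leaves, nrow(bc))
    expect_equal(sort(fg$path_distances_to_root), sort(bc[, "death"]),
                 tolerance = 1e-6)
  }
  expect_error(growTuft(rbind(c(10, 5)), c(0, 0, 0)), "malformed")
  expect_error(growTuft(rbind(c(5, 30)), c(0, 0, 0)), "malformed")
})

test_that("containment keeps tuft leaves inside the requested region", {
  atlas <- twoRegionAtlas()
  inside <- function(p) {
    r <- regionAt(atlas, p)
    !is.na(r) && r == "A"
  }
  root <- samplePointInRegion(atlas, "A", seed = 3)[1, ]
  for (s in 1:5) {
    m <- growTuft(rbind(c(0, 300), c(40, 300), c(80, 200)), root = root,
                  initialDirection = c(1, 0, 0), step = 25, noise = 0.5,
                  seed = s, inside = inside)
    lv <- neuriteLeaves(m, "axon")
    expect_true(all(regionAt(atlas, as.matrix(lv[, c("x", "y", "z")])) == "A"))
  }
})

test_that("synthesized populations cover their targets deterministically", {
  d <- demoInputs(20, seed = 9)
  somata <- samplePointInRegion(d$atlas, "PRE", n = 8, hemisphere = "left",
                                seed = 4)
  cfg <- synthesisConfig(latticeStep = 1L)
  res <- synthesizePopulation(somata, d$model, d$stats, d$lib, d$atlas, cfg,
                              seed = 21)
  expect_length(res$morphologies, 8L)
  for (i in seq_len(8)) {
    m <- res$morphologies[[i]]
    expect_true(validObject(m))
    f <- computeProjectionFeatures(m, d$atlas, level = 2)
    regions <- strsplit(res$manifest$regions[i], ";")[[1]]
    # every selected region contains at least one terminal of this axon
    expect_true(all(regions %in% names(f$terminals)[f$terminals > 0]))
  }
  # determinism: identical master seed gives identical node tables
  res2 <- synthesizePopulation(somata, d$model, d$stats, d$lib, d$atlas, cfg,
                               seed = 21)
  for (i in seq_len(8)) {
    expect_identical(morphNodes(res$morphologies[[i]]),
                     morphNodes(res2$morphologies[[i]]))
  }
  expect_identical(res$manifest, res2$manifest)
})
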