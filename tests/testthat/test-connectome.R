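# Touch detection, inter-bouton filtering, density pruning and aggregation.

# Minimal axon along the x axis at a given offset.
lineAxon <- function(id, y = 0, z = 0, x0 = 0, x1 = 100, n = 5L) {
  xs <- seq(x0, x1, length.out = n)
  nodes <- data.frame(id = 1L, parent = -1L, type = 1L, x = xs[1] - 10,
                      y = y, z = z, radius = 5)
  for (q in seq_along(xs)) {
    nodes[q + 1L, ] <- list(q + 1L, q, 2L, xs[q], y, z, 0.5)
  }
  Morphology(nodes, id)
}

lineDendrite <- function(id, y = 0, z = 0, x0 = 0, x1 = 100, n = 5L) {
  m <- lineAxon(id, y, z, x0, x1, n)
  nd <- morphNodes(m)
  nd$type[nd$type == 2L] <- 3L
  Morphology(nd, id)
}

test_that("parallel close segments touch once per overlapping pair", {
  pre <- lineAxon("a", y = 0)
  post <- lineDendrite("d", y = 1)        # 1 um apart
  touches <- detectTouches(list(pre), list(post), touchDistance = 2)
  expect_gt(nrow(touches), 0)
  expect_true(all(touches$dist <= 2))
  expect_true(all(touches$pre == "a" & touches$post == "d"))
  # out of range: no touches
  far <- lineDendrite("far", y = 50)
  expect_identical(nrow(detectTouches(list(pre), list(far), touchDistance = 2)), 0L)
})

test_that("segments of the same neuron never touch each other", {
  nodes <- morphNodes(lineAxon("self", y = 0))
  dend <- morphNodes(lineDendrite("self", y = 1))
  dend <- dend[dend$type == 3L, ]
  dend$id <- dend$id + 100L
  dend$parent <- c(1L, dend$id[-nrow(dend)])
  both <- Morphology(rbind(nodes, dend), "self")
  expect_identical(nrow(detectTouches(list(both), list(both),
                                      touchDistance = 5)), 0L)
})

test_that("hashed detection equals brute-force all-pairs on random scenes", {
  atlas <- twoRegionAtlas()
  for (s in 1:5) {
    pre <- lapply(1:4, function(i)
      randomTreeMorphology(nNodes = 15L, seed = 500 + 10 * s + i, step = 80,
                           id = paste0("pre", i)))
    post <- generateScene(6L, atlas, totalLength = 600, branches = 3L,
                          step = 30, seed = 600 + s)
    # place the axons near the dendrites so touches actually occur
    pre <- lapply(seq_along(pre), function(i) {
      nd <- morphNodes(pre[[i]])
      ctr <- somaCenter(post[[i %% length(post) + 1L]])
      nd$x <- nd$x + ctr[1]; nd$y <- nd$y + ctr[2]; nd$z <- nd$z + ctr[3]
      Morphology(nd, neuronId(pre[[i]]))
    })
    fast <- detectTouches(pre, post, touchDistance = 20)
    slow <- detectTouchesBruteForce(pre, post, touchDistance = 20)
    key <- function(df) {
      k <- sprintf("%s|%s|%.6f|%.6f|%.6f", df$pre, df$post, df$x, df$y, df$z)
      sort(k)
    }
    expect_identical(key(fast), key(slow))
  }
})

test_that("inter-bouton filtering keeps greedy maximal spacing", {
  touches <- data.frame(pre = "a", post = c("d1", "d2", "d3"),
                        x = 0, y = 0, z = 0, arc = c(0, 3, 8),
                        branch = 1L, dist = 0.5)
  kept <- filterInterbouton(touches, interval = 5)
  expect_identical(kept$arc, c(0, 8))     # the 3-um neighbour is dropped
  expect_identical(nrow(filterInterbouton(touches, interval = 0)), 3L)
  # greedy equals an independent reimplementation on random inputs
  localSeed(31)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    touches <- data.frame(pre = sample(c("a", "b"), n, replace = TRUE),
                          post = "d", x = 0, y = 0, z = 0,
                          arc = stats::runif(n, 0, 100),
                          branch = sample(1:3, n, replace = TRUE), dist = 0.5)
    kept <- filterInterbouton(touches, interval = 7)
    for (g in unique(paste(touches$pre, touches$branch))) {
      rows <- which(paste(touches$pre, touches$branch) == g)
      arcs <- sort(touches$arc[rows])
      ref <- arcs[1]; keepArcs <- arcs[1]
      for (a in arcs[-1]) if (a - ref >= 7) { keepArcs <- c(keepArcs, a); ref <- a }
      got <- sort(kept$arc[paste(kept$pre, kept$branch) == g])
      expect_equal(got, keepArcs)
    }
  }
})

test_that("density pruning caps synapse counts per postsynaptic neuron", {
  touches <- data.frame(pre = "a", post = rep(c("d1", "d2"), c(10, 4)),
                        x = 0, y = 0, z = 0, arc = 1:14, branch = 1L,
                        dist = 0.5)
  lens <- c(d1 = 50, d2 = 1000)
  expect_identical(nrow(pruneToDensity(touches, 1e6, lens, seed = 1)), 14L)
  expect_identical(nrow(pruneToDensity(touches, 0, lens, seed = 1)), 0L)
  pr <- pruneToDensity(touches, 0.1, lens, seed = 1)
  expect_identical(sum(pr$post == "d1"), 5L)   # floor(0.1 * 50)
  expect_identical(sum(pr$post == "d2"), 4L)   # under the cap: all kept
  expect_identical(pruneToDensity(touches, 0.1, lens, seed = 3),
                   pruneToDensity(touches, 0.1, lens, seed = 3))
})

test_that("aggregation yields consistent adjacency, projectome and degrees", {
  atlas <- twoRegionAtlas()
  pA <- samplePointInRegion(atlas, "A", seed = 1)[1, ]
  pB <- samplePointInRegion(atlas, "B", seed = 2)[1, ]
  synapses <- data.frame(
    pre = c("n1", "n1", "n1", "n2"), post = c("m1", "m1", "m2", "m1"),
    x = c(pA[1], pA[1], pB[1], pB[1]), y = c(pA[2], pA[2], pB[2], pB[2]),
    z = c(pA[3], pA[3], pB[3], pB[3]), arc = 1:4, branch = 1L, dist = 0.5)
  cn <- buildConnectome(synapses, atlas, level = "leaf",
                        preSomaRegions = c(n1 = "A", n2 = "A"))
  expect_identical(sum(projectome(cn)), 4)
  expect_identical(sum(adjacencyMatrix(cn)), 4)
  expect_equal(as.numeric(projectome(cn)["A", "B"]), 2)
  od <- outDegree(cn)
  expect_equal(unname(od["n1"]), 2)        # distinct partners
  expect_equal(unname(outDegree(cn, "synapses")["n1"]), 3)
  # single synapse: unit projectome entry
  cn1 <- buildConnectome(synapses[1, ], atlas, "leaf", c(n1 = "A"))
  expect_identical(sum(projectome(cn1)), 1)
  # brute-force recount of the out-degree histogram
  brute <- tapply(synapses$post, synapses$pre, function(p) length(unique(p)))
  expect_equal(unname(as.numeric(od[names(brute)])), unname(as.numeric(brute)))
  # serialization
  dir <- withr::local_tempdir()
  writeConnectome(cn, dir)
  expect_true(file.exists(file.path(dir, "synapses.csv")))
  adj <- Matrix::readMM(file.path(dir, "adjacency.mtx"))
  expect_equal(sum(adj), 4)
})

test_that("pipeline conservation: synapses within filtered within raw touches", {
  atlas <- twoRegionAtlas()
  pre <- lapply(1:3, function(i) {
    nd <- morphNodes(randomTreeMorphology(25L, seed = 700 + i, step = 60,
                                          id = paste0("p", i)))
    ctr <- samplePointInRegion(atlas, "A", seed = i)[1, ]
    nd$x <- nd$x + ctr[1]; nd$y <- nd$y + ctr[2]; nd$z <- nd$z + ctr[3]
    Morphology(nd, paste0("p", i))
  })
  post <- generateScene(8L, atlas, totalLength = 800, branches = 4L,
                        step = 25, region = "A", seed = 11)
  raw <- detectTouches(pre, post, touchDistance = 30)
  filt <- filterInterbouton(raw, 5)
  lens <- vapply(post, function(m)
    computeMorphometrics(m, "basal_dendrite")$total_length, 0)
  names(lens) <- vapply(post, neuronId, "")
  syn <- pruneToDensity(filt, 0.05, lens, seed = 2)
  expect_lte(nrow(syn), nrow(filt))
  expect_lte(nrow(filt), nrow(raw))
  key <- function(df) sprintf("%s|%s|%.4f|%.4f", df$pre, df$post, df$x, df$arc)
  expect_true(all(key(filt) %in% key(raw)))
  expect_true(all(key(syn) %in% key(filt)))
})
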