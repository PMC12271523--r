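# Tuft extraction, barcodes, grouping and representativity.

# Axon with two terminal pairs: one tight pair (mergeable), one far apart.
pairedTuftAxon <- function() {
  Morphology(data.frame(
    id = 1:8,
    parent = c(-1L, 1L, 2L, 3L, 3L, 2L, 6L, 6L),
    type = c(1L, rep(2L, 7)),
    x = c(0, 100, 2000, 2050, 2050, 100, 150, 150),
    y = c(0, 0, 0, 30, -30, 3000, 3030, 2970),
    z = 0, radius = c(5, rep(0.5, 7))), "paired")
}

test_that("close terminals merge into one tuft rooted at their ancestor", {
  m <- pairedTuftAxon()
  res <- extractTufts(m, radialMax = 300, pathMax = 300)
  expect_length(res$tufts, 2L)
  anc <- sort(vapply(res$tufts, `[[`, 0L, "ancestorId"))
  expect_identical(anc, c(3L, 6L))        # the two fork nodes
  # node conservation with ancestors owned by the tufts
  owned <- sum(vapply(res$tufts, `[[`, 0L, "ownedNodes"))
  expect_identical(nrow(morphNodes(res$trunk)) + owned, nrow(morphNodes(m)))
})

test_that("the path-distance constraint blocks radially close terminals", {
  # two terminals 60 um apart radially but ~4 mm apart along the tree
  m <- Morphology(data.frame(
    id = 1:6,
    parent = c(-1L, 1L, 2L, 3L, 2L, 5L),
    type = c(1L, rep(2L, 5)),
    x = c(0, 10, 1010, 2010, 10, 10),
    y = c(0, 0, 1000, 0, -1000, -2000),
    z = c(0, 0, 0, 30, 1000, 30),
    radius = c(5, rep(0.5, 5))), "farpath")
  leaves <- neuriteLeaves(m, "axon")
  euclid <- dist(as.matrix(leaves[, c("x", "y", "z")]))
  expect_lt(max(euclid), 3000)            # sanity: radial gap is moderate
  res <- extractTufts(m, radialMax = 3000, pathMax = 300)
  expect_length(res$tufts, 0L)            # path constraint blocks the merge
  res2 <- extractTufts(m, radialMax = 3000, pathMax = 1e7)
  expect_length(res2$tufts, 1L)
})

test_that("terminal clustering matches the brute-force constraint graph", {
  for (s in 1:30) {
    m <- randomTreeMorphology(nNodes = sample(15:45, 1), seed = 200 + s,
                              step = 120)
    res <- extractTufts(m, radialMax = 300, pathMax = 300)
    # independent oracle: pairwise double-threshold graph components
    leaves <- neuriteLeaves(m, "axon")
    nd <- morphNodes(m)
    nL <- nrow(leaves)
    adj <- matrix(FALSE, nL, nL)
    for (i in seq_len(nL)) for (j in seq_len(nL)) {
      if (i == j) next
      eu <- sqrt(sum((unlist(leaves[i, c("x", "y", "z")]) -
                        unlist(leaves[j, c("x", "y", "z")]))^2))
      pd <- oraclePathDistance(nd, leaves$id[i], leaves$id[j])
      adj[i, j] <- eu <= 300 && pd <= 300
    }
    comp <- oracleComponents(adj)
    sizes <- sort(table(comp))
    nMulti <- sum(sizes >= 2L)
    expect_length(res$tufts, nMulti)
    # every extracted tuft's leaf count equals its component size
    if (nMulti > 0) {
      tuftLeafCounts <- sort(vapply(res$tufts, function(t)
        t$morphometrics$number_of_leaves, 0L))
      expect_identical(tuftLeafCounts, as.integer(sort(sizes[sizes >= 2L])))
    }
    # node conservation
    owned <- sum(vapply(res$tufts, `[[`, 0L, "ownedNodes"))
    expect_identical(nrow(morphNodes(res$trunk)) + owned, nrow(morphNodes(m)))
  }
})

test_that("barcodes follow the elder rule with one bar per leaf", {
  # unbranched tuft of length L
  frag <- Morphology(data.frame(id = 1:3, parent = c(-1L, 1L, 2L),
                                type = 2L, x = c(0, 40, 100), y = 0, z = 0,
                                radius = 0.5), "line")
  bc <- tuftBarcode(frag)
  expect_equal(unname(bc), matrix(c(0, 100), 1))
  # Y with stem 10 and branches 20: bars (0,30) and (10,30)
  y <- Morphology(data.frame(id = 1:4, parent = c(-1L, 1L, 2L, 2L), type = 2L,
                             x = c(0, 10, 30, 30), y = c(0, 0, 5, -5) * 0,
                             z = 0, radius = 0.5), "y")
  # fix geometry: branches of length 20 from the fork at (10,0,0)
  y <- Morphology(data.frame(id = 1:4, parent = c(-1L, 1L, 2L, 2L), type = 2L,
                             x = c(0, 10, 30, 30), y = c(0, 0, 0, 0),
                             z = c(0, 0, 5, -5), radius = 0.5), "y")
  yNodes <- morphNodes(y)
  stopifnot(abs(sqrt(400 + 25) - sqrt(425)) < 1e-9)
  len <- 10 + sqrt(425)
  bcY <- tuftBarcode(y)
  expect_equal(sort(bcY[, "birth"]), c(0, 10), tolerance = 1e-9)
  expect_equal(unname(bcY[, "death"]), c(len, len), tolerance = 1e-9)
  # random trees: bar count = leaf count; max death = max path distance
  for (s in 1:10) {
    m <- randomTreeMorphology(nNodes = sample(10:40, 1), seed = 300 + s)
    ex <- extractTufts(m, radialMax = 1e9, pathMax = 1e9)  # one giant tuft
    if (!length(ex$tufts)) next
    t1 <- ex$tufts[[1]]
    expect_identical(nrow(t1$barcode), t1$morphometrics$number_of_leaves)
    expect_equal(max(t1$barcode[, "death"]),
                 max(t1$morphometrics$path_distances_to_root),
                 tolerance = 1e-9)
    expect_true(all(t1$barcode[, "death"] > t1$barcode[, "birth"] - 1e-12))
  }
})

test_that("group statistics use population variance and ignore input order", {
  mkTuft <- function(nid, region) {
    frag <- Morphology(data.frame(id = 1:2, parent = c(-1L, 1L), type = 2L,
                                  x = c(0, 50), y = 0, z = 0, radius = 0.5),
                       paste0(nid, "_t"))
    structure(list(neuronId = nid, ancestorXYZ = c(0, 0, 0), ancestorId = 1L,
                   morphology = frag, barcode = tuftBarcode(frag),
                   morphometrics = computeMorphometrics(frag, "axon"),
                   ownedNodes = 2L, ownsAncestor = TRUE), class = "Tuft")
  }
  tufts <- c(replicate(3, mkTuft("n1", "X"), simplify = FALSE),
             replicate(2, mkTuft("n2", "X"), simplify = FALSE),
             replicate(4, mkTuft("n2", "X"), simplify = FALSE)[0])
  clusters <- c(n1 = 1L, n2 = 1L)
  g <- groupTufts(tufts, clusters, rep("X", 5))
  expect_identical(nrow(g$groups), 1L)
  expect_equal(g$groups$mean_count, 2.5)            # counts 3 and 2
  expect_equal(g$groups$var_count, 0.25)            # population variance
  # order invariance
  perm <- c(4, 2, 5, 1, 3)
  g2 <- groupTufts(tufts[perm], clusters, rep("X", 5))
  expect_equal(g2$groups$mean_count, g$groups$mean_count)
  expect_equal(g2$groups$var_count, g$groups$var_count)
  # two axons with 2 and 4 tufts: mean 3, var 1
  tufts2 <- c(replicate(2, mkTuft("a", "X"), simplify = FALSE),
              replicate(4, mkTuft("b", "X"), simplify = FALSE))
  g3 <- groupTufts(tufts2, c(a = 1L, b = 1L), rep("X", 6))
  expect_equal(g3$groups$mean_count, 3)
  expect_equal(g3$groups$var_count, 1)
  expect_error(groupTufts(tufts, c(n1 = 1L), rep("X", 5)), "n2")
})

test_that("representativity is 1 for typical tufts and decays monotonically", {
  mkScaled <- function(scale, nid = "n") {
    frag <- Morphology(data.frame(id = 1:3, parent = c(-1L, 1L, 2L), type = 2L,
                                  x = c(0, 50 * scale, 100 * scale),
                                  y = 0, z = 0, radius = 0.5), nid)
    structure(list(neuronId = nid, ancestorXYZ = c(0, 0, 0), ancestorId = 1L,
                   morphology = frag, barcode = tuftBarcode(frag),
                   morphometrics = computeMorphometrics(frag, "axon"),
                   ownedNodes = 3L, ownsAncestor = TRUE), class = "Tuft")
  }
  identical5 <- replicate(5, mkScaled(1), simplify = FALSE)
  expect_equal(representativityScores(identical5), rep(1, 5))
  expect_equal(representativityScores(identical5[1]), 1)  # singleton
  # group with spread: the median tuft scores 1
  grp <- lapply(c(0.8, 0.9, 1, 1.1, 1.2), mkScaled)
  sc <- representativityScores(grp)
  expect_equal(sc[3], 1)
  # scaling one tuft away from the median decreases its score monotonically
  scores <- vapply(c(1.1, 1.5, 2.5, 4), function(s)
    representativityScores(c(grp[1:4], list(mkScaled(s))))[5], 0)
  expect_true(all(diff(scores) <= 1e-12))
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("the tuft library serializes to SWC fragments + JSON index", {
  atlas <- demoToyAtlas()
  pop <- generatePopulation(demoPopulationSpec(8), atlas, seed = 4)
  cl <- stats::setNames(rep(1L, 8), vapply(pop$morphologies, neuronId, ""))
  lib <- buildTuftLibrary(pop$morphologies, atlas, cl, level = 2)
  dir <- withr::local_tempdir()
  writeTuftLibrary(lib, dir)
  back <- readTuftLibrary(dir)
  expect_identical(length(back$tufts), length(lib$tufts))
  expect_equal(back$groups$mean_count, lib$groups$mean_count)
  for (i in seq_along(lib$tufts)) {
    expect_equal(unname(back$tufts[[i]]$barcode), unname(lib$tufts[[i]]$barcode),
                 tolerance = 1e-6)
  }
})
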