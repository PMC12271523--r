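# Gaussian mixture machinery: densities, posteriors, EM, BIC and sampling.

threeBlobs <- function(seed, n = 120L, sep = 8) {
  withr::with_seed(seed, {
    mu <- rbind(c(0, 0, 0), c(sep, 0, 0), c(0, sep, 0))
    k <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
    list(X = mu[k, ] + matrix(stats::rnorm(3 * n), ncol = 3), k = k, mu = mu)
  })
}

test_that("gaussian density matches closed forms and the direct formula", {
  d <- 4L
  expect_equal(gaussianDensity(rep(0, d), rep(0, d), 1), (2 * pi)^(-d / 2))
  # 1D: value at one sd from the mean equals dnorm scaled by 1/sigma
  expect_equal(gaussianDensity(3, 1, 4), stats::dnorm(3, 1, 2))
  # random inputs vs direct matrix formula
  localSeed(2)
  for (rep in 1:10) {
    B <- sample(2:5, 1)
    mu <- stats::rnorm(B)
    f <- stats::rnorm(B)
    sig <- stats::runif(B, 0.5, 2)        # diagonal
    direct <- prod(stats::dnorm(f, mu, sqrt(sig)))
    expect_equal(gaussianDensity(f, mu, sig), direct, tolerance = 1e-12)
    # full covariance
    A <- matrix(stats::rnorm(B * B), B)
    S <- crossprod(A) + diag(B)
    directFull <- exp(-0.5 * (B * log(2 * pi) + determinant(S)$modulus[1] +
                                t(f - mu) %*% solve(S) %*% (f - mu)))
    expect_equal(gaussianDensity(f, mu, S), as.numeric(directFull),
                 tolerance = 1e-10)
  }
  expect_error(gaussianDensity(c(0, 0), c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "singular")
})

test_that("posteriors are normalized, symmetric and stabilized", {
  d <- threeBlobs(1)
  m1 <- fitGMM(d$X, 1L, seed = 1)
  expect_equal(unname(gmmPosterior(m1, d$X[1, ])[1, ]), 1)
  # mirror-symmetric two-component model: midpoint point splits 50/50
  m2 <- new("ProjectionGMM", sourceRegion = "s", vocab = c("a", "b"),
            weights = c(0.5, 0.5), means = rbind(c(-2, 0), c(2, 0)),
            variances = list(1, 1), covType = "spherical",
            masks = matrix(TRUE, 2, 2), logLik = 0, bic = 0, n = 2L,
            nIter = 0L, seed = 1L, llTrace = numeric(0),
            bicTrace = data.frame(C = integer(0), bic = numeric(0)))
  expect_equal(unname(gmmPosterior(m2, c(0, 5))[1, ]), c(0.5, 0.5))
  # rows sum to 1 even at extreme scales (log-sum-exp stabilization)
  mBig <- m2; mBig@means <- rbind(c(-2000, 0), c(2000, 0))
  post <- gmmPosterior(mBig, rbind(c(-1999, 3), c(1999, -3)))
  expect_equal(rowSums(post), c(1, 1), tolerance = 1e-9)
  # against a naive unstabilized evaluation at moderate scales
  naive <- function(model, f) {
    dens <- vapply(seq_along(model@weights), function(k)
      model@weights[k] * gaussianDensity(f, model@means[k, ],
                                         model@variances[[k]]), 0)
    dens / sum(dens)
  }
  localSeed(3)
  for (rep in 1:10) {
    f <- stats::rnorm(2, sd = 3)
    expect_equal(unname(gmmPosterior(m2, f)[1, ]), unname(naive(m2, f)),
                 tolerance = 1e-10)
  }
})

test_that("single-component EM recovers the closed-form MLE", {
  localSeed(7)
  X <- matrix(stats::rnorm(300, 5, 2), ncol = 3)
  m <- fitGMM(X, 1L, seed = 2)
  expect_equal(unname(clusterMeans(m)[1, ]), colMeans(X), tolerance = 1e-9)
  # spherical MLE: mean over dimensions of the biased per-dim variance
  biased <- mean(apply(X, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(m@variances[[1]], biased, tolerance = 1e-9)
  expect_equal(clusterWeights(m), 1)
})

test_that("EM log-likelihood is monotone and weights stay normalized", {
  for (s in 1:6) {
    d <- threeBlobs(10 + s, n = 80)
    m <- fitGMM(d$X, sample(2:5, 1), seed = s)
    expect_true(all(diff(m@llTrace) >= -1e-8))
    expect_equal(sum(clusterWeights(m)), 1, tolerance = 1e-9)
    expect_true(all(unlist(m@variances) > 0))
  }
})

test_that("EM recovers parameters of well-separated mixtures", {
  hits <- 0L
  for (s in 1:5) {
    d <- threeBlobs(20 + s, n = 200)
    m <- fitGMM(d$X, 3L, seed = s)
    # match components to truth by nearest mean
    perm <- apply(clusterMeans(m), 1L, function(mn)
      which.min(colSums((t(d$mu) - mn)^2)))
    if (length(unique(perm)) != 3L) next
    nk <- table(factor(d$k, levels = 1:3))
    meanOK <- all(vapply(1:3, function(k) {
      err <- sqrt(sum((clusterMeans(m)[match(k, perm), ] - d$mu[k, ])^2))
      err <= 3 * sqrt(3) / sqrt(nk[k])
    }, TRUE))
    wOK <- all(abs(clusterWeights(m)[order(perm)] -
                     as.numeric(nk / 200)[sort(perm)]) < 0.1)
    if (meanOK && wOK) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("EM matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC       # Mclust resolves this in the caller
  d <- threeBlobs(33, n = 150)
  mine <- fitGMM(d$X, 3L, seed = 4)
  ref <- mclust::Mclust(d$X, G = 3, modelNames = "VII", verbose = FALSE)
  # same data, same model class: log-likelihoods agree closely
  expect_equal(mine@logLik, ref$loglik, tolerance = 1e-3)
  # and the hard partitions agree
  expect_gt(mclust::adjustedRandIndex(classifyAxons(mine, d$X),
                                      ref$classification), 0.97)
})

test_that("BIC counts free parameters correctly and penalizes duplicates", {
  # single-cluster BIC matches a hand computation
  localSeed(8)
  X <- matrix(stats::rnorm(120), ncol = 3)
  m1 <- fitGMM(X, 1L, seed = 1)
  sigma2 <- m1@variances[[1]]
  llHand <- sum(vapply(seq_len(nrow(X)), function(i)
    sum(stats::dnorm(X[i, ], clusterMeans(m1)[1, ], sqrt(sigma2), log = TRUE)),
    0))
  kappa <- 0 + 1 * 3 + 1                  # (C-1) + C*B + C, spherical
  expect_equal(gmmBIC(m1), kappa * log(nrow(X)) - 2 * llHand, tolerance = 1e-6)
  # duplicating a component (same mean/variance, split weight) leaves the
  # likelihood unchanged but grows kappa: BIC can only get worse
  m2 <- new("ProjectionGMM", sourceRegion = "s", vocab = m1@vocab,
            weights = c(0.5, 0.5),
            means = rbind(clusterMeans(m1)[1, ], clusterMeans(m1)[1, ]),
            variances = list(sigma2, sigma2), covType = "spherical",
            masks = matrix(TRUE, 2, 3), logLik = 0, bic = 0,
            n = m1@n, nIter = 0L, seed = 1L, llTrace = numeric(0),
            bicTrace = data.frame(C = integer(0), bic = numeric(0)))
  expect_gt(gmmBIC(m2, X), gmmBIC(m1, X))
})

test_that("model selection honors imposed C, degenerate sizes and the range", {
  atlas <- demoToyAtlas()
  pop <- generatePopulation(demoPopulationSpec(59), atlas, seed = 5)
  se <- stackPopulation(lapply(pop$morphologies, computeProjectionFeatures,
                               atlas = atlas, level = 2))
  X <- t(SummarizedExperiment::assay(se, "lengths"))
  m5 <- selectGMM(X, imposedC = 5, seed = 2, sourceRegion = "PRE")
  expect_identical(nClusters(m5), 5L)
  # N = 1: degenerate single-component model at the variance floor
  m1 <- selectGMM(X[1, , drop = FALSE], seed = 1)
  expect_identical(nClusters(m1), 1L)
  expect_lte(m1@variances[[1]], 1e-11)
  expect_error(selectGMM(X[0, , drop = FALSE]), "empty|rows")
  # default range: ceil(n/2)..n
  m <- selectGMM(matrix(stats::rnorm(15), ncol = 3), seed = 3)
  expect_true(all(m@bicTrace$C == 3:5))
  expect_error(fitGMM(matrix(0, 2, 2), 3L), "exceeds")
})

test_that("BIC selection recovers the true cluster count on blobs", {
  hits <- 0L
  for (s in 1:5) {
    d <- threeBlobs(40 + s, n = 150)
    m <- selectGMM(d$X, cRange = 1:5, seed = s)
    if (nClusters(m) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("virtual axon sampling respects weights, clipping and masks", {
  d <- threeBlobs(50, n = 150)
  m <- fitGMM(d$X, 3L, seed = 6)
  s <- sampleVirtualAxons(m, 10000L, seed = 9)
  freq <- table(factor(attr(s, "cluster"), levels = 1:3)) / 10000
  bound <- 3 * sqrt(clusterWeights(m) * (1 - clusterWeights(m)) / 10000)
  expect_true(all(abs(freq - clusterWeights(m)) <= bound))
  expect_true(all(s >= 0))                # negatives clipped
  # masked regions always zero
  mMasked <- m
  mMasked@masks[, 2] <- FALSE
  s2 <- sampleVirtualAxons(mMasked, 500L, seed = 9)
  expect_true(all(s2[, 2] == 0))
  # identical seed, identical draw
  expect_identical(sampleVirtualAxons(m, 20L, seed = 4),
                   sampleVirtualAxons(m, 20L, seed = 4))
})

test_that("virtual axons reproduce each cluster's main projection regions", {
  atlas <- demoToyAtlas()
  pop <- generatePopulation(demoPopulationSpec(59), atlas, seed = 6)
  se <- stackPopulation(lapply(pop$morphologies, computeProjectionFeatures,
                               atlas = atlas, level = 2))
  X <- t(SummarizedExperiment::assay(se, "lengths"))
  m <- selectGMM(X, imposedC = 5, seed = 3, sourceRegion = "PRE")
  cl <- classifyAxons(m, X)
  virtual <- sampleVirtualAxons(m, 59L, seed = 7)
  vk <- attr(virtual, "cluster")
  for (c in 1:5) {
    if (sum(vk == c) < 2L || sum(cl == c) < 2L) next
    topTrain <- names(sort(colMeans(X[cl == c, , drop = FALSE]),
                           decreasing = TRUE))[1:3]
    topVirtual <- names(sort(colMeans(virtual[vk == c, , drop = FALSE]),
                             decreasing = TRUE))[1:3]
    expect_gte(length(intersect(topTrain, topVirtual)), 2L)
  }
})

test_that("models round-trip through JSON", {
  d <- threeBlobs(60, n = 90)
  m <- fitGMM(d$X, 3L, seed = 2, sourceRegion = "SRC")
  path <- withr::local_tempfile(fileext = ".json")
  writeGMM(m, path)
  back <- readGMM(path)
  expect_equal(clusterWeights(back), clusterWeights(m), tolerance = 1e-12)
  expect_equal(unname(clusterMeans(back)), unname(clusterMeans(m)),
               tolerance = 1e-12)
  expect_equal(back@variances, m@variances, tolerance = 1e-12)
  expect_identical(back@masks, m@masks)
  expect_identical(back@sourceRegion, "SRC")
})
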