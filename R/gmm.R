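# Gaussian mixture clustering of projection features: hand-written EM with
# BIC model selection and virtual-axon sampling. The EM here is the package's
# own implementation (log-space E-step, weighted MLE M-step, k-means++-style
# seeding, variance floor); external mixture packages are used only as
# independent cross-checks in the tests.

#' Multivariate normal density with spherical/diagonal/full covariance
#'
#' @param f feature vector (length B) or n x B matrix.
#' @param mu mean vector.
#' @param sigma scalar variance (spherical), length-B vector of variances
#'   (diagonal) or B x B covariance matrix (full).
#' @param log return the log density.
#' @return density value(s); computed in log space internally.
#' @export
gaussianDensity <- function(f, mu, sigma, log = FALSE) {
  f <- rbind(f)
  B <- length(mu)
  diff <- sweep(f, 2L, mu)
  if (is.matrix(sigma)) {
    ch <- tryCatch(chol(sigma), error = function(e)
      stop("singular covariance matrix"))
    logdet <- 2 * sum(base::log(diag(ch)))
    q <- colSums(backsolve(ch, t(diff), transpose = TRUE)^2)
  } else if (length(sigma) == 1L) {
    if (sigma <= 0) stop("variance must be positive")
    logdet <- B * base::log(sigma)
    q <- rowSums(diff^2) / sigma
  } else {
    if (any(sigma <= 0)) stop("variances must be positive")
    logdet <- sum(base::log(sigma))
    q <- rowSums(sweep(diff^2, 2L, sigma, "/"))
  }
  ll <- unname(-0.5 * (B * base::log(2 * pi) + logdet + q))
  if (log) ll else exp(ll)
}

# n x C matrix of per-component log densities.
componentLogDensities <- function(X, means, variances) {
  C <- nrow(means)
  out <- matrix(0, nrow(X), C)
  for (k in seq_len(C)) {
    out[, k] <- gaussianDensity(X, means[k, ], variances[[k]], log = TRUE)
  }
  out
}

#' Posterior cluster probabilities
#'
#' Bayes responsibilities P(c | a) of each feature vector under the mixture,
#' log-sum-exp stabilized; rows sum to 1.
#'
#' @param model a \linkS4class{ProjectionGMM}.
#' @param f feature vector or n x B matrix (columns in model vocabulary order).
#' @return n x C matrix of posterior probabilities.
#' @export
gmmPosterior <- function(model, f) {
  X <- rbind(f)
  lp <- sweep(componentLogDensities(X, model@means, model@variances), 2L,
              base::log(model@weights), "+")
  exp(lp - logSumExpRows(lp))
}

# Observed-data log-likelihood of X under (weights, means, variances).
mixtureLogLik <- function(X, weights, means, variances) {
  lp <- sweep(componentLogDensities(X, means, variances), 2L,
              base::log(weights), "+")
  sum(logSumExpRows(lp))
}

# k-means++-style seeding (distance-weighted choice of C data rows)
# refined by a few Lloyd iterations, so EM restarts start from balanced
# partitions rather than collapsing onto outlier points (a one-point
# component with floored variance diverges the likelihood and corrupts BIC
# selection).
seedMeans <- function(X, C, lloydIter = 10L) {
  n <- nrow(X)
  centers <- integer(C)
  centers[1L] <- sample.int(n, 1L)
  if (C > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
    for (k in 2L:C) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[k], ])^2))
    }
  }
  means <- X[centers, , drop = FALSE]
  for (it in seq_len(lloydIter)) {
    d2 <- vapply(seq_len(C), function(k) rowSums(sweep(X, 2L, means[k, ])^2),
                 numeric(n))
    assign <- max.col(-rbind(d2))
    newMeans <- means
    for (k in seq_len(C)) {
      rows <- which(assign == k)
      if (length(rows)) newMeans[k, ] <- colMeans(X[rows, , drop = FALSE])
      else {
        far <- which.max(apply(rbind(d2), 1L, min))
        newMeans[k, ] <- X[far, ]
      }
    }
    if (max(abs(newMeans - means)) < 1e-10) { means <- newMeans; break }
    means <- newMeans
  }
  means
}

#' Fit a Gaussian mixture to projection features by EM
#'
#' Standard EM: the E-step computes posteriors, the M-step the weighted
#' maximum-likelihood updates of weights, means and variances under the
#' covariance constraint (spherical: one scalar variance per component,
#' the default; diagonal optional). The observed-data log-likelihood is
#' non-decreasing across iterations (checked in tests); the best of
#' \code{nInit} seeded restarts is kept; variances are floored at 1 percent
#' of the mean per-dimension data variance -- small enough that duplicate
#' feature patterns still form near-degenerate components, large enough
#' that a component collapsed onto a single outlier cannot buy its BIC
#' parameter cost with a diverging likelihood. An empty component is
#' re-seeded from the data point with the lowest maximum posterior.
#'
#' @param X n x B feature matrix (rows = axons). Column names become the
#'   model vocabulary.
#' @param C number of mixture components (C <= n).
#' @param covType "spherical" (default) or "diagonal".
#' @param seed integer seed; restart r uses \code{deriveSeed(seed, "em", r)}.
#' @param nInit number of restarts.
#' @param tol convergence tolerance on the log-likelihood.
#' @param maxIter maximum EM iterations.
#' @param sourceRegion stored in the model.
#' @param varFloorFrac variance floor as a fraction of the mean
#'   per-dimension data variance.
#' @return a \linkS4class{ProjectionGMM}.
#' @export
fitGMM <- function(X, C, covType = c("spherical", "diagonal"), seed = 1L,
                   nInit = 10L, tol = 1e-6, maxIter = 500L,
                   sourceRegion = "unknown", varFloorFrac = 1e-2) {
  covType <- match.arg(covType)
  X <- as.matrix(X)
  n <- nrow(X); B <- ncol(X)
  if (C > n) stop("C = ", C, " exceeds the number of data rows (", n, ")")
  if (C < 1L) stop("C must be >= 1")
  totVar <- mean(apply(X, 2L, function(col) mean((col - mean(col))^2)))
  floorVar <- max(varFloorFrac * totVar, 1e-12)

  best <- NULL
  for (r in seq_len(nInit)) {
    fit <- withSeed(deriveSeed(seed, "em", r),
                    emOnce(X, C, covType, tol, maxIter, floorVar))
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }

  post <- bestPosterior(X, best)
  hard <- max.col(post)
  masks <- matrix(FALSE, C, B)
  for (k in seq_len(C)) {
    members <- which(hard == k)
    if (length(members)) masks[k, ] <- colSums(X[members, , drop = FALSE] > 0) > 0
  }
  vocab <- colnames(X)
  if (is.null(vocab)) vocab <- paste0("dim", seq_len(B))
  colnames(best$means) <- vocab
  model <- new("ProjectionGMM", sourceRegion = sourceRegion, vocab = vocab,
               weights = best$weights, means = best$means,
               variances = best$variances, covType = covType, masks = masks,
               logLik = best$logLik, bic = NA_real_, n = as.integer(n),
               nIter = as.integer(best$nIter), seed = as.integer(seed),
               llTrace = best$llTrace,
               bicTrace = data.frame(C = integer(0), bic = numeric(0)))
  model@bic <- gmmBIC(model)
  model
}

bestPosterior <- function(X, fit) {
  lp <- sweep(componentLogDensities(X, fit$means, fit$variances), 2L,
              base::log(fit$weights), "+")
  exp(lp - logSumExpRows(lp))
}

emOnce <- function(X, C, covType, tol, maxIter, floorVar) {
  n <- nrow(X); B <- ncol(X)
  means <- seedMeans(X, C)
  # initial hard assignment to nearest seed
  d2 <- vapply(seq_len(C), function(k) rowSums(sweep(X, 2L, means[k, ])^2),
               numeric(n))
  assign0 <- max.col(-rbind(d2))
  weights <- tabulate(assign0, C) / n
  weights[weights == 0] <- 1 / n
  weights <- weights / sum(weights)
  variances <- lapply(seq_len(C), function(k) {
    rows <- which(assign0 == k)
    v <- if (length(rows)) mean(rbind(d2)[rows, k]) / B else floorVar
    v <- max(v, floorVar)
    if (covType == "spherical") v else rep(v, B)
  })

  ll <- -Inf
  llTrace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    lp <- sweep(componentLogDensities(X, means, variances), 2L,
                base::log(weights), "+")
    rowLse <- logSumExpRows(lp)
    newLL <- sum(rowLse)
    resp <- exp(lp - rowLse)

    # empty-component rescue: re-seed from the worst-explained point
    Nk <- colSums(resp)
    empties <- which(Nk < 1e-8)
    if (length(empties)) {
      worst <- order(apply(resp, 1L, max))[seq_along(empties)]
      for (j in seq_along(empties)) {
        k <- empties[j]
        means[k, ] <- X[worst[j], ]
        variances[[k]] <- if (covType == "spherical") max(floorVar, 1) else
          rep(max(floorVar, 1), ncol(X))
        weights[k] <- 1 / n
      }
      weights <- weights / sum(weights)
      ll <- -Inf
      llTrace <- numeric(0)              # restart the trace after a re-seed
      next
    }

    llTrace <- c(llTrace, newLL)
    if (is.finite(ll) && newLL - ll < tol) { ll <- newLL; break }
    ll <- newLL

    # M-step: weighted MLE
    weights <- Nk / n
    means <- crossprod(resp, X) / Nk
    variances <- lapply(seq_len(C), function(k) {
      diff2 <- sweep(X, 2L, means[k, ])^2
      if (covType == "spherical") {
        max(sum(resp[, k] * rowSums(diff2)) / (B * Nk[k]), floorVar)
      } else {
        pmax(colSums(resp[, k] * diff2) / Nk[k], floorVar)
      }
    })
  }
  list(weights = weights, means = means, variances = variances,
       logLik = ll, nIter = length(llTrace), llTrace = llTrace)
}

#' BIC of a fitted mixture
#'
#' \code{BIC = kappa * ln(n) - 2 * logLik} with kappa the free-parameter
#' count given the covariance type (spherical: \code{(C-1) + C*B + C};
#' diagonal: \code{(C-1) + C*B + C*B}). Under this sign convention lower is
#' better and model selection uses argmin; this is the same criterion as
#' "maximize the BIC score" under the opposite sign convention.
#'
#' @param model a \linkS4class{ProjectionGMM}.
#' @param X optional data matrix to re-evaluate the log-likelihood on;
#'   default uses the stored fit log-likelihood.
#' @return the BIC value.
#' @export
gmmBIC <- function(model, X = NULL) {
  C <- length(model@weights)
  B <- length(model@vocab)
  kappa <- switch(model@covType,
                  spherical = (C - 1L) + C * B + C,
                  diagonal = (C - 1L) + C * B + C * B)
  ll <- if (is.null(X)) model@logLik else
    mixtureLogLik(as.matrix(X), model@weights, model@means, model@variances)
  n <- if (is.null(X)) model@n else nrow(X)
  kappa * base::log(n) - 2 * ll
}

#' Select the cluster count by BIC
#'
#' Fits a mixture for each candidate C and returns the best-BIC model with
#' the full BIC trace. The default range is \code{ceil(n/2) .. n} (the
#' operating default for projection clustering); an imposed C overrides the
#' range, and an explicit \code{cRange} widens or narrows it. Degenerate
#' populations collapse the range (n = 1 -> C = 1).
#'
#' @param X n x B feature matrix.
#' @param cRange candidate cluster counts (default \code{ceiling(n/2):n}).
#' @param imposedC fixed cluster count, overrides \code{cRange}.
#' @param covType,seed,nInit,tol,maxIter,sourceRegion passed to [fitGMM()].
#' @return a \linkS4class{ProjectionGMM} with a populated \code{bicTrace}.
#' @export
selectGMM <- function(X, cRange = NULL, imposedC = NULL,
                      covType = "spherical", seed = 1L, nInit = 10L,
                      tol = 1e-6, maxIter = 500L, sourceRegion = "unknown") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stop("empty population: no axons to cluster")
  if (!is.null(imposedC)) {
    cRange <- imposedC
  } else if (is.null(cRange)) {
    cRange <- ceiling(n / 2):n
  }
  cRange <- sort(unique(pmin(pmax(as.integer(cRange), 1L), n)))
  fits <- lapply(cRange, function(C)
    fitGMM(X, C, covType = covType, seed = deriveSeed(seed, "C", C),
           nInit = nInit, tol = tol, maxIter = maxIter,
           sourceRegion = sourceRegion))
  bics <- vapply(fits, function(f) f@bic, 0)
  best <- fits[[which.min(bics)]]
  best@bicTrace <- data.frame(C = cRange, bic = bics)
  best
}

#' Sample virtual axons from a fitted mixture
#'
#' For each sample a cluster is chosen with probability \code{p_c} and a
#' feature vector drawn from its Gaussian; negatives are clipped to 0 and
#' entries in regions unobserved in that cluster's training members are
#' zeroed (the post-processing step that removes values sampled in regions
#' not seen in the biological input).
#'
#' @param model a \linkS4class{ProjectionGMM}.
#' @param n number of virtual axons.
#' @param seed integer seed.
#' @return n x B matrix of sampled feature vectors (columns = vocabulary),
#'   with the sampled cluster in attribute \code{"cluster"}.
#' @export
sampleVirtualAxons <- function(model, n, seed = NULL) {
  C <- length(model@weights)
  B <- length(model@vocab)
  withSeed(seed, {
    ks <- sample.int(C, n, replace = TRUE, prob = model@weights)
    out <- matrix(0, n, B, dimnames = list(NULL, model@vocab))
    for (i in seq_len(n)) {
      k <- ks[i]
      v <- model@variances[[k]]
      sd <- if (length(v) == 1L) rep(sqrt(v), B) else sqrt(v)
      x <- model@means[k, ] + stats::rnorm(B) * sd
      x[x < 0] <- 0
      x[!model@masks[k, ]] <- 0
      out[i, ] <- x
    }
    attr(out, "cluster") <- ks
    out
  })
}

#' Hard cluster assignment of the training data or new feature vectors
#'
#' @param model a \linkS4class{ProjectionGMM}.
#' @param X n x B matrix of feature vectors.
#' @return integer vector of argmax-posterior cluster indices.
#' @export
classifyAxons <- function(model, X) {
  max.col(gmmPosterior(model, X))
}

# ---- model serialization ----------------------------------------------

#' Write / read a ProjectionGMM as JSON
#' @param model a \linkS4class{ProjectionGMM}.
#' @param path JSON file path.
#' @export
writeGMM <- function(model, path) {
  obj <- list(source_region = model@sourceRegion, vocab = model@vocab,
              weights = model@weights, means = model@means,
              variances = model@variances, cov_type = model@covType,
              masks = model@masks, log_lik = model@logLik, bic = model@bic,
              n = model@n, n_iter = model@nIter, seed = model@seed,
              bic_trace = model@bicTrace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeGMM
#' @export
readGMM <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- length(o$weights)
  means <- matrix(unlist(o$means), nrow = C, byrow = FALSE)
  if (!identical(dim(o$means), NULL)) means <- o$means
  colnames(means) <- o$vocab
  variances <- if (is.list(o$variances)) lapply(o$variances, as.numeric) else
    as.list(as.numeric(o$variances))
  masks <- matrix(as.logical(o$masks), nrow = C)
  new("ProjectionGMM", sourceRegion = o$source_region, vocab = o$vocab,
      weights = as.numeric(o$weights), means = means, variances = variances,
      covType = o$cov_type, masks = masks, logLik = o$log_lik, bic = o$bic,
      n = as.integer(o$n), nIter = as.integer(o$n_iter),
      seed = as.integer(o$seed), llTrace = numeric(0),
      bicTrace = if (is.data.frame(o$bic_trace)) o$bic_trace else
        data.frame(C = integer(0), bic = numeric(0)))
}
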