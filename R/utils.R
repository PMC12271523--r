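# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' A single master seed deterministically spawns per-stage and per-neuron
#' substreams, so execution order cannot change results. The derivation is a
#' 32-bit FNV-1a style hash of the master seed and the stream labels, reduced
#' below 2^31 so it is always a valid \code{set.seed()} argument.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return a single integer in \code{[1, 2^31 - 2]}.
#' @export
deriveSeed <- function(seed, ...) {
  labels <- paste(c(format(as.integer(seed)), vapply(list(...), as.character, "")),
                  collapse = "/")
  h <- 2166136261
  for (code in utf8ToInt(labels)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(code))
    # 32-bit multiply by the FNV prime without overflow: split into halves
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L + 1L)
}

# Evaluate expr with a locally-set RNG state; restores the caller's state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise log-sum-exp of a matrix.
logSumExpRows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

vecNorm <- function(v) sqrt(sum(v * v))

unitVector <- function(v) {
  n <- vecNorm(v)
  if (n < .Machine$double.eps) c(1, 0, 0) else v / n
}

# Uniformly random unit vector.
randomUnitVector <- function() {
  v <- stats::rnorm(3L)
  unitVector(v)
}
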