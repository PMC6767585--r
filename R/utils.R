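#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib weedmapr, .registration = TRUE
NULL

# Derive a child seed from a master seed and a named stream, so that every
# stochastic stage of the pipeline draws from its own reproducible stream.
# Keeps results below 2^31 - 1 so the value is a valid R integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 9349) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian-kernel smoothing of a matrix by separable convolution with
# per-cell renormalisation (so edges are not darkened). sigma in cells;
# sigma = 0 returns the input untouched.
smooth_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  smooth_1d <- function(m, kern) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (d in seq(-r, r)) {
      w <- kern[d + r + 1L]
      src <- pmin(pmax(seq_len(n) + d, 1L), n)
      out <- out + w * m[src, , drop = FALSE]
    }
    out / sum(kern)
  }
  t(smooth_1d(t(smooth_1d(x, k)), k))
}

# Nearest-neighbour resize of a matrix to side x side pixels; preserves the
# original value set (no interpolation), as appropriate for index rasters.
resize_nn <- function(m, side) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == side && nc == side) return(m)
  ri <- pmin(nr, floor((seq_len(side) - 0.5) * nr / side) + 1L)
  ci <- pmin(nc, floor((seq_len(side) - 0.5) * nc / side) + 1L)
  m[ri, ci, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
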