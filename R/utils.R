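#' @useDynLib dynFNC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# correlation clipped away from +/-1 so atanh stays finite
.CLIP <- 1 - 1e-12

#' Fisher z transform with clipping
#'
#' Applies \code{atanh} to correlations after clipping them to
#' +/-(1 - 1e-12), so perfectly correlated pairs map to a large finite
#' z (about 13.8) instead of infinity.
#'
#' @param r numeric vector or matrix of correlations.
#' @return transformed values, same shape as \code{r}.
#' @export
fisherZ <- function(r) {
  atanh(pmin(pmax(r, -.CLIP), .CLIP))
}

# upper-triangle (i < j) vectorization, column-major order shared by all modules
.vecUT <- function(m) m[upper.tri(m)]

.unvecUT <- function(v, C, diag = 0) {
  m <- matrix(diag, C, C)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

.pairNames <- function(labels) {
  C <- length(labels)
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  paste0(labels[idx[, 1]], "-", labels[idx[, 2]])
}

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Vectorised two-sample Welch t-tests, one per column of A (nA x P) vs B
# (nB x P).  Used inside the 10,000-resample bootstrap where calling
# stats::t.test per pair would dominate runtime; agreement with t.test is
# asserted in the test suite.
.colWelchT <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- .colVars(A, mA); vB <- .colVars(B, mB)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# Vectorised paired t-tests on the rows-matched difference matrix D (n x P).
.colPairedT <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- .colVars(D, m)
  t <- m / sqrt(v / n)
  df <- rep(n - 1, length(m))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

.colVars <- function(X, mu = colMeans(X)) {
  colSums((X - rep(mu, each = nrow(X)))^2) / (nrow(X) - 1)
}

.colMedians <- function(X) apply(X, 2, stats::median)

.isSquareNumeric <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.noticef <- function(...) message(sprintf(...))
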