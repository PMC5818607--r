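# Small graphs and cohorts built in code for the tests.

# Complete graph on n nodes with unit weights.
completeSC <- function(n, subjectID = "complete") {
  w <- matrix(1, n, n)
  diag(w) <- 0
  StructuralConnectome(w, subjectID = subjectID)
}

# Random connected weighted graph: Erdos-Renyi pattern + lognormal weights,
# redrawn until connected.
randomSC <- function(n, density = 0.4, seed = 1L, subjectID = "random") {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    w[ut] <- rbinom(sum(ut), 1L, density) * rlnorm(sum(ut), 0, 0.5)
    w <- w + t(w)
    if (all(rowSums(w) > 0) && isConnectedGraphForTest(w)) break
  }
  StructuralConnectome(w, subjectID = subjectID)
}

upperOffDiagForTest <- function(x) x[upper.tri(x)]

isConnectedGraphForTest <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Dense matrix-exponential oracle, independent of the package's spectral
# evaluation (series if Matrix is unavailable).
expmOracle <- function(A) {
  if (requireNamespace("Matrix", quietly = TRUE))
    return(as.matrix(Matrix::expm(Matrix::Matrix(A))))
  n <- nrow(A)
  out <- diag(n)
  term <- diag(n)
  for (k in 1:60) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# Proximal-gradient (ISTA) brute-force reference for the LASSO objective
# ||Xb - y||^2 + lambda ||b||_1; best-iterate tracking.
lassoBruteForce <- function(X, y, lambda, iters = 50000L) {
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values)
  step <- 1 / L
  b <- numeric(ncol(X))
  obj <- function(b) sum((X %*% b - y)^2) + lambda * sum(abs(b))
  best <- b; bestObj <- obj(b)
  for (t in seq_len(iters)) {
    g <- 2 * crossprod(X, X %*% b - y)
    z <- b - step * g
    b <- sign(z) * pmax(abs(z) - step * lambda, 0)
    o <- obj(b)
    if (o < bestObj) { bestObj <- o; best <- b }
  }
  list(coef = best, objective = bestObj)
}

lassoObjective <- function(X, y, b, lambda) {
  sum((X %*% b - y)^2) + lambda * sum(abs(b))
}

# KKT residuals of a LASSO solution: at optimum, 2 X'(y - Xb) equals
# lambda * sign(b_k) on the active set and is bounded by lambda elsewhere.
lassoKKTViolation <- function(X, y, b, lambda) {
  g <- as.numeric(2 * crossprod(X, y - X %*% b))
  active <- b != 0
  vA <- if (any(active)) max(abs(g[active] - lambda * sign(b[active]))) else 0
  vI <- if (any(!active)) max(pmax(abs(g[!active]) - lambda, 0)) else 0
  max(vA, vI)
}

# Small standard cohort used across tests (cached per session).
testCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(SyntheticCohortSpec(n = 12L, p = 8L, m = 3L,
                                                   seed = 42L))
    cache
  }
})
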