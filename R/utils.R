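## Internal helpers.

symmetrizeMatrix <- function(x) (x + t(x)) / 2

# Off-diagonal upper-triangle entries, the domain of every FC comparison.
upperOffDiag <- function(x) x[upper.tri(x)]

#' Derive a named RNG substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (fold splits, perturbation draws, simulator noise, cohort
#' synthesis), so that changing one stream's consumption cannot shift
#' another. The derivation is a deterministic polynomial hash of the stream
#' name mixed with the master seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return A single integer seed in \[0, 2^31 - 2\].
#' @examples
#' subSeed(1, "cv-folds")
#' @export
subSeed <- function(seed, stream) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (c in utf8ToInt(stream)) h <- (h * 31 + c) %% mod
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Is the graph with adjacency w connected? BFS on the nonzero pattern.
isConnectedGraph <- function(w) {
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
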