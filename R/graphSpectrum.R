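#' Build and decompose the graph Laplacian of a structural connectome
#'
#' Computes either the symmetric normalized Laplacian
#' L = I - D^{-1/2} W D^{-1/2} (default) or the combinatorial Laplacian
#' L = D - W of the structural graph, and returns its full
#' eigendecomposition. Eigenvalues are ascending and clamped to be
#' nonnegative (tiny negative round-off below 1e-8 is zeroed); the sign of
#' each eigenvector is fixed so its largest-magnitude entry is positive,
#' making the decomposition reproducible. Downstream kernels are invariant to
#' this convention.
#'
#' For a connected graph the smallest eigenvalue is 0 with null eigenvector
#' proportional to D^{1/2} 1 (normalized case) or 1 (unnormalized case).
#'
#' @param sc a [StructuralConnectome-class].
#' @param normalization `"symmetric_normalized"` (default) or
#'   `"unnormalized"`.
#' @return A [SpectralDecomposition-class].
#' @examples
#' sc <- StructuralConnectome(matrix(c(0, 1, 1, 0), 2, 2))
#' spec <- buildLaplacian(sc)
#' eigenvalues(spec)  # 0 and 2 for a single unit edge
#' @export
buildLaplacian <- function(sc,
                           normalization = c("symmetric_normalized",
                                             "unnormalized")) {
  stopifnot(is(sc, "StructuralConnectome"))
  normalization <- match.arg(normalization)
  w <- sc@weights
  n <- nrow(w)
  deg <- rowSums(w)
  if (any(deg == 0))
    stop("degenerate graph: isolated node(s) ",
         paste(which(deg == 0), collapse = ", "))
  L <- if (normalization == "symmetric_normalized") {
    dis <- 1 / sqrt(deg)
    diag(n) - dis * t(dis * w)  # I - D^{-1/2} W D^{-1/2}
  } else {
    diag(deg) - w
  }
  L <- symmetrizeMatrix(L)
  e <- eigen(L, symmetric = TRUE)
  ord <- seq(n, 1L)  # eigen() returns descending; flip to ascending
  lam <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  if (min(lam) < -1e-8)
    stop("Laplacian has an eigenvalue below -1e-8; input is not a valid ",
         "nonnegative graph")
  lam[lam < 0] <- 0
  for (k in seq_len(n)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  new("SpectralDecomposition", laplacian = L, eigenvectors = V,
      eigenvalues = lam, normalization = normalization)
}

#' Diffusion kernel at one scale
#'
#' The heat kernel H(gamma) = Psi exp(-Lambda gamma) Psi' of the graph
#' Laplacian, evaluated spectrally (exact for symmetric L). H(0) is the
#' identity; H(gamma1) H(gamma2) = H(gamma1 + gamma2); as gamma grows the
#' kernel contracts onto the projector of the Laplacian null space.
#'
#' @param spec a [SpectralDecomposition-class].
#' @param gamma nonnegative diffusion scale.
#' @return Symmetric positive semi-definite n x n matrix.
#' @examples
#' sc <- StructuralConnectome(matrix(c(0, 1, 1, 0), 2, 2))
#' spec <- buildLaplacian(sc)
#' diffusionKernel(spec, 0)    # identity
#' diffusionKernel(spec, 0.5)
#' @export
diffusionKernel <- function(spec, gamma) {
  stopifnot(is(spec, "SpectralDecomposition"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0)
    stop("gamma must be a single nonnegative number")
  V <- spec@eigenvectors
  H <- V %*% (exp(-spec@eigenvalues * gamma) * t(V))
  symmetrizeMatrix(H)
}

#' Build the multi-scale kernel bank of one subject
#'
#' Evaluates the diffusion kernel at each scale of `scaleSet` and assembles
#' the horizontally stacked form `H = cbind(H_1, ..., H_m)` (n x mn) used as
#' the subject's design block in the multiple-kernel model.
#'
#' @param spec a [SpectralDecomposition-class].
#' @param scaleSet a [ScaleSet-class].
#' @param subjectID identifier carried on the bank.
#' @return A [DiffusionKernelBank-class].
#' @export
buildKernelBank <- function(spec, scaleSet, subjectID = "subject") {
  stopifnot(is(spec, "SpectralDecomposition"), is(scaleSet, "ScaleSet"))
  kernels <- lapply(scaleSet@scales, function(g) diffusionKernel(spec, g))
  stacked <- do.call(cbind, kernels)
  new("DiffusionKernelBank", kernels = kernels, stacked = stacked,
      scaleSet = scaleSet, subjectID = as.character(subjectID))
}

#' Data-driven default diffusion scale set
#'
#' Places `m` log-spaced scales between two data-driven endpoints:
#' `gamma_min` where the kernel first deviates from the identity by Frobenius
#' norm 0.01 n, and `gamma_max` where it last deviates from the rank-1
#' stationary projector (outer product of the null eigenvector) by at most
#' 0.01 n. Both deviations have closed forms in the Laplacian eigenvalues
#' (`||H - I||_F^2 = sum (1 - e^{-lambda gamma})^2`,
#' `||H - P0||_F^2 = sum_{k >= 2} e^{-2 lambda_k gamma}`), so the endpoints
#' are solved by bisection on those scalar functions and are deterministic
#' for a fixed decomposition. The endpoints do not depend on `m`, so
#' doubling `m` nests the previous scale set's extremes.
#'
#' @param spec a [SpectralDecomposition-class] of a connected graph.
#' @param m number of scales (default 16).
#' @return A [ScaleSet-class] of `m` strictly increasing scales.
#' @export
defaultScaleSet <- function(spec, m = 16L) {
  stopifnot(is(spec, "SpectralDecomposition"))
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  lam <- spec@eigenvalues
  n <- length(lam)
  if (n < 2L || lam[2L] <= 1e-8)
    stop("degenerate graph: disconnected (stationary projector undefined)")
  thr <- 0.01 * n
  devFromIdentity <- function(g) sqrt(sum((1 - exp(-lam * g))^2))
  devFromProjector <- function(g) sqrt(sum(exp(-2 * lam[-1L] * g)))
  if (devFromIdentity(1e-12) >= thr || devFromProjector(1e12) > thr)
    stop("cannot bracket scale endpoints for this graph")
  maxIdentityDev <- sqrt(n - 1)  # limit of devFromIdentity as gamma -> Inf
  if (thr >= maxIdentityDev)
    stop("deviation threshold unreachable: graph too small")
  gMin <- uniroot(function(g) devFromIdentity(g) - thr,
                  lower = 1e-12, upper = 1e12, tol = 1e-12)$root
  gMax <- uniroot(function(g) devFromProjector(g) - thr,
                  lower = 1e-12, upper = 1e12, tol = 1e-12)$root
  if (gMax <= gMin) stop("degenerate scale range: gamma_max <= gamma_min")
  scales <- if (m == 1L) gMin else exp(seq(log(gMin), log(gMax),
                                           length.out = m))
  ScaleSet(scales)
}

#' Evolve a graph signal under reaction-diffusion dynamics
#'
#' Propagates an initial activity vector u0 for time `t` under the linear
#' graph dynamics whose per-mode decay rate is
#' (1 - e^{-lambda sigma^2 / 2}) / tau: the solution is
#' u(t) = Psi exp(-(I - e^{-Lambda sigma^2/2}) t / tau) Psi' u0. The null
#' mode never decays, so a signal proportional to the Laplacian null
#' eigenvector is a fixed point, and any signal converges to its projection
#' onto that eigenvector as t grows.
#'
#' @param spec a [SpectralDecomposition-class].
#' @param u0 numeric initial signal of length n.
#' @param t nonnegative evolution time (model units).
#' @param tau characteristic reaction time constant (> 0).
#' @param sigma2 spatial diffusion variance (> 0); the kernel scale per
#'   reaction interval is sigma2 / 2.
#' @return Numeric vector, the evolved signal u(t).
#' @export
evolveGraphSignal <- function(spec, u0, t, tau = 1, sigma2 = 1) {
  stopifnot(is(spec, "SpectralDecomposition"))
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be a single nonnegative number")
  if (tau <= 0 || sigma2 <= 0) stop("tau and sigma2 must be positive")
  n <- length(spec@eigenvalues)
  if (length(u0) != n) stop("u0 must have length ", n)
  V <- spec@eigenvectors
  decay <- exp(-(1 - exp(-spec@eigenvalues * sigma2 / 2)) * t / tau)
  as.numeric(V %*% (decay * crossprod(V, u0)))
}
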