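#' Generate a cohort of synthetic structural connectomes
#'
#' Draws one modular group-template graph (nodes assigned to
#' `moduleCount` communities round-robin; within-module edges present with
#' probability `intraDensity` and lognormal(`intraWeight`) weights,
#' between-module edges with probability `interDensity` and
#' lognormal(`interWeight`) weights), redrawn until connected (bounded
#' retries), then derives each subject by multiplying every template edge by
#' an independent lognormal jitter `exp(subjectJitter * N(0,1))`. With zero
#' jitter all subjects equal the template; jitter preserves the support, so
#' every subject stays connected.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return List of p [StructuralConnectome-class] objects; the template is
#'   attached as `attr(., "template")`.
#' @export
generateSCCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  n <- spec@n
  modules <- rep_len(seq_len(spec@moduleCount), n)
  template <- withSeed(subSeed(spec@seed, "sc-template"), {
    for (try in seq_len(100L)) {
      w <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          intra <- modules[i] == modules[j]
          pEdge <- if (intra) spec@intraDensity else spec@interDensity
          if (runif(1) < pEdge) {
            mw <- if (intra) spec@intraWeight else spec@interWeight
            w[i, j] <- w[j, i] <- rlnorm(1, mw[1L], mw[2L])
          }
        }
      }
      if (isConnectedGraph(w)) break
      w <- NULL
    }
    if (is.null(w)) stop("could not draw a connected template in 100 tries")
    w
  })
  scs <- withSeed(subSeed(spec@seed, "sc-jitter"), {
    lapply(seq_len(spec@p), function(s) {
      jit <- matrix(0, n, n)
      jit[upper.tri(jit)] <- exp(spec@subjectJitter * rnorm(n * (n - 1) / 2))
      jit <- jit + t(jit)
      StructuralConnectome(template * jit,
                           subjectID = sprintf("synth%02d", s))
    })
  })
  attr(scs, "template") <- template
  scs
}

#' Generate a sparse ground-truth co-activation stack
#'
#' Nonzero positions are independent Bernoulli(`piSparsity`) indicators;
#' nonzero values have magnitude uniform on \[0.5, 1.5\] with random sign
#' (symmetric about zero). Magnitudes are bounded away from zero — the usual
#' beta-min condition of sparse-recovery benchmarks — so that "the support"
#' is a well-defined target at any finite noise level; entries arbitrarily
#' close to zero would make support recovery ill-posed by construction.
#' Deterministic under the cohort specification seed (substream `"ground-truth-pi"`).
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param scaleSet the cohort [ScaleSet-class] (m scales).
#' @return A [CoactivationStack-class] with recorded sparsity.
#' @export
generateGroundTruthPi <- function(spec, scaleSet) {
  stopifnot(is(spec, "SyntheticCohortSpec"), is(scaleSet, "ScaleSet"))
  m <- length(scaleSet@scales)
  mn <- m * spec@n
  stacked <- withSeed(subSeed(spec@seed, "ground-truth-pi"), {
    mask <- matrix(rbinom(mn * spec@n, 1L, spec@piSparsity), mn, spec@n)
    signs <- matrix(sample(c(-1, 1), mn * spec@n, replace = TRUE), mn, spec@n)
    vals <- matrix(runif(mn * spec@n, 0.5, 1.5), mn, spec@n)
    signs * vals * mask
  })
  CoactivationStack(stacked, scaleSet, lambda = 0)
}

#' Generate functional connectomes from the forward model
#'
#' For each subject computes the symmetrized forward prediction
#' sym(sum_i H_i pi_i), adds symmetric Gaussian off-diagonal noise of sd
#' `fcNoiseSD`, then rescales the whole cohort by one shared scalar (the
#' maximum absolute off-diagonal entry across subjects) so entries lie in
#' \[-1, 1\], and sets the diagonal to 1. Because the rescaling scalar is
#' shared, the linear structure is preserved up to that scalar, which folds
#' into Pi during recovery. The rescaled pre-noise matrices and the scalar
#' are returned for oracle tests.
#'
#' @param banks list of [DiffusionKernelBank-class] (one per subject) sharing
#'   the stack's scale set.
#' @param stack ground-truth [CoactivationStack-class].
#' @param fcNoiseSD additive noise sd.
#' @param seed integer seed (substream `"fc-noise"`).
#' @return List with `fcs` (list of [FunctionalConnectome-class]),
#'   `preNoise` (list of matrices on the same scale, unit diagonal) and
#'   `scaleFactor` (the shared normalising scalar).
#' @export
generateFCCohort <- function(banks, stack, fcNoiseSD = 0.01, seed = 1L) {
  stopifnot(length(banks) >= 1L, is(stack, "CoactivationStack"))
  p <- length(banks)
  n <- ncol(stack@stacked)
  clean <- lapply(banks, function(b)
    symmetrizeMatrix(b@stacked %*% stack@stacked))
  noisy <- withSeed(subSeed(seed, "fc-noise"), {
    lapply(clean, function(C) {
      if (fcNoiseSD > 0) {
        E <- matrix(0, n, n)
        E[upper.tri(E)] <- rnorm(n * (n - 1) / 2, sd = fcNoiseSD)
        C + E + t(E)
      } else C
    })
  })
  scaleFactor <- max(vapply(noisy, function(C) max(abs(upperOffDiag(C))),
                            numeric(1)))
  if (scaleFactor == 0) stop("forward model produced an all-zero cohort")
  fcs <- vector("list", p)
  preNoise <- vector("list", p)
  for (s in seq_len(p)) {
    Cn <- noisy[[s]] / scaleFactor
    diag(Cn) <- 1
    fcs[[s]] <- FunctionalConnectome(Cn, subjectID = banks[[s]]@subjectID)
    Cp <- clean[[s]] / scaleFactor
    diag(Cp) <- 1
    preNoise[[s]] <- Cp
  }
  list(fcs = fcs, preNoise = preNoise, scaleFactor = scaleFactor)
}

#' Generate a complete synthetic SC-FC cohort with known ground truth
#'
#' End-to-end generator: structural cohort, shared default scale set (from
#' the first subject's Laplacian, m scales), kernel banks, sparse
#' ground-truth co-activation stack, and forward-model FC with noise. The
#' returned cohort is ready for [fitMKL()] / [crossValidate()].
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param scaleSet optional [ScaleSet-class] overriding the default.
#' @param normalization Laplacian normalization.
#' @return List with `cohort` ([SCFCCohort-class]), `truePi`
#'   ([CoactivationStack-class]), `preNoise`, `scaleFactor` and `spec`.
#' @examples
#' \donttest{
#' gen <- generateCohort(SyntheticCohortSpec(n = 10L, p = 4L, m = 2L))
#' gen$cohort
#' }
#' @export
generateCohort <- function(spec = SyntheticCohortSpec(), scaleSet = NULL,
                           normalization = "symmetric_normalized") {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  scs <- generateSCCohort(spec)
  specs <- lapply(scs, buildLaplacian, normalization = normalization)
  if (is.null(scaleSet)) scaleSet <- defaultScaleSet(specs[[1L]], m = spec@m)
  banks <- mapply(function(sp, sc) buildKernelBank(sp, scaleSet,
                                                   subjectID = sc@subjectID),
                  specs, scs, SIMPLIFY = FALSE)
  truePi <- generateGroundTruthPi(spec, scaleSet)
  fcGen <- generateFCCohort(banks, truePi, fcNoiseSD = spec@fcNoiseSD,
                            seed = spec@seed)
  cohort <- new("SCFCCohort", scs = scs, specs = specs, banks = banks,
                fcs = fcGen$fcs, scaleSet = scaleSet,
                subjectIDs = vapply(scs, function(x) x@subjectID,
                                    character(1)))
  list(cohort = cohort, truePi = truePi, preNoise = fcGen$preNoise,
       scaleFactor = fcGen$scaleFactor, spec = spec)
}

#' Support recovery experiment on forward-model targets
#'
#' The estimator's recovery benchmark: draws a synthetic structural cohort
#' and a sparse ground-truth stack, builds targets exactly from the linear
#' forward model (`Y = X Pi* + noise`, entrywise Gaussian noise of sd
#' `spec@fcNoiseSD`, no rescaling or diagonal overwrite, so the generating
#' parameters are the population minimiser), selects the penalty by 3-fold
#' cross-validated prediction error over subjects on a half-decade
#' logarithmic grid, fits all columns at that penalty, and scores support
#' recovery at matched sparsity (fraction of true nonzeros among the top-k
#' fitted magnitudes, k = true support size).
#'
#' @param spec a [SyntheticCohortSpec-class] (its `p` subjects are all used
#'   for training; recovery is a parameter-estimation experiment, not a
#'   prediction experiment).
#' @param gridExponents exponents of the penalty grid, relative to the
#'   all-zero penalty `max|2 X'Y|`.
#' @return List with `recovery` (fraction in \[0, 1\]), `lambda`, `fitted`
#'   and `truth` ([CoactivationStack-class] objects).
#' @export
supportRecoveryExperiment <- function(spec,
                                      gridExponents = seq(-1, -5,
                                                          by = -0.5)) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  scs <- generateSCCohort(spec)
  specs <- lapply(scs, buildLaplacian)
  scaleSet <- defaultScaleSet(specs[[1L]], m = spec@m)
  banks <- lapply(specs, buildKernelBank, scaleSet = scaleSet)
  X <- do.call(rbind, lapply(banks, stackedKernels))
  truth <- generateGroundTruthPi(spec, scaleSet)
  P <- truth@stacked
  n <- ncol(P)
  Y <- X %*% P + withSeed(subSeed(spec@seed, "recovery-noise"),
                          matrix(rnorm(nrow(X) * n, sd = spec@fcNoiseSD),
                                 nrow(X), n))
  grid <- max(abs(2 * crossprod(X, Y))) * 10^gridExponents
  folds <- withSeed(subSeed(spec@seed, "recovery-cv"),
                    sample(rep(seq_len(3L), length.out = spec@p)))
  rowsOf <- function(subj)
    unlist(lapply(subj, function(s) (s - 1L) * n + seq_len(n)))
  cvm <- numeric(length(grid))
  for (f in seq_len(3L)) {
    tr <- rowsOf(which(folds != f)); te <- rowsOf(which(folds == f))
    XtX <- crossprod(X[tr, , drop = FALSE])
    XtY <- crossprod(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    B <- matrix(0, ncol(X), n)
    for (g in seq_along(grid)) {
      for (j in seq_len(n))
        B[, j] <- suppressWarnings(
          fitColumnGram(XtX, XtY[, j], grid[g], maxIter = 20000L,
                        init = B[, j]))
      cvm[g] <- cvm[g] +
        mean((X[te, , drop = FALSE] %*% B - Y[te, , drop = FALSE])^2)
    }
  }
  sel <- which.min(cvm)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  B <- matrix(0, ncol(X), n)
  for (g in seq_len(sel)) {  # warm-started path down to the selected penalty
    for (j in seq_len(n))
      B[, j] <- suppressWarnings(
        fitColumnGram(XtX, XtY[, j], grid[g], maxIter = 20000L,
                      init = B[, j]))
  }
  fitted <- CoactivationStack(B, scaleSet, lambda = grid[sel])
  list(recovery = supportRecovery(fitted, truth), lambda = grid[sel],
       fitted = fitted, truth = truth)
}

#' Support recovery against a ground-truth stack
#'
#' Fraction of the true nonzero co-activation entries recovered when the
#' fitted stack is thresholded to the same number of nonzeros (matched
#' sparsity: the top-|k| entries by magnitude, k = true support size).
#'
#' @param fitted fitted [CoactivationStack-class].
#' @param truth ground-truth [CoactivationStack-class].
#' @return Fraction in \[0, 1\].
#' @export
supportRecovery <- function(fitted, truth) {
  stopifnot(is(fitted, "CoactivationStack"), is(truth, "CoactivationStack"))
  trueIdx <- which(truth@stacked != 0)
  k <- length(trueIdx)
  if (k == 0L) stop("ground truth has empty support")
  fittedIdx <- order(abs(fitted@stacked), decreasing = TRUE)[seq_len(k)]
  length(intersect(trueIdx, fittedIdx)) / k
}
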