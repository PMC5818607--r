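#' Assemble the stacked cohort design matrices
#'
#' Stacks the subject kernel banks vertically into X (pn x mn) and the
#' empirical FC matrices into Y (pn x n), so that column j of the
#' co-activation stack solves the regression X Pi_j ~ Y_j where Y_j
#' concatenates the j-th FC column of every training subject.
#'
#' @param cohort an [SCFCCohort-class].
#' @return List with elements `X` (pn x mn) and `Y` (pn x n).
#' @export
assembleDesign <- function(cohort) {
  stopifnot(is(cohort, "SCFCCohort"))
  X <- do.call(rbind, lapply(cohort@banks, function(b) b@stacked))
  Y <- do.call(rbind, lapply(cohort@fcs, function(f) f@values))
  list(X = X, Y = Y)
}

#' Solve one co-activation column by LASSO
#'
#' Minimises `||X b - y||^2 + lambda ||b||_1` by cyclic coordinate descent on
#' the Gram form, with no intercept and no column standardization: the
#' kernels already share a common spectral footing, and standardizing would
#' distort the scale semantics of the co-activations. Convergence is declared
#' when the largest coordinate update in a sweep falls below `tol`; at
#' `maxIter` sweeps without convergence a warning with diagnostics is emitted
#' and the best iterate returned. `lambda = 0` gives the least-squares
#' solution; `lambda >= max|2 X'y|` shrinks every coefficient to zero.
#'
#' @param X design matrix (rows = stacked FC entries, columns = mn kernel
#'   coordinates).
#' @param y response vector.
#' @param lambda nonnegative L1 penalty.
#' @param tol convergence tolerance on the max coordinate update (default
#'   1e-6; the working tolerance is scaled conservatively so the reported
#'   KKT residuals meet 1e-5).
#' @param maxIter maximum coordinate-descent sweeps.
#' @param init optional warm-start coefficient vector.
#' @return Numeric coefficient vector of length `ncol(X)` with attributes
#'   `converged`, `iterations`.
#' @examples
#' X <- diag(4); y <- c(1, -2, 0.5, 0)
#' fitColumn(X, y, lambda = 0)  # equals y
#' @export
fitColumn <- function(X, y, lambda, tol = 1e-6, maxIter = 100000L,
                      init = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single nonnegative number")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  fitColumnGram(XtX, Xty, lambda, tol = tol, maxIter = maxIter, init = init)
}

# Gram-form worker shared by fitColumn and fitMKL (one Gram matrix for all n
# column problems). lambda = 0 is solved exactly as the minimum-norm least
# squares solution (spectral pseudo-inverse of the Gram matrix): the kernel
# design is highly collinear, and coordinate descent crawls along its flat
# directions when nothing is penalised.
fitColumnGram <- function(XtX, Xty, lambda, tol = 1e-6, maxIter = 100000L,
                          init = NULL) {
  p <- ncol(XtX)
  if (lambda == 0) {
    e <- eigen(XtX, symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * 1e-12
    inv <- ifelse(keep, 1 / e$values, 0)
    coef <- as.numeric(e$vectors %*% (inv * crossprod(e$vectors, Xty)))
    attr(coef, "converged") <- TRUE
    attr(coef, "iterations") <- 0L
    return(coef)
  }
  if (is.null(init)) init <- numeric(p)
  res <- lassoCoordinateDescent(XtX, Xty, lambda, tol, as.integer(maxIter),
                                as.numeric(init))
  if (!res$converged)
    warning("coordinate descent did not converge in ", maxIter,
            " sweeps (last max coordinate update ",
            format(res$maxDelta, digits = 3),
            "); returning the best iterate", call. = FALSE)
  coef <- as.numeric(res$coef)
  attr(coef, "converged") <- res$converged
  attr(coef, "iterations") <- res$iterations
  coef
}

#' Fit the multiple-kernel model on a training cohort
#'
#' Learns the co-activation stack Pi by solving the n independent column-wise
#' LASSO problems on the stacked cohort design. The total training objective
#' decomposes exactly into the sum of the column objectives, so columns can
#' be solved separately (and in any order) with identical results.
#'
#' `lambda = "auto"` selects the penalty on a logarithmic grid
#' (`lambda_max * 10^seq(0, -4)`, where `lambda_max` is the smallest penalty
#' that zeroes every column) by 3-fold cross-validated mean squared
#' prediction error over the training subjects; the folds are derived
#' deterministically from `seed` via the `"lasso-cv"` substream, and ties
#' prefer the larger (sparser) penalty. The selected value is recorded on the
#' returned object.
#'
#' @param cohort an [SCFCCohort-class] with p >= 1 subjects.
#' @param lambda nonnegative penalty, or `"auto"`.
#' @param seed integer seed for the inner cross-validation folds.
#' @param tol,maxIter coordinate-descent controls, see [fitColumn()].
#' @return A [CoactivationStack-class] with the fitted Pi, the penalty used
#'   and the achieved sparsity.
#' @export
fitMKL <- function(cohort, lambda = "auto", seed = 1L, tol = 1e-6,
                   maxIter = 100000L) {
  stopifnot(is(cohort, "SCFCCohort"))
  if (length(cohort) < 1L) stop("empty cohort")
  d <- assembleDesign(cohort)
  if (identical(lambda, "auto")) {
    lambda <- selectLambdaCV(cohort, seed = seed, tol = tol,
                             maxIter = maxIter)
  }
  if (!is.numeric(lambda) || lambda < 0)
    stop("lambda must be nonnegative or \"auto\"")
  XtX <- crossprod(d$X)
  XtY <- crossprod(d$X, d$Y)
  n <- ncol(d$Y)
  B <- matrix(0, nrow = ncol(d$X), ncol = n)
  for (j in seq_len(n)) {
    B[, j] <- fitColumnGram(XtX, XtY[, j], lambda, tol = tol,
                            maxIter = maxIter)
  }
  CoactivationStack(B, cohort@scaleSet, lambda = lambda)
}

# Inner 3-fold CV over training subjects for the "auto" penalty.
selectLambdaCV <- function(cohort, seed = 1L, nFolds = 3L,
                           gridExponents = seq(0, -4, length.out = 9),
                           tol = 1e-6, maxIter = 100000L) {
  p <- length(cohort)
  if (p < nFolds) nFolds <- max(2L, p)
  if (p < 2L) stop("lambda = \"auto\" needs at least 2 training subjects")
  d <- assembleDesign(cohort)
  lambdaMax <- max(abs(2 * crossprod(d$X, d$Y)))
  grid <- lambdaMax * 10^gridExponents
  folds <- withSeed(subSeed(seed, "lasso-cv"),
                    sample(rep(seq_len(nFolds), length.out = p)))
  n <- ncol(d$Y)
  rowsOf <- function(subjects) {
    unlist(lapply(subjects, function(s) (s - 1L) * n + seq_len(n)))
  }
  mse <- matrix(NA_real_, nrow = nFolds, ncol = length(grid))
  for (f in seq_len(nFolds)) {
    trainRows <- rowsOf(which(folds != f))
    testRows <- rowsOf(which(folds == f))
    Xtr <- d$X[trainRows, , drop = FALSE]
    Ytr <- d$Y[trainRows, , drop = FALSE]
    XtX <- crossprod(Xtr)
    XtY <- crossprod(Xtr, Ytr)
    Xte <- d$X[testRows, , drop = FALSE]
    Yte <- d$Y[testRows, , drop = FALSE]
    B <- matrix(0, nrow = ncol(Xtr), ncol = n)
    for (g in seq_along(grid)) {  # descending lambda: warm-start each column
      for (j in seq_len(n)) {
        B[, j] <- fitColumnGram(XtX, XtY[, j], grid[g], tol = tol,
                                maxIter = maxIter, init = B[, j])
      }
      mse[f, g] <- mean((Xte %*% B - Yte)^2)
    }
  }
  score <- colMeans(mse)
  # ties toward the larger penalty (grid is descending in lambda)
  grid[which.min(score)]
}

#' Predict functional connectivity from a kernel bank
#'
#' The forward model C_f = sum_i H_i pi_i, computed as the product of the
#' horizontally stacked kernels with the vertically stacked co-activations.
#' Since a general Pi makes C_f asymmetric while empirical FC is symmetric,
#' the prediction is symmetrised by default.
#'
#' @param bank a [DiffusionKernelBank-class].
#' @param stack a [CoactivationStack-class] sharing the bank's scale set.
#' @param symmetrize average with the transpose (default `TRUE`).
#' @return A [PredictedFC-class].
#' @export
predictFC <- function(bank, stack, symmetrize = TRUE) {
  stopifnot(is(bank, "DiffusionKernelBank"), is(stack, "CoactivationStack"))
  if (!isTRUE(all.equal(bank@scaleSet@scales, stack@scaleSet@scales)))
    stop("scale-set mismatch between kernel bank and co-activation stack")
  C <- bank@stacked %*% stack@stacked
  if (symmetrize) C <- symmetrizeMatrix(C)
  dimnames(C) <- NULL
  new("PredictedFC", values = C, symmetrized = isTRUE(symmetrize))
}

#' Model factory for cross-validation: multiple-kernel model
#'
#' Returns a factory suitable for [crossValidate()]: called on a training
#' cohort it fits the co-activation stack and returns a predictor closure
#' mapping one held-out subject to its predicted FC.
#'
#' @param lambda penalty passed to [fitMKL()] (default `"auto"`).
#' @param seed seed for the inner lambda selection.
#' @param ... further arguments to [fitMKL()].
#' @return A function `train -> (subject -> PredictedFC)`.
#' @export
mklModelFactory <- function(lambda = "auto", seed = 1L, ...) {
  function(train) {
    stack <- fitMKL(train, lambda = lambda, seed = seed, ...)
    function(subject) predictFC(subject$bank, stack)
  }
}
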