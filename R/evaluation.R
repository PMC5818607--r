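#' Pearson correlation between predicted and empirical FC
#'
#' The package's scalar score: Pearson correlation over the off-diagonal
#' upper-triangle entries of the two (symmetrized) matrices. The diagonal is
#' always excluded — empirical FC has a trivial unit diagonal.
#'
#' @param predicted a [PredictedFC-class], [FunctionalConnectome-class] or
#'   plain matrix (symmetrized before comparison).
#' @param empirical a [FunctionalConnectome-class] (or matrix).
#' @return Single correlation in \[-1, 1\].
#' @export
fcCorrelation <- function(predicted, empirical) {
  a <- if (is.matrix(predicted)) predicted else connMatrix(predicted)
  b <- if (is.matrix(empirical)) empirical else connMatrix(empirical)
  if (!identical(dim(a), dim(b)))
    stop("dimension mismatch between predicted and empirical FC")
  x <- upperOffDiag(symmetrizeMatrix(a))
  y <- upperOffDiag(symmetrizeMatrix(b))
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero-variance off-diagonal entries")
  cor(x, y)
}

#' Cross-validated evaluation of a predictive model
#'
#' Splits the cohort by subject, fits the model on each training split via
#' `modelFactory`, predicts every held-out subject and scores it with
#' [fcCorrelation()]. Splits are deterministic functions of `seed` (substream
#' `"cv-folds"`).
#'
#' Protocols: `"holdout_half"` trains on a random half of the subjects and
#' tests on the rest; `"loo"` is leave-one-out; `"kfold"` is k-fold (default
#' k = 5) with fold sizes differing by at most one.
#'
#' @param cohort an [SCFCCohort-class] with at least 2 subjects (at least k
#'   for k-fold).
#' @param modelFactory function taking a training [SCFCCohort-class] and
#'   returning a predictor `subject -> PredictedFC` (see
#'   [mklModelFactory()], [sdkModelFactory()]).
#' @param protocol `"kfold"`, `"loo"` or `"holdout_half"`.
#' @param k folds for `"kfold"`.
#' @param seed integer seed for the splits.
#' @return An [EvaluationReport-class]; `perSubject` holds one correlation
#'   per evaluated (test) subject.
#' @export
crossValidate <- function(cohort, modelFactory,
                          protocol = c("kfold", "loo", "holdout_half"),
                          k = 5L, seed = 1L) {
  stopifnot(is(cohort, "SCFCCohort"))
  protocol <- match.arg(protocol)
  p <- length(cohort)
  if (p < 2L) stop("need at least 2 subjects for cross-validation")
  seed <- as.integer(seed)
  splitSeed <- subSeed(seed, "cv-folds")
  if (protocol == "loo") {
    folds <- seq_len(p)
  } else if (protocol == "kfold") {
    if (p < k) stop("need at least k = ", k, " subjects for k-fold")
    folds <- withSeed(splitSeed, sample(rep(seq_len(k), length.out = p)))
  } else {
    train <- withSeed(splitSeed, sample(seq_len(p), floor(p / 2)))
    folds <- ifelse(seq_len(p) %in% train, 0L, 1L)  # fold 1 = test half
  }
  scores <- numeric(0)
  evaluated <- integer(0)
  for (f in sort(unique(folds[folds > 0L]))) {
    testIdx <- which(folds == f)
    trainIdx <- if (protocol == "holdout_half") which(folds == 0L) else
      which(folds != f)
    predictor <- modelFactory(cohort[trainIdx])
    for (s in testIdx) {
      pred <- predictor(getSubject(cohort, s))
      scores <- c(scores, fcCorrelation(pred, cohort@fcs[[s]]))
      evaluated <- c(evaluated, s)
    }
  }
  names(scores) <- cohort@subjectIDs[evaluated]
  foldsOut <- as.integer(folds[evaluated])
  names(foldsOut) <- cohort@subjectIDs[evaluated]
  new("EvaluationReport", perSubject = scores,
      meanCorrelation = mean(scores),
      sdCorrelation = if (length(scores) > 1L) sd(scores) else 0,
      protocol = protocol, folds = foldsOut, seed = seed)
}

#' Threshold a structural connectome to its strongest connections
#'
#' Ranks the unique undirected nonzero edges by weight (descending) and keeps
#' the `ceiling(topPercent/100 * E)` strongest, zeroing the rest; ties at the
#' cutoff are broken by lexicographic (i, j) order. Symmetry is preserved.
#' If thresholding isolates a node, a warning is emitted and the returned
#' object carries `metadata$isolatedNodes` (prediction from such graphs may
#' degrade and the normalized Laplacian is undefined).
#'
#' @param sc a [StructuralConnectome-class].
#' @param topPercent percentage of edges to keep, in (0, 100\].
#' @return A thresholded [StructuralConnectome-class].
#' @export
thresholdSC <- function(sc, topPercent) {
  stopifnot(is(sc, "StructuralConnectome"))
  if (!is.numeric(topPercent) || topPercent <= 0 || topPercent > 100)
    stop("topPercent must lie in (0, 100]")
  w <- sc@weights
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[upper.tri(w)]
  nz <- which(vals > 0)
  E <- length(nz)
  keep <- ceiling(topPercent / 100 * E)
  ord <- nz[order(-vals[nz], ut[nz, 1L], ut[nz, 2L])]
  drop <- ord[-seq_len(keep)]
  out <- w
  for (e in drop) {
    out[ut[e, 1L], ut[e, 2L]] <- 0
    out[ut[e, 2L], ut[e, 1L]] <- 0
  }
  res <- StructuralConnectome(out, regionLabels = sc@regionLabels,
                              subjectID = sc@subjectID, allowIsolated = TRUE)
  if (!is.null(res@metadata$isolatedNodes))
    warning("thresholding isolated node(s) ",
            paste(res@metadata$isolatedNodes, collapse = ", "),
            call. = FALSE)
  res
}

#' Degree-destroying structural perturbation
#'
#' The robustness null for the structural input: the multiset of
#' off-diagonal upper-triangle weights (zeros included) is permuted uniformly
#' across all upper-triangle positions and mirrored for symmetry. The weight
#' multiset is preserved exactly; the degree sequence and all topology
#' generally are not.
#'
#' @param sc a [StructuralConnectome-class].
#' @param seed integer seed (substream `"perturb-sc"`).
#' @return A perturbed [StructuralConnectome-class] (isolated nodes allowed).
#' @export
perturbSC <- function(sc, seed = 1L) {
  stopifnot(is(sc, "StructuralConnectome"))
  w <- sc@weights
  vals <- w[upper.tri(w)]
  perm <- withSeed(subSeed(seed, "perturb-sc"), sample(length(vals)))
  out <- matrix(0, nrow(w), ncol(w))
  out[upper.tri(out)] <- vals[perm]
  out <- out + t(out)
  StructuralConnectome(out, regionLabels = sc@regionLabels,
                       subjectID = sc@subjectID, allowIsolated = TRUE)
}

#' Score predictions from perturbed structural inputs
#'
#' The structural robustness experiment: each draw perturbs every test
#' subject's SC with [perturbSC()], rebuilds its Laplacian and kernel bank at
#' the cohort scale set, predicts FC with the intact co-activation stack and
#' records the mean correlation over subjects. Draws whose permutation
#' isolates a node (where the normalized Laplacian is undefined) are redrawn
#' with a derived seed.
#'
#' @param stack an intact fitted [CoactivationStack-class].
#' @param cohort test [SCFCCohort-class].
#' @param nDraws number of perturbation draws (default 250).
#' @param seed integer master seed.
#' @param normalization Laplacian normalization for the rebuilt graphs.
#' @return Numeric vector of `nDraws` mean correlations.
#' @export
perturbedScTest <- function(stack, cohort, nDraws = 250L, seed = 1L,
                            normalization = "symmetric_normalized") {
  stopifnot(is(stack, "CoactivationStack"), is(cohort, "SCFCCohort"))
  p <- length(cohort)
  vapply(seq_len(nDraws), function(d) {
    scores <- vapply(seq_len(p), function(s) {
      attempt <- 0L
      repeat {
        pert <- perturbSC(cohort@scs[[s]],
                          seed = subSeed(seed, sprintf("draw-%d-subj-%d-%d",
                                                       d, s, attempt)))
        if (is.null(pert@metadata$isolatedNodes)) break
        attempt <- attempt + 1L
        if (attempt > 100L) stop("could not draw a connected perturbation")
      }
      spec <- buildLaplacian(pert, normalization = normalization)
      bank <- buildKernelBank(spec, cohort@scaleSet)
      fcCorrelation(predictFC(bank, stack), cohort@fcs[[s]])
    }, numeric(1))
    mean(scores)
  }, numeric(1))
}

#' Scale-specificity swap test of the co-activation matrices
#'
#' For each scale index i, swaps pi_i with pi_m (the last matrix), predicts
#' every test subject and records the mean correlation. The i = m entry swaps
#' the last matrix with itself, so it equals the unswapped baseline exactly;
#' swapping distant scales degrades performance if the parameters are
#' genuinely scale-specific.
#'
#' @param stack a fitted [CoactivationStack-class].
#' @param cohort test [SCFCCohort-class].
#' @return Numeric vector of m mean correlations (entry m = baseline).
#' @export
swapPiTest <- function(stack, cohort) {
  stopifnot(is(stack, "CoactivationStack"), is(cohort, "SCFCCohort"))
  m <- length(stack@pis)
  vapply(seq_len(m), function(i) {
    pis <- stack@pis
    tmp <- pis[[i]]; pis[[i]] <- pis[[m]]; pis[[m]] <- tmp
    swapped <- CoactivationStack(do.call(rbind, pis), stack@scaleSet,
                                 lambda = stack@lambda)
    mean(vapply(seq_len(length(cohort)), function(s) {
      fcCorrelation(predictFC(cohort@banks[[s]], swapped),
                    cohort@fcs[[s]])
    }, numeric(1)))
  }, numeric(1))
}

#' Row-permutation null of the co-activation stack
#'
#' Each draw permutes the mn rows of the stacked Pi uniformly at random,
#' predicts every test subject and records the mean correlation, giving a
#' null distribution against which the intact score is compared.
#'
#' @param stack a fitted [CoactivationStack-class].
#' @param cohort test [SCFCCohort-class].
#' @param nPerm number of permutation draws (default 250).
#' @param seed integer seed (substream `"pi-rows"`).
#' @return Numeric vector of `nPerm` mean correlations.
#' @export
permutePiRowsTest <- function(stack, cohort, nPerm = 250L, seed = 1L) {
  stopifnot(is(stack, "CoactivationStack"), is(cohort, "SCFCCohort"))
  mn <- nrow(stack@stacked)
  p <- length(cohort)
  perms <- withSeed(subSeed(seed, "pi-rows"),
                    lapply(seq_len(nPerm), function(i) sample(mn)))
  vapply(perms, function(perm) {
    permStacked <- stack@stacked[perm, , drop = FALSE]
    mean(vapply(seq_len(p), function(s) {
      C <- symmetrizeMatrix(cohort@banks[[s]]@stacked %*% permStacked)
      fcCorrelation(C, cohort@fcs[[s]]@values)
    }, numeric(1)))
  }, numeric(1))
}

#' Seed-based correlation map
#'
#' The connectivity profile of one seed region: the seed's row of the
#' (symmetrized) connectivity matrix. For empirical FC the self-entry is 1.
#'
#' @param fc a [FunctionalConnectome-class], [PredictedFC-class] or matrix.
#' @param seedRegion region index (or label, for a labelled empirical FC).
#' @return Numeric vector of length n.
#' @export
seedCorrelationMap <- function(fc, seedRegion) {
  v <- if (is.matrix(fc)) fc else connMatrix(fc)
  v <- symmetrizeMatrix(v)
  if (!is.numeric(seedRegion) || seedRegion < 1 || seedRegion > nrow(v))
    stop("seedRegion must be a region index in 1..", nrow(v))
  as.numeric(v[seedRegion, ])
}

#' Group-mean connectivity matrix
#'
#' Arithmetic mean of subject matrices (no Fisher transform), used for
#' group-level seed maps.
#'
#' @param fcs list of [FunctionalConnectome-class] / [PredictedFC-class] /
#'   matrices with common dimension.
#' @return The mean matrix.
#' @export
groupMeanFC <- function(fcs) {
  mats <- lapply(fcs, function(f) if (is.matrix(f)) f else connMatrix(f))
  Reduce(`+`, mats) / length(mats)
}
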