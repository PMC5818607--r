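test_that("fc correlation works on the off-diagonal upper triangle", {
  gen <- testCohort()
  fc <- gen$cohort@fcs[[1]]
  expect_equal(fcCorrelation(fc, fc), 1.0)
  neg <- connMatrix(fc)
  neg[upper.tri(neg) | lower.tri(neg)] <- -neg[upper.tri(neg) | lower.tri(neg)]
  expect_equal(fcCorrelation(neg, fc), -1.0)
  # formula oracle on a random 4x4 pair
  set.seed(19)
  a <- matrix(rnorm(16), 4); a <- a + t(a); diag(a) <- 1
  b <- matrix(rnorm(16), 4); b <- b + t(b); diag(b) <- 1
  x <- a[upper.tri(a)]; y <- b[upper.tri(b)]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fcCorrelation(a, b), oracle, tolerance = 1e-12)
  expect_error(fcCorrelation(diag(4), b), "zero-variance")
})

test_that("cross-validation protocols split subjects as specified", {
  gen <- testCohort()
  cohort <- gen$cohort
  p <- length(cohort)
  factory <- mklModelFactory(lambda = 0.01)
  loo <- crossValidate(cohort, factory, protocol = "loo", seed = 4L)
  expect_length(perSubjectCorrelation(loo), p)
  expect_equal(meanCorrelation(loo), mean(perSubjectCorrelation(loo)),
               tolerance = 1e-14)
  kf <- crossValidate(cohort, factory, protocol = "kfold", k = 4L, seed = 4L)
  expect_length(perSubjectCorrelation(kf), p)
  expect_identical(sort(unique(kf@folds)), 1:4)
  expect_true(max(table(kf@folds)) - min(table(kf@folds)) <= 1)
  kf2 <- crossValidate(cohort, factory, protocol = "kfold", k = 4L, seed = 4L)
  expect_identical(kf@folds, kf2@folds)  # same seed, same folds
  expect_identical(perSubjectCorrelation(kf), perSubjectCorrelation(kf2))
  ho <- crossValidate(cohort, factory, protocol = "holdout_half", seed = 4L)
  expect_length(perSubjectCorrelation(ho), p - floor(p / 2))
  expect_error(crossValidate(cohort[1], factory, protocol = "loo"),
               "at least 2")
})

test_that("five folds of nine subjects each on a 45-subject roster", {
  # protocol arithmetic only; predictor is a stub returning the subject's FC
  gen <- generateCohort(SyntheticCohortSpec(n = 6L, p = 5L, m = 2L,
                                            seed = 11L))
  big <- gen$cohort[rep(1:5, 9)]  # 45 subjects
  echoFactory <- function(train) function(subject)
    new("PredictedFC", values = connMatrix(subject$fc), symmetrized = TRUE)
  rep5 <- crossValidate(big, echoFactory, protocol = "kfold", k = 5L,
                        seed = 8L)
  expect_identical(as.integer(table(rep5@folds)), rep(9L, 5L))
  expect_length(perSubjectCorrelation(rep5), 45L)
})

test_that("thresholding keeps the strongest edges and preserves symmetry", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 2; w[2, 3] <- w[3, 2] <- 3
  sc <- StructuralConnectome(w)
  kept <- suppressWarnings(thresholdSC(sc, 34))  # ceil(0.34*3) = 2 edges
  expect_identical(sum(connMatrix(kept)[upper.tri(w)] > 0), 2L)
  expect_identical(connMatrix(kept)[1, 2], 0)
  one <- suppressWarnings(thresholdSC(sc, 33))   # ceil(0.33*3) = 1 edge
  expect_identical(sum(connMatrix(one)[upper.tri(w)] > 0), 1L)
  expect_identical(connMatrix(one)[2, 3], 3)
  # top 100% leaves the graph untouched
  sc2 <- randomSC(10, seed = 53)
  expect_identical(connMatrix(thresholdSC(sc2, 100)), connMatrix(sc2))
  # kept count follows ceil arithmetic on an enumerated toy
  dense <- completeSC(15)  # 105 edges; perturb weights to break ties
  set.seed(3)
  wd <- connMatrix(dense) * matrix(runif(225, 0.5, 1.5), 15)
  wd <- (wd + t(wd)) / 2
  dense <- StructuralConnectome(wd)
  t15 <- suppressWarnings(thresholdSC(dense, 15))
  expect_identical(sum(connMatrix(t15)[upper.tri(wd)] > 0),
                   as.integer(ceiling(0.15 * 105)))
  expect_error(thresholdSC(sc2, 0), "topPercent")
})

test_that("SC perturbation preserves the weight multiset, not degrees", {
  sc <- randomSC(12, seed = 59)
  pert <- perturbSC(sc, seed = 5L)
  expect_identical(sort(upperOffDiagForTest(connMatrix(pert))),
                   sort(upperOffDiagForTest(connMatrix(sc))))
  expect_false(isTRUE(all.equal(rowSums(connMatrix(pert)),
                                rowSums(connMatrix(sc)))))
  expect_equal(connMatrix(pert), t(connMatrix(pert)))
  # over many draws the perturbed weights decorrelate from the original
  rs <- vapply(1:250, function(d) {
    pd <- perturbSC(sc, seed = d)
    cor(upperOffDiagForTest(connMatrix(pd)),
        upperOffDiagForTest(connMatrix(sc)))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("swap test baseline and degradation behave as designed", {
  gen <- testCohort()
  stack <- fitMKL(gen$cohort[1:5], lambda = 0.01)
  test3 <- gen$cohort[6:8]
  swp <- swapPiTest(stack, test3)
  m <- length(scales(gen$cohort))
  expect_length(swp, m)
  baseline <- mean(vapply(1:3, function(s) {
    fcCorrelation(predictFC(test3@banks[[s]], stack), test3@fcs[[s]])
  }, numeric(1)))
  expect_identical(swp[m], baseline)  # no-swap entry is exact
  # swapping a distant scale into the last slot degrades performance
  expect_gt(baseline - swp[1], 0.1)
  # swapping a matrix with a near-identical copy of pi_m barely degrades
  stack2 <- stack
  pis <- piList(stack2)
  pis[[m - 1]] <- pis[[m]] + 1e-10
  stack2 <- CoactivationStack(do.call(rbind, pis), stack2@scaleSet,
                              penaltyLambda(stack2))
  swp2 <- swapPiTest(stack2, test3)
  expect_lt(abs(swp2[m] - swp2[m - 1]), 1e-6)
})

test_that("row-permutation null falls below the intact score", {
  gen <- testCohort()
  stack <- fitMKL(gen$cohort[1:5], lambda = 0.01)
  test3 <- gen$cohort[6:8]
  nulls <- permutePiRowsTest(stack, test3, nPerm = 60, seed = 2L)
  expect_length(nulls, 60L)
  intact <- mean(vapply(1:3, function(s) {
    fcCorrelation(predictFC(test3@banks[[s]], stack), test3@fcs[[s]])
  }, numeric(1)))
  expect_gt(intact, quantile(nulls, 0.95))
  # identity permutation reproduces the baseline
  idStack <- CoactivationStack(stackedPi(stack)[seq_len(nrow(stackedPi(stack))), ],
                               stack@scaleSet, penaltyLambda(stack))
  expect_identical(
    mean(vapply(1:3, function(s)
      fcCorrelation(predictFC(test3@banks[[s]], idStack), test3@fcs[[s]]),
      numeric(1))), intact)
  # reproducibility under the same seed
  expect_identical(nulls, permutePiRowsTest(stack, test3, nPerm = 60,
                                            seed = 2L))
})

test_that("perturbed-SC predictions score below intact predictions", {
  gen <- testCohort()
  stack <- fitMKL(gen$cohort[1:5], lambda = 0.01)
  test3 <- gen$cohort[6:8]
  pert <- perturbedScTest(stack, test3, nDraws = 15, seed = 3L)
  expect_length(pert, 15L)
  intact <- mean(vapply(1:3, function(s) {
    fcCorrelation(predictFC(test3@banks[[s]], stack), test3@fcs[[s]])
  }, numeric(1)))
  expect_gt(intact, mean(pert))
})

test_that("prediction quality recovers monotonically with threshold level", {
  gen <- testCohort()
  stack <- fitMKL(gen$cohort[1:5], lambda = 0.01)
  test3 <- gen$cohort[6:8]
  scores <- vapply(c(40, 60, 80, 100), function(T) {
    mean(vapply(1:3, function(s) {
      scT <- suppressWarnings(thresholdSC(test3@scs[[s]], T))
      if (!is.null(scT@metadata$isolatedNodes)) return(NA_real_)
      bank <- buildKernelBank(buildLaplacian(scT), test3@scaleSet)
      fcCorrelation(predictFC(bank, stack), test3@fcs[[s]])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  # non-decreasing within Monte-Carlo tolerance
  expect_true(all(diff(scores) > -0.01))
  expect_equal(scores[4], mean(vapply(1:3, function(s) {
    fcCorrelation(predictFC(test3@banks[[s]], stack), test3@fcs[[s]])
  }, numeric(1))), tolerance = 1e-12)
})

test_that("seed maps are matrix rows and group maps average linearly", {
  gen <- testCohort()
  fc <- gen$cohort@fcs[[2]]
  map <- seedCorrelationMap(fc, 3)
  expect_identical(map, as.numeric(connMatrix(fc)[3, ]))
  expect_identical(map[3], 1)
  maps <- lapply(gen$cohort@fcs, seedCorrelationMap, seedRegion = 3)
  groupMap <- seedCorrelationMap(groupMeanFC(gen$cohort@fcs), 3)
  expect_equal(groupMap, Reduce(`+`, maps) / length(maps),
               tolerance = 1e-12)
  expect_error(seedCorrelationMap(fc, 99), "region index")
})
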