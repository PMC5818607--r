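test_that("design assembly stacks banks and FC matrices consistently", {
  gen <- testCohort()
  cohort <- gen$cohort
  d <- assembleDesign(cohort)
  p <- length(cohort); n <- nRegions(cohort); m <- length(scales(cohort))
  expect_identical(dim(d$X), c(p * n, m * n))
  expect_identical(dim(d$Y), c(p * n, n))
  for (s in c(1L, p)) {
    rows <- (s - 1L) * n + seq_len(n)
    expect_identical(d$X[rows, ], stackedKernels(cohort@banks[[s]]))
    expect_identical(d$Y[rows, ], connMatrix(cohort@fcs[[s]]))
  }
  # p = 1, m = 1 bank of gamma ~ 0 kernels: X is (numerically) the identity
  spec <- buildLaplacian(completeSC(4))
  bank <- buildKernelBank(spec, ScaleSet(1e-12))
  fc <- FunctionalConnectome(diag(4), "one")
  one <- new("SCFCCohort", scs = list(completeSC(4)), specs = list(spec),
             banks = list(bank), fcs = list(fc), scaleSet = ScaleSet(1e-12),
             subjectIDs = "one")
  expect_equal(assembleDesign(one)$X, diag(4), tolerance = 1e-10)
})

test_that("fitColumn solves identity designs and full-shrinkage exactly", {
  y <- c(1.5, -2, 0.25, 0)
  expect_equal(fitColumn(diag(4), y, lambda = 0), y,
               ignore_attr = TRUE, tolerance = 1e-12)
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  yv <- rnorm(10)
  lamMax <- max(abs(2 * crossprod(X, yv)))
  expect_equal(fitColumn(X, yv, lambda = lamMax + 1e-9), rep(0, 4),
               ignore_attr = TRUE)
  expect_error(fitColumn(X, yv, lambda = -1), "nonnegative")
})

test_that("fitColumn satisfies the LASSO KKT conditions on random instances", {
  set.seed(7)
  worst <- 0
  for (i in 1:25) {
    pn <- sample(6:20, 1); mn <- sample(3:10, 1)
    X <- matrix(rnorm(pn * mn), pn, mn)
    y <- rnorm(pn)
    lambda <- runif(1, 0.05, 2)
    b <- fitColumn(X, y, lambda, tol = 1e-9)
    worst <- max(worst, lassoKKTViolation(X, y, b, lambda))
  }
  expect_lt(worst, 1e-5)
})

test_that("fitColumn matches the brute-force reference objective", {
  set.seed(11)
  for (i in 1:6) {
    pn <- 12; mn <- sample(4:8, 1)
    X <- matrix(rnorm(pn * mn), pn, mn)
    y <- rnorm(pn)
    lambda <- runif(1, 0.1, 1.5)
    b <- fitColumn(X, y, lambda, tol = 1e-9)
    ref <- lassoBruteForce(X, y, lambda, iters = 20000L)
    fCD <- lassoObjective(X, y, b, lambda)
    expect_lt(abs(fCD - ref$objective) / abs(ref$objective), 1e-4)
  }
})

test_that("fitColumn agrees with glmnet on its shared objective", {
  skip_if_not_installed("glmnet")
  set.seed(13)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  lambda <- 0.8
  b <- fitColumn(X, y, lambda, tol = 1e-10)
  # glmnet minimises (1/2N)||y - Xb||^2 + lam||b||_1
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda / (2 * nrow(X)),
                      intercept = FALSE, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(as.numeric(g$beta), as.numeric(b), tolerance = 1e-5)
})

test_that("training objective decomposes over columns", {
  gen <- testCohort()
  cohort <- gen$cohort[1:5]
  d <- assembleDesign(cohort)
  stack <- fitMKL(cohort, lambda = 0.01)
  B <- stackedPi(stack)
  total <- sum((d$X %*% B - d$Y)^2) + 0.01 * sum(abs(B))
  perColumn <- vapply(seq_len(ncol(d$Y)), function(j) {
    sum((d$X %*% B[, j] - d$Y[, j])^2) + 0.01 * sum(abs(B[, j]))
  }, numeric(1))
  expect_equal(total, sum(perColumn), tolerance = 1e-10)
})

test_that("lasso path sparsity is monotone in lambda", {
  gen <- testCohort()
  cohort <- gen$cohort[1:5]
  d <- assembleDesign(cohort)
  lamMax <- max(abs(2 * crossprod(d$X, d$Y)))
  nnz <- vapply(lamMax * 10^seq(0, -3, by = -0.5), function(l) {
    sum(stackedPi(fitMKL(cohort, lambda = l)) != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))  # descending lambda, non-decreasing nnz
})

test_that("fitMKL is deterministic for fixed cohort, lambda and seed", {
  gen <- testCohort()
  cohort <- gen$cohort[1:5]
  a <- fitMKL(cohort, lambda = "auto", seed = 9L)
  b <- fitMKL(cohort, lambda = "auto", seed = 9L)
  expect_identical(stackedPi(a), stackedPi(b))
  expect_identical(penaltyLambda(a), penaltyLambda(b))
})

test_that("predictFC reproduces single-kernel and linear structure", {
  gen <- testCohort()
  bank <- gen$cohort@banks[[1]]
  n <- nRegions(gen$cohort); m <- length(scales(gen$cohort))
  # pi_1 = I, others 0: prediction equals H_1
  stacked <- matrix(0, m * n, n)
  stacked[seq_len(n), ] <- diag(n)
  st <- CoactivationStack(stacked, gen$cohort@scaleSet)
  expect_equal(connMatrix(predictFC(bank, st, symmetrize = FALSE)),
               kernelList(bank)[[1]], tolerance = 1e-12)
  # Pi = 0 predicts 0
  zero <- CoactivationStack(matrix(0, m * n, n), gen$cohort@scaleSet)
  expect_identical(connMatrix(predictFC(bank, zero)), matrix(0, n, n))
  # linearity in Pi
  set.seed(3)
  A <- CoactivationStack(matrix(rnorm(m * n * n), m * n, n),
                         gen$cohort@scaleSet)
  B <- CoactivationStack(matrix(rnorm(m * n * n), m * n, n),
                         gen$cohort@scaleSet)
  AB <- CoactivationStack(stackedPi(A) + stackedPi(B), gen$cohort@scaleSet)
  expect_equal(connMatrix(predictFC(bank, AB)),
               connMatrix(predictFC(bank, A)) +
                 connMatrix(predictFC(bank, B)),
               tolerance = 1e-10)
  # scale-set mismatch is an error
  other <- CoactivationStack(matrix(0, 2 * n, n), ScaleSet(c(1, 2)))
  expect_error(predictFC(bank, other), "scale-set mismatch")
})

test_that("noiseless forward-model round trip recovers held-out FC", {
  gen <- generateCohort(SyntheticCohortSpec(n = 12L, p = 8L, m = 3L,
                                            fcNoiseSD = 0, seed = 5L))
  train <- gen$cohort[1:6]
  stack <- fitMKL(train, lambda = 0)
  rs <- vapply(7:8, function(s) {
    fcCorrelation(predictFC(gen$cohort@banks[[s]], stack),
                  gen$cohort@fcs[[s]])
  }, numeric(1))
  expect_true(all(rs > 0.99))
})

test_that("model serialization round-trips through a directory", {
  gen <- testCohort()
  stack <- fitMKL(gen$cohort[1:4], lambda = 0.05)
  dir <- withr::local_tempdir()
  writeMKLModel(stack, dir, trainingIDs = gen$cohort@subjectIDs[1:4])
  back <- readMKLModel(dir)
  expect_equal(stackedPi(back), stackedPi(stack), tolerance = 1e-15)
  expect_equal(scales(back), scales(stack), tolerance = 1e-12)
  expect_identical(attr(back, "trainingIDs"), gen$cohort@subjectIDs[1:4])
})
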