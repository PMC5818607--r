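test_that("structural connectome construction sanitises and validates", {
  w <- matrix(c(0, 2, 2, 0), 2, 2)
  sc <- StructuralConnectome(w, subjectID = "a")
  expect_identical(connMatrix(sc), w)
  # near-symmetric input is averaged
  w2 <- w; w2[1, 2] <- 2 + 1e-9
  expect_equal(connMatrix(StructuralConnectome(w2))[1, 2], 2 + 5e-10)
  # asymmetry beyond tolerance, isolated nodes, negatives all rejected
  w3 <- w; w3[1, 2] <- 3
  expect_error(StructuralConnectome(w3), "asymmetric")
  expect_error(StructuralConnectome(matrix(0, 2, 2)), "isolated")
  expect_error(StructuralConnectome(matrix(c(0, -1, -1, 0), 2, 2)),
               "nonnegative")
})

test_that("normalized Laplacian of K2 and K5 matches closed forms", {
  spec2 <- buildLaplacian(completeSC(2))
  expect_equal(eigenvalues(spec2), c(0, 2), tolerance = 1e-12)
  spec5 <- buildLaplacian(completeSC(5))
  expect_equal(eigenvalues(spec5), c(0, rep(1.25, 4)), tolerance = 1e-10)
  # dense eigensolver oracle on the same matrix
  oracle <- sort(eigen(laplacianMatrix(spec5), symmetric = TRUE)$values)
  expect_equal(eigenvalues(spec5), pmax(oracle, 0), tolerance = 1e-10)
})

test_that("Laplacian null space is D^{1/2} 1 (normalized) or 1", {
  sc <- randomSC(9, seed = 3)
  spec <- buildLaplacian(sc)
  expect_lt(eigenvalues(spec)[1], 1e-8)
  v0 <- eigenvectors(spec)[, 1]
  ref <- sqrt(rowSums(connMatrix(sc)))
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(v0), ref, tolerance = 1e-8)
  specU <- buildLaplacian(sc, normalization = "unnormalized")
  expect_equal(abs(eigenvectors(specU)[, 1]), rep(1 / 3, 9),
               tolerance = 1e-8)
})

test_that("diffusion kernel matches the dense matrix-exponential oracle", {
  for (seed in 1:3) {
    sc <- randomSC(sample(5:20, 1), seed = seed)
    spec <- buildLaplacian(sc)
    for (gamma in c(0.05, 0.7, 3)) {
      H <- diffusionKernel(spec, gamma)
      expect_lt(max(abs(H - expmOracle(-gamma * laplacianMatrix(spec)))),
                1e-8)
    }
  }
})

test_that("kernel identity, semigroup, and PSD properties hold", {
  spec <- buildLaplacian(randomSC(10, seed = 5))
  expect_equal(diffusionKernel(spec, 0), diag(10), tolerance = 1e-12)
  H1 <- diffusionKernel(spec, 0.4)
  H2 <- diffusionKernel(spec, 1.1)
  expect_equal(H1 %*% H2, diffusionKernel(spec, 1.5), tolerance = 1e-8)
  expect_gt(min(eigen(H1, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  expect_error(diffusionKernel(spec, -1), "nonnegative")
})

test_that("large-scale kernel converges to the stationary projector", {
  spec <- buildLaplacian(randomSC(8, seed = 7))
  v0 <- eigenvectors(spec)[, 1]
  expect_lt(max(abs(diffusionKernel(spec, 1e3) - tcrossprod(v0))), 1e-6)
})

test_that("kernels are invariant to eigenvector sign flips", {
  spec <- buildLaplacian(randomSC(7, seed = 11))
  H <- diffusionKernel(spec, 0.8)
  flipped <- spec
  flipped@eigenvectors[, c(2, 5)] <- -flipped@eigenvectors[, c(2, 5)]
  expect_lt(max(abs(diffusionKernel(flipped, 0.8) - H)), 1e-10)
})

test_that("kernel trace contracts monotonically in the scale", {
  spec <- buildLaplacian(randomSC(9, seed = 13))
  traces <- vapply(c(0, 0.1, 0.5, 1, 2, 5, 20),
                   function(g) sum(diag(diffusionKernel(spec, g))),
                   numeric(1))
  expect_true(all(diff(traces) <= 1e-12))
})

test_that("kernel bank stacks the per-scale kernels in order", {
  spec <- buildLaplacian(randomSC(6, seed = 17))
  ss <- ScaleSet(c(0.2, 0.9, 4))
  bank <- buildKernelBank(spec, ss)
  expect_identical(dim(stackedKernels(bank)), c(6L, 18L))
  for (i in 1:3) {
    expect_equal(kernelList(bank)[[i]],
                 diffusionKernel(spec, scales(bank)[i]), tolerance = 1e-12)
    expect_identical(stackedKernels(bank)[, (i - 1) * 6 + 1:6],
                     kernelList(bank)[[i]])
  }
})

test_that("default scale set spans identity-to-stationarity deviations", {
  spec <- buildLaplacian(randomSC(14, seed = 19))
  ss <- defaultScaleSet(spec)
  expect_length(scales(ss), 16L)
  expect_true(all(diff(scales(ss)) > 0))
  n <- 14
  gMin <- min(scales(ss)); gMax <- max(scales(ss))
  expect_equal(norm(diffusionKernel(spec, gMin) - diag(n), "F"), 0.01 * n,
               tolerance = 1e-6)
  v0 <- eigenvectors(spec)[, 1]
  expect_equal(norm(diffusionKernel(spec, gMax) - tcrossprod(v0), "F"),
               0.01 * n, tolerance = 1e-6)
  # endpoints are m-invariant: doubling m nests the extremes
  ss32 <- defaultScaleSet(spec, m = 32L)
  expect_equal(range(scales(ss32)), range(scales(ss)), tolerance = 1e-10)
  # disconnected graph has no stationary projector
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  expect_error(defaultScaleSet(buildLaplacian(StructuralConnectome(w))),
               "disconnected")
})

test_that("graph signal evolution decays onto the null mode", {
  spec <- buildLaplacian(randomSC(9, seed = 23))
  u0 <- rnorm(9)
  expect_equal(evolveGraphSignal(spec, u0, t = 0), u0, tolerance = 1e-12)
  v0 <- eigenvectors(spec)[, 1]
  expect_equal(evolveGraphSignal(spec, v0, t = 50), v0, tolerance = 1e-8)
  # long-time limit is the spectral projection onto the null eigenvector
  proj <- v0 * sum(v0 * u0)
  expect_equal(evolveGraphSignal(spec, u0, t = 1e4), proj, tolerance = 1e-6)
  expect_error(evolveGraphSignal(spec, u0, t = -1), "nonnegative")
})

test_that("per-mode decay matches its small-sigma Taylor limit", {
  spec <- buildLaplacian(randomSC(8, seed = 29))
  lam <- eigenvalues(spec)
  sigma2 <- 0.02
  tau <- 1; t <- 2
  exact <- exp(-(1 - exp(-lam * sigma2 / 2)) * t / tau)
  approx <- exp(-lam * sigma2 * t / (2 * tau))
  relErr <- abs(exact - approx) / approx
  expect_true(all(relErr <= 10 * (sigma2 * max(lam) / 2)^2))
})
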