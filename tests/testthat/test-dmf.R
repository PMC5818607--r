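test_that("transfer function handles the removable singularity and is monotone", {
  p <- DMFParameters()
  # limit at a x = b is 1/d
  expect_equal(firingRate(p@b / p@a, p), 1 / p@d, tolerance = 1e-9)
  # scalar oracle evaluation at x = 0.5 with defaults
  u <- 270 * 0.5 - 108
  expect_equal(firingRate(0.5, p), u / (1 - exp(-0.154 * u)),
               tolerance = 1e-12)
  x <- seq(-0.2, 1.5, length.out = 200)
  expect_true(all(diff(firingRate(x, p)) >= 0))
  # continuity across the singularity
  eps <- 1e-9
  expect_equal(firingRate(p@b / p@a + eps, p), firingRate(p@b / p@a - eps, p),
               tolerance = 1e-6)
})

test_that("uncoupled noiseless integration reaches the scalar fixed point", {
  sc <- completeSC(5)
  p <- DMFParameters(G = 0, sigmaNoise = 0)
  st <- SimulationSettings(dt = 0.001, duration = 25, tr = 1, burnIn = 1,
                           seed = 1L)
  S <- dmfIntegrate(sc, p, st)
  # independent scalar root-finder oracle for S/tauS = (1-S) gam H(w JN S + I0)
  g <- function(s) -s / p@tauS + (1 - s) * p@gammaKinetic *
    firingRate(p@w * p@JN * s + p@I0, p)
  sStar <- uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(unname(S[nrow(S), ]), rep(sStar, 5), tolerance = 1e-4)
  expect_true(all(S >= 0 & S <= 1))
})

test_that("regular graph with sigma = 0 keeps nodes exchangeable", {
  sc <- completeSC(6)
  p <- DMFParameters(G = 0.5, sigmaNoise = 0)
  st <- SimulationSettings(dt = 0.001, duration = 5, tr = 1, burnIn = 1)
  S <- dmfIntegrate(sc, p, st, S0 = 0.2)
  expect_lt(max(abs(S - S[, 1])), 1e-12)
})

test_that("trajectories are bit-identical under a fixed seed", {
  sc <- randomSC(6, seed = 41)
  p <- DMFParameters(G = 1)
  st <- SimulationSettings(dt = 0.001, duration = 3, tr = 1, burnIn = 1,
                           seed = 7L)
  expect_identical(dmfIntegrate(sc, p, st), dmfIntegrate(sc, p, st))
})

test_that("noise-induced variance about the fixed point scales with sigma^2", {
  sc <- completeSC(5)
  st <- SimulationSettings(dt = 0.001, duration = 40, tr = 1, burnIn = 1,
                           seed = 3L)
  getVar <- function(sigma) {
    S <- dmfIntegrate(sc, DMFParameters(G = 0, sigmaNoise = sigma), st)
    mean(apply(S[-(1:20000), ], 2, var))  # discard transient
  }
  ratio <- getVar(0.002) / getVar(0.001)
  expect_lt(abs(ratio - 4), 4 * 0.3)
})

test_that("BOLD forward model settles to a constant for constant drive", {
  st <- SimulationSettings(dt = 0.001, duration = 60, tr = 1, burnIn = 40)
  S <- matrix(0.15, nrow = 60000 + 1, ncol = 2)
  bold <- boldForward(S, st)
  expect_lt(max(apply(bold@samples, 2, var)), 1e-8)
  # zero-length post-burn-in window errors
  stBad <- new("SimulationSettings", dt = 0.001, duration = 60, tr = 2,
               burnIn = 59.5, seed = 1L)
  expect_error(boldForward(S, stBad), "zero-length")
})

test_that("an 8-minute window at tr = 2 s yields 240 BOLD samples", {
  sc <- completeSC(3)
  st <- SimulationSettings(dt = 0.01, duration = 500, tr = 2, burnIn = 20,
                           seed = 2L)
  S <- dmfIntegrate(sc, DMFParameters(G = 0.2), st)
  bold <- boldForward(S, st)
  expect_identical(nrow(bold@samples), 240L)
  expect_identical(bold@tr, 2)
})

test_that("simulated FC is a unit-diagonal symmetric correlation matrix", {
  sc <- randomSC(5, seed = 43)
  st <- SimulationSettings(dt = 0.005, duration = 120, tr = 2, burnIn = 20,
                           seed = 11L)
  S <- dmfIntegrate(sc, DMFParameters(G = 1), st)
  fc <- dmfFC(boldForward(S, st))
  v <- connMatrix(fc)
  expect_equal(diag(v), rep(1, 5))
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_true(all(abs(v) <= 1 + 1e-12))
  # duplicated columns correlate exactly
  b <- new("BOLDTimeseries", samples = cbind(rnorm(50), rnorm(50)), tr = 2)
  b@samples[, 2] <- b@samples[, 1]
  expect_equal(connMatrix(dmfFC(b))[1, 2], 1)
})

test_that("white-noise columns decorrelate at large T", {
  set.seed(17)
  T <- 4000
  b <- new("BOLDTimeseries", samples = matrix(rnorm(T * 4), T, 4), tr = 2)
  off <- upperOffDiag(connMatrix(dmfFC(b)))
  expect_true(all(abs(off) < 3 / sqrt(T)))
})

test_that("global coupling fit recovers G on a self-consistent target", {
  sc <- randomSC(6, seed = 47)
  gGrid <- c(0, 0.8, 1.6, 2.4)
  params <- DMFParameters()
  st <- SimulationSettings(dt = 0.005, duration = 80, tr = 2, burnIn = 20,
                           seed = 5L)
  # target: FC simulated at G* under the same per-subject seed policy
  gStar <- gGrid[3]
  pStar <- params; pStar@G <- gStar
  stSubj <- st; stSubj@seed <- subSeed(st@seed, "dmf-subject-1")
  target <- dmfFC(boldForward(dmfIntegrate(sc, pStar, stSubj), stSubj))
  fit <- dmfFitG(sc, target, params, st, gGrid = gGrid)
  expect_lte(abs(fit$optimalG - gStar), diff(gGrid)[1])
  # per-subject best is the argmax of its correlation row
  expect_equal(fit$perSubject$correlation[1], max(fit$correlations[1, ]))
  # single-value grid returns that value
  fit1 <- dmfFitG(sc, target, params, st, gGrid = 1.2)
  expect_identical(fit1$optimalG, 1.2)
})
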