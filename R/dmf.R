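#' Population transfer function of the reduced mean-field model
#'
#' H(x) = (a x - b) / (1 - exp(-d (a x - b))), the sigmoid-like input-output
#' curve mapping input current to population firing rate (Hz). The removable
#' singularity at a x = b is evaluated by its analytic limit 1/d.
#'
#' @param x numeric vector of input currents (nA).
#' @param params a [DMFParameters-class].
#' @return Numeric vector of firing rates (Hz), monotone non-decreasing in
#'   `x`.
#' @examples
#' p <- DMFParameters()
#' firingRate(108 / 270, p)  # the limit 1/d ~ 6.49 Hz
#' @export
firingRate <- function(x, params = DMFParameters()) {
  stopifnot(is(params, "DMFParameters"))
  if (any(!is.finite(x))) stop("x must be finite")
  as.numeric(firingRateCpp(as.numeric(x), params@a, params@b, params@d))
}

#' Integrate the reduced dynamic mean field model
#'
#' Euler-Maruyama integration of the coupled stochastic gating equations
#' dS_i = \[-S_i / tauS + (1 - S_i) gamma H(x_i)\] dt + sigma sqrt(dt) N(0,1),
#' with input current x_i = w J_N S_i + G J_N sum_j C_ij S_j + I_0. The
#' gating variables are clipped to \[0, 1\] after every step. By default the
#' coupling matrix C is the SC weights normalized by their maximum entry, so
#' that the global coupling G has a comparable range across cohorts; set
#' `normalizeSC = FALSE` to use raw weights.
#'
#' The noise is drawn from R's RNG after `set.seed(settings@seed)` (via the
#' `"dmf-noise"` substream), so identical settings give a bit-identical
#' trajectory.
#'
#' @param sc a [StructuralConnectome-class].
#' @param params a [DMFParameters-class].
#' @param settings a [SimulationSettings-class].
#' @param S0 initial gating value(s), recycled to n (default 0.1).
#' @param normalizeSC divide SC by its maximum entry before coupling
#'   (default `TRUE`).
#' @return Matrix of gating trajectories, (steps + 1) x n at `dt` resolution,
#'   first row = initial state.
#' @export
dmfIntegrate <- function(sc, params = DMFParameters(),
                         settings = SimulationSettings(), S0 = 0.1,
                         normalizeSC = TRUE) {
  stopifnot(is(sc, "StructuralConnectome"), is(params, "DMFParameters"),
            is(settings, "SimulationSettings"))
  C <- sc@weights
  if (normalizeSC && max(C) > 0) C <- C / max(C)
  n <- nrow(C)
  S0 <- rep_len(S0, n)
  if (any(S0 < 0 | S0 > 1)) stop("S0 must lie in [0, 1]")
  nSteps <- as.integer(round(settings@duration / settings@dt))
  res <- withSeed(subSeed(settings@seed, "dmf-noise"),
    dmfIntegrateCpp(C, params@a, params@b, params@d, params@gammaKinetic,
                    params@tauS, params@w, params@JN, params@I0, params@G,
                    params@sigmaNoise, settings@dt, nSteps, S0))
  if (!isTRUE(res$ok))
    stop("integration blew up (non-finite state) at step ", res$badStep,
         ", node ", res$badNode)
  res$trajectory
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Rate of vasodilatory signal decay `kappa` (s^-1), flow-dependent
#' elimination `gammaH` (s^-1), hemodynamic transit time `tauH` (s), vessel
#' stiffness exponent `alpha`, resting oxygen extraction `rho`, and resting
#' venous volume fraction `V0`.
#'
#' @param kappa,gammaH,tauH,alpha,rho,V0 numeric scalars.
#' @return Named list of constants for [boldForward()].
#' @export
hemodynamicConstants <- function(kappa = 0.65, gammaH = 0.41, tauH = 0.98,
                                 alpha = 0.32, rho = 0.34, V0 = 0.02) {
  list(kappa = kappa, gammaH = gammaH, tauH = tauH, alpha = alpha,
       rho = rho, V0 = V0)
}

#' Transform synaptic activity into sampled BOLD signal
#'
#' Drives a Balloon-Windkessel model (vasodilatory signal, inflow, venous
#' volume, deoxyhemoglobin per region) with the gating trajectory, integrated
#' at the same `dt`, then discards the burn-in and samples every `tr`
#' seconds. The sample count is `floor((duration - burnIn) / tr)`; with the
#' defaults (8-minute window, tr = 2 s) that is 240 samples.
#'
#' @param S gating trajectory matrix from [dmfIntegrate()] ((steps + 1) x n).
#' @param settings the [SimulationSettings-class] used for the integration.
#' @param hemo hemodynamic constants from [hemodynamicConstants()].
#' @return A [BOLDTimeseries-class].
#' @export
boldForward <- function(S, settings = SimulationSettings(),
                        hemo = hemodynamicConstants()) {
  stopifnot(is.matrix(S), is(settings, "SimulationSettings"))
  if (any(!is.finite(S))) stop("gating trajectory contains non-finite values")
  dt <- settings@dt
  duration <- (nrow(S) - 1L) * dt
  nSamples <- floor((duration - settings@burnIn) / settings@tr)
  if (nSamples < 1L)
    stop("zero-length post-burn-in window: duration ", duration,
         " s, burn-in ", settings@burnIn, " s, tr ", settings@tr, " s")
  bold <- boldForwardCpp(S, dt, hemo$kappa, hemo$gammaH, hemo$tauH,
                         hemo$alpha, hemo$rho, hemo$V0)
  idx <- round((settings@burnIn + seq_len(nSamples) * settings@tr) / dt) + 1L
  new("BOLDTimeseries", samples = bold[idx, , drop = FALSE],
      tr = settings@tr)
}

#' Functional connectivity of a simulated BOLD series
#'
#' Pearson correlation matrix of the regional time series, with unit
#' diagonal.
#'
#' @param bold a [BOLDTimeseries-class].
#' @param subjectID identifier carried on the result.
#' @return A [FunctionalConnectome-class].
#' @export
dmfFC <- function(bold, subjectID = "simulated") {
  stopifnot(is(bold, "BOLDTimeseries"))
  v <- apply(bold@samples, 2L, var)
  if (any(v == 0))
    stop("zero-variance BOLD series in region(s) ",
         paste(which(v == 0), collapse = ", "),
         ": correlation undefined")
  C <- cor(bold@samples)
  diag(C) <- 1
  C <- symmetrizeMatrix(C)
  FunctionalConnectome(C, subjectID = subjectID)
}

#' Fit the global coupling G of the mean-field model
#'
#' For every candidate G the model is simulated (same seed policy: each
#' subject reuses its own seed across the grid so the noise realisation is
#' held fixed), BOLD and simulated FC are computed, and the Pearson
#' correlation with the subject's empirical FC (off-diagonal upper triangle)
#' is recorded. The per-subject optimum is the argmax (ties toward smaller
#' G); the cohort optimum is the mode of the per-subject optima (ties toward
#' smaller G).
#'
#' @param scs list of [StructuralConnectome-class] (or a single one).
#' @param fcs list of [FunctionalConnectome-class] matching `scs`.
#' @param params a [DMFParameters-class]; its `G` slot is overridden by the
#'   grid.
#' @param settings a [SimulationSettings-class]; subject s uses seed
#'   `subSeed(settings@seed, paste0("dmf-subject-", s))`.
#' @param gGrid candidate couplings (default 13 values spanning \[0, 3\]).
#' @return List with `optimalG`, `perSubject` (data.frame subjectID, G,
#'   correlation) and `correlations` (subjects x grid matrix).
#' @export
dmfFitG <- function(scs, fcs, params = DMFParameters(),
                    settings = SimulationSettings(),
                    gGrid = seq(0, 3, by = 0.25)) {
  if (is(scs, "StructuralConnectome")) scs <- list(scs)
  if (is(fcs, "FunctionalConnectome")) fcs <- list(fcs)
  stopifnot(length(scs) == length(fcs), length(gGrid) >= 1L)
  p <- length(scs)
  cors <- matrix(NA_real_, nrow = p, ncol = length(gGrid))
  for (s in seq_len(p)) {
    subjSettings <- settings
    subjSettings@seed <- subSeed(settings@seed, paste0("dmf-subject-", s))
    target <- upperOffDiag(fcs[[s]]@values)
    for (g in seq_along(gGrid)) {
      pg <- params
      pg@G <- gGrid[g]
      S <- dmfIntegrate(scs[[s]], pg, subjSettings)
      bold <- boldForward(S, subjSettings)
      sim <- dmfFC(bold)
      cors[s, g] <- cor(upperOffDiag(sim@values), target)
    }
  }
  bestIdx <- apply(cors, 1L, which.max)  # first max = smaller G on ties
  perSubject <- data.frame(
    subjectID = vapply(scs, function(x) x@subjectID, character(1)),
    G = gGrid[bestIdx],
    correlation = cors[cbind(seq_len(p), bestIdx)])
  counts <- table(factor(perSubject$G, levels = gGrid))
  list(optimalG = gGrid[which.max(counts)], perSubject = perSubject,
       correlations = cors)
}
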