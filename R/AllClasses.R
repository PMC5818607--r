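#' @import methods
#' @importFrom stats cor rnorm rbinom rlnorm runif sd uniroot var
#' @importFrom utils read.table write.table modifyList
#' @useDynLib diffusionMKL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Structural connectome
## ---------------------------------------------------------------------------

#' StructuralConnectome: a subject's weighted anatomical graph
#'
#' An n x n symmetric, nonnegative weighted adjacency matrix over brain
#' regions (e.g. streamline counts between parcels of a cortical
#' parcellation), with a zero diagonal. The matrix is sanitised on
#' construction: symmetrised as (W + t(W))/2, diagonal zeroed, then
#' validated. Tractography matrices are near- but not exactly symmetric,
#' hence the symmetrise-then-check policy; asymmetry beyond `asymTol`
#' (relative to the largest weight) is an error rather than silently
#' averaged away.
#'
#' @slot weights numeric matrix, symmetric nonnegative, zero diagonal.
#' @slot regionLabels character vector of region identifiers, one per node.
#' @slot subjectID single string.
#' @slot metadata list of free-form annotations (e.g. the isolated-node flag
#'   set by [thresholdSC()]).
#' @export
setClass("StructuralConnectome",
  representation(weights = "matrix", regionLabels = "character",
                 subjectID = "character", metadata = "list"),
  prototype(metadata = list()))

setValidity("StructuralConnectome", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "weights must be a square numeric matrix")
  else {
    if (any(!is.finite(w))) msg <- c(msg, "weights contain non-finite values")
    if (max(abs(w - t(w))) > 1e-12)
      msg <- c(msg, "weights must be symmetric (tolerance 1e-12)")
    if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
    if (length(object@regionLabels) != nrow(w))
      msg <- c(msg, "regionLabels length must equal the matrix dimension")
  }
  if (length(object@subjectID) != 1L)
    msg <- c(msg, "subjectID must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a StructuralConnectome
#'
#' @param weights square numeric matrix of connection weights. Symmetrised as
#'   (W + t(W))/2 and its diagonal zeroed before validation.
#' @param regionLabels optional character vector of region names; defaults to
#'   `"R1" ... "Rn"`.
#' @param subjectID subject identifier string.
#' @param allowIsolated if `FALSE` (default) a node with zero degree is an
#'   error, since the normalized graph Laplacian is undefined there. Aggressive
#'   thresholding can legitimately isolate nodes, so [thresholdSC()] constructs
#'   with `allowIsolated = TRUE` and flags the result.
#' @param asymTol maximum tolerated relative asymmetry of the input before an
#'   error is raised (default `1e-6`).
#' @return A [StructuralConnectome-class] object.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' StructuralConnectome(w, subjectID = "toy")
#' @export
StructuralConnectome <- function(weights, regionLabels = NULL,
                                 subjectID = "subject",
                                 allowIsolated = FALSE, asymTol = 1e-6) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop("weights must be square, got ", nrow(weights), " x ", ncol(weights))
  if (any(!is.finite(weights)))
    stop("weights contain non-finite entries")
  scale <- max(abs(weights), 1e-300)
  asym <- max(abs(weights - t(weights))) / scale
  if (asym > asymTol)
    stop("input matrix is asymmetric beyond tolerance (relative asymmetry ",
         format(asym, digits = 3), ")")
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  if (any(w < 0)) stop("weights must be nonnegative")
  n <- nrow(w)
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(n))
  deg <- rowSums(w)
  isolated <- which(deg == 0)
  if (length(isolated) && !allowIsolated)
    stop("degenerate graph: isolated node(s) ",
         paste(isolated, collapse = ", "))
  dimnames(w) <- NULL
  md <- list()
  if (length(isolated)) md$isolatedNodes <- isolated
  new("StructuralConnectome", weights = w,
      regionLabels = as.character(regionLabels),
      subjectID = as.character(subjectID), metadata = md)
}

## ---------------------------------------------------------------------------
## Spectral decomposition of the graph Laplacian
## ---------------------------------------------------------------------------

#' SpectralDecomposition: eigenpairs of a graph Laplacian
#'
#' Holds the Laplacian of one subject's structural graph together with its
#' full eigendecomposition: orthonormal eigenvectors (columns, ascending
#' eigenvalue order, sign fixed so the largest-magnitude entry of each column
#' is positive) and nonnegative eigenvalues. The eigenvectors are the graph
#' harmonics on which all diffusion kernels are evaluated.
#'
#' @slot laplacian symmetric matrix L.
#' @slot eigenvectors orthonormal matrix Psi, columns ascending by eigenvalue.
#' @slot eigenvalues nonnegative vector Lambda, ascending.
#' @slot normalization `"symmetric_normalized"` or `"unnormalized"`.
#' @export
setClass("SpectralDecomposition",
  representation(laplacian = "matrix", eigenvectors = "matrix",
                 eigenvalues = "numeric", normalization = "character"))

setValidity("SpectralDecomposition", function(object) {
  msg <- character()
  L <- object@laplacian; V <- object@eigenvectors; lam <- object@eigenvalues
  n <- nrow(L)
  if (ncol(V) != n || nrow(V) != n || length(lam) != n)
    return("dimension mismatch between laplacian, eigenvectors, eigenvalues")
  if (is.unsorted(lam)) msg <- c(msg, "eigenvalues must be ascending")
  if (any(lam < -1e-8)) msg <- c(msg, "eigenvalues must be nonnegative")
  if (max(abs(crossprod(V) - diag(n))) > 1e-8)
    msg <- c(msg, "eigenvectors are not orthonormal within 1e-8")
  if (max(abs(V %*% (lam * t(V)) - L)) > 1e-8)
    msg <- c(msg, "eigendecomposition does not reconstruct the laplacian")
  if (!object@normalization %in% c("symmetric_normalized", "unnormalized"))
    msg <- c(msg, "unknown normalization")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Diffusion scales and kernel banks
## ---------------------------------------------------------------------------

#' ScaleSet: the diffusion scales gamma_1 < ... < gamma_m
#'
#' @slot scales strictly increasing positive numeric vector.
#' @export
setClass("ScaleSet", representation(scales = "numeric"))

setValidity("ScaleSet", function(object) {
  s <- object@scales
  if (length(s) < 1L) return("at least one scale required")
  if (any(!is.finite(s)) || any(s <= 0)) return("scales must be positive")
  if (any(diff(s) <= 0)) return("scales must be strictly increasing")
  TRUE
})

#' Construct a ScaleSet
#' @param scales strictly increasing positive numeric vector of diffusion
#'   scales.
#' @return A [ScaleSet-class] object.
#' @export
ScaleSet <- function(scales) new("ScaleSet", scales = as.numeric(scales))

#' DiffusionKernelBank: the m heat kernels of one subject
#'
#' Kernels H_i = Psi exp(-Lambda gamma_i) Psi' at each scale of a
#' [ScaleSet-class], plus their horizontal stacking `H = cbind(H_1, ..., H_m)`
#' (n x mn), the per-subject design block of the multiple-kernel model.
#'
#' @slot kernels list of m symmetric PSD n x n matrices.
#' @slot stacked n x mn matrix, column block i equals `kernels[[i]]`.
#' @slot scaleSet the [ScaleSet-class] the kernels were built at.
#' @slot subjectID single string.
#' @export
setClass("DiffusionKernelBank",
  representation(kernels = "list", stacked = "matrix", scaleSet = "ScaleSet",
                 subjectID = "character"))

setValidity("DiffusionKernelBank", function(object) {
  m <- length(object@scaleSet@scales)
  if (length(object@kernels) != m) return("kernel count != scale count")
  n <- nrow(object@kernels[[1L]])
  if (!identical(dim(object@stacked), c(n, n * m)))
    return("stacked must be n x mn")
  for (i in seq_len(m)) {
    K <- object@kernels[[i]]
    if (max(abs(K - t(K))) > 1e-10) return("kernel not symmetric within 1e-10")
    if (max(abs(object@stacked[, (i - 1L) * n + seq_len(n)] - K)) > 0)
      return("stacked block does not match kernel list")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Functional connectomes (empirical and predicted)
## ---------------------------------------------------------------------------

#' FunctionalConnectome: an empirical correlation matrix
#'
#' Pearson correlations between regional BOLD time series: symmetric, unit
#' diagonal, entries in \[-1, 1\].
#'
#' @slot values n x n correlation matrix.
#' @slot subjectID single string.
#' @export
setClass("FunctionalConnectome",
  representation(values = "matrix", subjectID = "character"))

setValidity("FunctionalConnectome", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) return("values must be square")
  if (any(!is.finite(v))) msg <- c(msg, "non-finite entries")
  if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "not symmetric within 1e-10")
  if (max(abs(diag(v) - 1)) > 1e-10) msg <- c(msg, "diagonal must be 1")
  if (max(abs(v)) > 1 + 1e-6) msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FunctionalConnectome
#' @param values square symmetric matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @param subjectID subject identifier string.
#' @return A [FunctionalConnectome-class] object.
#' @export
FunctionalConnectome <- function(values, subjectID = "subject") {
  dimnames(values) <- NULL
  new("FunctionalConnectome", values = values,
      subjectID = as.character(subjectID))
}

#' PredictedFC: a model-predicted functional connectivity matrix
#'
#' Unlike empirical FC this is not constrained to \[-1, 1\] or to a unit
#' diagonal: the forward model C_f = sum_i H_i pi_i is unbounded. When
#' `symmetrized` is `TRUE` the values have been averaged with their transpose.
#'
#' @slot values n x n numeric matrix.
#' @slot symmetrized logical flag.
#' @export
setClass("PredictedFC",
  representation(values = "matrix", symmetrized = "logical"))

setValidity("PredictedFC", function(object) {
  if (object@symmetrized &&
      max(abs(object@values - t(object@values))) > 1e-12)
    return("symmetrized flag set but values not symmetric within 1e-12")
  TRUE
})

## ---------------------------------------------------------------------------
## Learned co-activation parameters
## ---------------------------------------------------------------------------

#' CoactivationStack: the trained parameters Pi of the multiple-kernel model
#'
#' One n x n co-activation matrix pi_i per diffusion scale, stacked
#' vertically into the mn x n matrix Pi whose column j solves the column-wise
#' LASSO problem. These are the model's only trained parameters; they are
#' shared across subjects, while the kernels are subject-specific.
#'
#' @slot pis list of m n x n matrices, scale-ordered.
#' @slot stacked mn x n matrix; row block i equals `pis[[i]]`.
#' @slot scaleSet the [ScaleSet-class] the parameters correspond to.
#' @slot lambda nonnegative L1 penalty used in fitting.
#' @slot sparsity fraction of exactly-zero entries (recorded, not enforced).
#' @export
setClass("CoactivationStack",
  representation(pis = "list", stacked = "matrix", scaleSet = "ScaleSet",
                 lambda = "numeric", sparsity = "numeric"))

setValidity("CoactivationStack", function(object) {
  m <- length(object@scaleSet@scales)
  if (length(object@pis) != m) return("pi count != scale count")
  n <- ncol(object@pis[[1L]])
  if (!identical(dim(object@stacked), c(n * m, n)))
    return("stacked must be mn x n")
  for (i in seq_len(m)) {
    if (max(abs(object@stacked[(i - 1L) * n + seq_len(n), ] -
                object@pis[[i]])) > 0)
      return("stacked row block does not match pi list")
  }
  if (length(object@lambda) != 1L || object@lambda < 0)
    return("lambda must be a single nonnegative number")
  TRUE
})

#' Construct a CoactivationStack from a stacked mn x n matrix
#' @param stacked mn x n matrix (vertical stack of the m co-activation
#'   matrices).
#' @param scaleSet the [ScaleSet-class] giving m.
#' @param lambda L1 penalty associated with the parameters (0 if unknown).
#' @return A [CoactivationStack-class] object; sparsity is recorded from the
#'   zero pattern.
#' @export
CoactivationStack <- function(stacked, scaleSet, lambda = 0) {
  m <- length(scaleSet@scales)
  n <- ncol(stacked)
  stopifnot(nrow(stacked) == m * n)
  dimnames(stacked) <- NULL
  pis <- lapply(seq_len(m), function(i)
    stacked[(i - 1L) * n + seq_len(n), , drop = FALSE])
  new("CoactivationStack", pis = pis, stacked = stacked, scaleSet = scaleSet,
      lambda = as.numeric(lambda), sparsity = mean(stacked == 0))
}

## ---------------------------------------------------------------------------
## Cohorts
## ---------------------------------------------------------------------------

#' SCFCCohort: paired structural and functional connectomes
#'
#' The training/evaluation container: per subject a structural connectome,
#' its spectral decomposition, the kernel bank at a shared [ScaleSet-class],
#' and the empirical functional connectome. All subjects share n and the
#' scale set.
#'
#' @slot scs list of [StructuralConnectome-class].
#' @slot specs list of [SpectralDecomposition-class].
#' @slot banks list of [DiffusionKernelBank-class].
#' @slot fcs list of [FunctionalConnectome-class].
#' @slot scaleSet shared [ScaleSet-class].
#' @slot subjectIDs character vector.
#' @export
setClass("SCFCCohort",
  representation(scs = "list", specs = "list", banks = "list", fcs = "list",
                 scaleSet = "ScaleSet", subjectIDs = "character"))

setValidity("SCFCCohort", function(object) {
  p <- length(object@banks)
  if (length(object@fcs) != p || length(object@specs) != p ||
      length(object@scs) != p || length(object@subjectIDs) != p)
    return("per-subject lists must have equal length")
  if (p == 0L) return("cohort is empty")
  n <- nrow(object@fcs[[1L]]@values)
  for (s in seq_len(p)) {
    if (nrow(object@fcs[[s]]@values) != n ||
        nrow(object@banks[[s]]@kernels[[1L]]) != n)
      return("all subjects must share the same number of regions")
    if (!isTRUE(all.equal(object@banks[[s]]@scaleSet@scales,
                          object@scaleSet@scales)))
      return("all kernel banks must share the cohort scale set")
  }
  TRUE
})

#' Assemble an SCFCCohort from paired SC/FC lists
#'
#' Computes the Laplacian decomposition and kernel bank for every subject.
#'
#' @param scs list of [StructuralConnectome-class].
#' @param fcs list of [FunctionalConnectome-class], same order.
#' @param scaleSet shared [ScaleSet-class]; if `NULL`, the default scale set
#'   of the first subject at `m` scales is used.
#' @param m number of scales when `scaleSet` is `NULL`.
#' @param normalization Laplacian normalization passed to [buildLaplacian()].
#' @return An [SCFCCohort-class].
#' @export
SCFCCohort <- function(scs, fcs, scaleSet = NULL, m = 16L,
                       normalization = "symmetric_normalized") {
  stopifnot(length(scs) == length(fcs), length(scs) >= 1L)
  specs <- lapply(scs, buildLaplacian, normalization = normalization)
  if (is.null(scaleSet)) scaleSet <- defaultScaleSet(specs[[1L]], m = m)
  banks <- mapply(function(sp, sc) buildKernelBank(sp, scaleSet,
                                                   subjectID = sc@subjectID),
                  specs, scs, SIMPLIFY = FALSE)
  new("SCFCCohort", scs = scs, specs = specs, banks = banks, fcs = fcs,
      scaleSet = scaleSet,
      subjectIDs = vapply(scs, function(x) x@subjectID, character(1)))
}

## ---------------------------------------------------------------------------
## Baseline models and reports
## ---------------------------------------------------------------------------

#' SDKModel: the single-diffusion-kernel baseline
#'
#' One diffusion kernel at one cohort-level optimal scale is hypothesised as
#' FC. The optimal scale is the mode of per-subject best scales over a shared
#' sweep grid.
#'
#' @slot optimalScale positive scalar, an element of `scaleGrid`.
#' @slot scaleGrid increasing positive numeric vector swept.
#' @slot perSubjectBest data.frame with columns subjectID, scale, correlation.
#' @export
setClass("SDKModel",
  representation(optimalScale = "numeric", scaleGrid = "numeric",
                 perSubjectBest = "data.frame"))

setValidity("SDKModel", function(object) {
  if (!object@optimalScale %in% object@scaleGrid)
    return("optimalScale must be an element of scaleGrid")
  TRUE
})

#' EvaluationReport: per-subject prediction scores under a CV protocol
#'
#' @slot perSubject named numeric vector of Pearson correlations between
#'   predicted and empirical FC (off-diagonal upper triangle).
#' @slot meanCorrelation mean of `perSubject`.
#' @slot sdCorrelation standard deviation of `perSubject`.
#' @slot protocol one of `"holdout_half"`, `"loo"`, `"kfold"`.
#' @slot folds integer vector of fold assignments (named by subject), or
#'   length 0 when the protocol has no folds.
#' @slot seed integer seed the splits were derived from.
#' @export
setClass("EvaluationReport",
  representation(perSubject = "numeric", meanCorrelation = "numeric",
                 sdCorrelation = "numeric", protocol = "character",
                 folds = "integer", seed = "integer"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (abs(object@meanCorrelation - mean(object@perSubject)) > 1e-12)
    msg <- c(msg, "meanCorrelation inconsistent with perSubject")
  sdv <- if (length(object@perSubject) > 1L) sd(object@perSubject) else 0
  if (abs(object@sdCorrelation - sdv) > 1e-12)
    msg <- c(msg, "sdCorrelation inconsistent with perSubject")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Dynamic mean field model
## ---------------------------------------------------------------------------

#' DMFParameters: constants of the reduced dynamic mean field model
#'
#' Defaults follow the standard reduced single-population model: transfer
#' function gain `a` = 270 (nC^-1), offset `b` = 108 (Hz), shape `d` = 0.154
#' (s), kinetic rate `gammaKinetic` = 0.641, synaptic time constant `tauS` =
#' 0.1 (s), local recurrence `w` = 0.9, synaptic coupling `JN` = 0.2609 (nA),
#' external input `I0` = 0.3 (nA), noise amplitude `sigmaNoise` = 0.001 (nA).
#' The global coupling `G` (dimensionless, typically swept over \[0, 3\]) is
#' the one free parameter fitted per subject.
#'
#' @slot a,b,d,gammaKinetic,tauS,w,JN,I0,G,sigmaNoise numeric scalars, see
#'   description.
#' @export
setClass("DMFParameters",
  representation(a = "numeric", b = "numeric", d = "numeric",
                 gammaKinetic = "numeric", tauS = "numeric", w = "numeric",
                 JN = "numeric", I0 = "numeric", G = "numeric",
                 sigmaNoise = "numeric"))

setValidity("DMFParameters", function(object) {
  msg <- character()
  if (object@tauS <= 0) msg <- c(msg, "tauS must be positive")
  if (object@d <= 0) msg <- c(msg, "d must be positive")
  if (object@sigmaNoise < 0) msg <- c(msg, "sigmaNoise must be nonnegative")
  if (object@G < 0) msg <- c(msg, "G must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct DMFParameters
#' @param a,b,d transfer-function gain (nC^-1), offset (Hz) and shape (s).
#' @param gammaKinetic kinetic rate of the gating variable.
#' @param tauS synaptic time constant (s).
#' @param w local recurrent weight.
#' @param JN synaptic coupling (nA).
#' @param I0 external input current (nA).
#' @param G global coupling strength.
#' @param sigmaNoise noise amplitude (nA).
#' @return A [DMFParameters-class] object.
#' @export
DMFParameters <- function(a = 270, b = 108, d = 0.154, gammaKinetic = 0.641,
                          tauS = 0.1, w = 0.9, JN = 0.2609, I0 = 0.3,
                          G = 0, sigmaNoise = 0.001) {
  new("DMFParameters", a = a, b = b, d = d, gammaKinetic = gammaKinetic,
      tauS = tauS, w = w, JN = JN, I0 = I0, G = G, sigmaNoise = sigmaNoise)
}

#' SimulationSettings: integration and sampling controls for the simulator
#'
#' @slot dt Euler-Maruyama step (s).
#' @slot duration total simulated time (s).
#' @slot tr BOLD sampling interval (s).
#' @slot burnIn initial time discarded before sampling (s).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationSettings",
  representation(dt = "numeric", duration = "numeric", tr = "numeric",
                 burnIn = "numeric", seed = "integer"))

setValidity("SimulationSettings", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@duration <= object@burnIn)
    msg <- c(msg, "duration must exceed burnIn")
  if (object@tr < object@dt) msg <- c(msg, "tr must be >= dt")
  if (length(msg)) msg else TRUE
})

#' Construct SimulationSettings
#'
#' Defaults give an 8-minute post-burn-in window sampled every 2 s
#' (240 BOLD samples), integrated at 1 ms.
#'
#' @param dt integration step in seconds.
#' @param duration total simulated time in seconds (burn-in included).
#' @param tr BOLD sampling interval in seconds.
#' @param burnIn discarded initial time in seconds.
#' @param seed integer RNG seed.
#' @return A [SimulationSettings-class] object.
#' @export
SimulationSettings <- function(dt = 0.001, duration = 500, tr = 2,
                               burnIn = 20, seed = 1L) {
  new("SimulationSettings", dt = dt, duration = duration, tr = tr,
      burnIn = burnIn, seed = as.integer(seed))
}

#' BOLDTimeseries: sampled simulated BOLD signal
#'
#' @slot samples T x n matrix of BOLD samples (rows = time points).
#' @slot tr sampling interval (s).
#' @export
setClass("BOLDTimeseries",
  representation(samples = "matrix", tr = "numeric"))

setValidity("BOLDTimeseries", function(object) {
  if (any(!is.finite(object@samples))) return("non-finite BOLD samples")
  if (object@tr <= 0) return("tr must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic cohort specification
## ---------------------------------------------------------------------------

#' SyntheticCohortSpec: study conditions for a synthetic SC-FC cohort
#'
#' Describes a desk-scale cohort with known ground truth: a modular group
#' template graph with lognormal weights, per-subject multiplicative jitter,
#' a sparse ground-truth co-activation stack, and additive FC noise. The
#' defaults (n = 20 regions, p = 15 subjects, m = 4 scales, 4 modules,
#' within-module weights ~ lognormal(0, 0.5) at density 0.9, between-module
#' weights ~ lognormal(-2, 0.5) at density 0.3, jitter 0.5, Pi sparsity 0.05,
#' FC noise sd 0.01) emulate a small heavy-tailed modular connectome cohort.
#' The jitter sd matches the template weight spread (both lognormal sd 0.5):
#' inter-subject weight variability comparable to the within-graph weight
#' spread is what identifies scale-specific co-activations — with
#' near-identical subjects the stacked kernel design is rank-deficient.
#'
#' @slot n,p,m,moduleCount integer counts.
#' @slot intraWeight,interWeight length-2 numeric (meanlog, sdlog) of the
#'   lognormal edge-weight distributions.
#' @slot intraDensity,interDensity edge probabilities within/between modules.
#' @slot subjectJitter sd of the per-subject multiplicative lognormal weight
#'   jitter (0 = identical subjects).
#' @slot piSparsity fraction of nonzero entries in the ground-truth Pi.
#' @slot fcNoiseSD sd of the additive symmetric Gaussian FC noise.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticCohortSpec",
  representation(n = "integer", p = "integer", m = "integer",
                 moduleCount = "integer", intraWeight = "numeric",
                 interWeight = "numeric", intraDensity = "numeric",
                 interDensity = "numeric", subjectJitter = "numeric",
                 piSparsity = "numeric", fcNoiseSD = "numeric",
                 seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  msg <- character()
  if (object@n < 2L || object@p < 1L || object@m < 1L ||
      object@moduleCount < 1L)
    msg <- c(msg, "counts n, p, m, moduleCount must be >= 1 (n >= 2)")
  if (object@piSparsity <= 0 || object@piSparsity > 1)
    msg <- c(msg, "piSparsity must be in (0, 1]")
  if (object@fcNoiseSD < 0) msg <- c(msg, "fcNoiseSD must be nonnegative")
  if (object@subjectJitter < 0) msg <- c(msg, "subjectJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticCohortSpec
#' @param n regions per subject.
#' @param p subjects.
#' @param m diffusion scales.
#' @param moduleCount communities in the template graph.
#' @param intraWeight,interWeight c(meanlog, sdlog) of within/between module
#'   lognormal weights.
#' @param intraDensity,interDensity within/between module edge probabilities.
#' @param subjectJitter multiplicative lognormal jitter sd.
#' @param piSparsity fraction of nonzero ground-truth co-activations.
#' @param fcNoiseSD additive FC noise sd.
#' @param seed master RNG seed.
#' @return A [SyntheticCohortSpec-class] object.
#' @export
SyntheticCohortSpec <- function(n = 20L, p = 15L, m = 4L, moduleCount = 4L,
                                intraWeight = c(0, 0.5),
                                interWeight = c(-2, 0.5),
                                intraDensity = 0.9, interDensity = 0.3,
                                subjectJitter = 0.5, piSparsity = 0.05,
                                fcNoiseSD = 0.01, seed = 1L) {
  new("SyntheticCohortSpec", n = as.integer(n), p = as.integer(p),
      m = as.integer(m), moduleCount = as.integer(moduleCount),
      intraWeight = intraWeight, interWeight = interWeight,
      intraDensity = intraDensity, interDensity = interDensity,
      subjectJitter = subjectJitter, piSparsity = piSparsity,
      fcNoiseSD = fcNoiseSD, seed = as.integer(seed))
}
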