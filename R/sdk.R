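#' Single-kernel scale sweep for one subject
#'
#' Evaluates the Pearson correlation (off-diagonal upper triangle) between
#' the diffusion kernel H(gamma) and the subject's empirical FC at every grid
#' scale, and returns the maximiser. Ties are broken toward the smaller
#' scale.
#'
#' @param spec a [SpectralDecomposition-class].
#' @param fc a [FunctionalConnectome-class].
#' @param scaleGrid increasing positive numeric vector of candidate scales.
#' @return List with `bestScale`, `bestCorrelation` and the full
#'   `correlations` vector (named by scale).
#' @export
sdkScaleSweep <- function(spec, fc, scaleGrid) {
  stopifnot(is(spec, "SpectralDecomposition"),
            is(fc, "FunctionalConnectome"))
  if (length(scaleGrid) < 1L) stop("scale grid must be non-empty")
  if (any(scaleGrid <= 0) || any(diff(scaleGrid) <= 0))
    stop("scale grid must be increasing and positive")
  target <- upperOffDiag(fc@values)
  cors <- vapply(scaleGrid, function(g) {
    cor(upperOffDiag(diffusionKernel(spec, g)), target)
  }, numeric(1))
  best <- which.max(cors)  # first maximum = smallest scale on ties
  list(bestScale = scaleGrid[best], bestCorrelation = cors[best],
       correlations = stats::setNames(cors, scaleGrid))
}

#' Fit the single-diffusion-kernel baseline on a cohort
#'
#' Sweeps the grid for every subject and takes the cohort-level optimal scale
#' as the mode of the per-subject best scales (counted over the grid points
#' themselves, since all subjects share the grid); ties go to the smallest
#' scale.
#'
#' @param cohort an [SCFCCohort-class].
#' @param scaleGrid candidate scales; default is 50 log-spaced points
#'   spanning the cohort's default scale-set endpoints.
#' @return An [SDKModel-class].
#' @export
sdkFitCohort <- function(cohort, scaleGrid = NULL) {
  stopifnot(is(cohort, "SCFCCohort"), length(cohort) >= 1L)
  if (is.null(scaleGrid)) scaleGrid <- defaultSdkGrid(cohort@specs[[1L]])
  rows <- lapply(seq_len(length(cohort)), function(s) {
    sw <- sdkScaleSweep(cohort@specs[[s]], cohort@fcs[[s]], scaleGrid)
    data.frame(subjectID = cohort@subjectIDs[s], scale = sw$bestScale,
               correlation = sw$bestCorrelation)
  })
  best <- do.call(rbind, rows)
  counts <- table(factor(best$scale, levels = scaleGrid))
  optimal <- scaleGrid[which.max(counts)]  # first max = smallest scale
  new("SDKModel", optimalScale = optimal, scaleGrid = as.numeric(scaleGrid),
      perSubjectBest = best)
}

# Default sweep grid: 50 log-spaced points over the default scale-set span.
defaultSdkGrid <- function(spec, length.out = 50L) {
  ends <- range(defaultScaleSet(spec, m = 2L)@scales)
  exp(seq(log(ends[1L]), log(ends[2L]), length.out = length.out))
}

#' Predict FC under the single-kernel baseline
#'
#' The diffusion kernel at the fitted cohort-optimal scale is hypothesised as
#' the subject's FC.
#'
#' @param spec a [SpectralDecomposition-class] of the subject.
#' @param model a fitted [SDKModel-class].
#' @return A [PredictedFC-class] (symmetric PSD by construction).
#' @export
sdkPredict <- function(spec, model) {
  stopifnot(is(spec, "SpectralDecomposition"), is(model, "SDKModel"))
  new("PredictedFC", values = diffusionKernel(spec, model@optimalScale),
      symmetrized = TRUE)
}

#' Model factory for cross-validation: single-kernel baseline
#'
#' @param scaleGrid candidate scales forwarded to [sdkFitCohort()]; `NULL`
#'   for the default grid of the training cohort.
#' @return A function `train -> (subject -> PredictedFC)` for
#'   [crossValidate()].
#' @export
sdkModelFactory <- function(scaleGrid = NULL) {
  function(train) {
    model <- sdkFitCohort(train, scaleGrid = scaleGrid)
    function(subject) sdkPredict(subject$spec, model)
  }
}
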