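#' Accessors for diffusionMKL objects
#'
#' Small accessor family, preferred over direct slot access: `connMatrix()`
#' returns the numeric matrix of a structural, functional or predicted
#' connectome; `eigenvalues()`/`eigenvectors()`/`laplacianMatrix()` read a
#' spectral decomposition; `scales()`/`nScales()` read a scale set (or any
#' object carrying one); `kernelList()`/`stackedKernels()` read a kernel
#' bank; `piList()`/`stackedPi()`/`penaltyLambda()`/`piSparsity()` read a
#' fitted co-activation stack; `perSubjectCorrelation()`/`meanCorrelation()`
#' read an evaluation report.
#'
#' @param x the object.
#' @return The slot value indicated by the accessor name.
#' @name accessors
NULL

#' @rdname accessors
setMethod("connMatrix", "StructuralConnectome", function(x) x@weights)
#' @rdname accessors
setMethod("connMatrix", "FunctionalConnectome", function(x) x@values)
#' @rdname accessors
setMethod("connMatrix", "PredictedFC", function(x) x@values)

#' @rdname accessors
setMethod("regionLabels", "StructuralConnectome", function(x) x@regionLabels)

#' @rdname accessors
setMethod("subjectID", "StructuralConnectome", function(x) x@subjectID)
#' @rdname accessors
setMethod("subjectID", "FunctionalConnectome", function(x) x@subjectID)

#' @rdname accessors
setMethod("nRegions", "StructuralConnectome", function(x) nrow(x@weights))
#' @rdname accessors
setMethod("nRegions", "FunctionalConnectome", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nRegions", "SpectralDecomposition", function(x) nrow(x@laplacian))
#' @rdname accessors
setMethod("nRegions", "SCFCCohort", function(x) nrow(x@fcs[[1L]]@values))

#' @rdname accessors
setMethod("eigenvalues", "SpectralDecomposition", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("eigenvectors", "SpectralDecomposition", function(x) x@eigenvectors)
#' @rdname accessors
setMethod("laplacianMatrix", "SpectralDecomposition", function(x) x@laplacian)

#' @rdname accessors
setMethod("scales", "ScaleSet", function(x) x@scales)
#' @rdname accessors
setMethod("scales", "DiffusionKernelBank", function(x) x@scaleSet@scales)
#' @rdname accessors
setMethod("scales", "CoactivationStack", function(x) x@scaleSet@scales)
#' @rdname accessors
setMethod("scales", "SCFCCohort", function(x) x@scaleSet@scales)

#' @rdname accessors
setMethod("nScales", "ScaleSet", function(x) length(x@scales))
#' @rdname accessors
setMethod("nScales", "DiffusionKernelBank",
          function(x) length(x@scaleSet@scales))
#' @rdname accessors
setMethod("nScales", "CoactivationStack",
          function(x) length(x@scaleSet@scales))

#' @rdname accessors
setMethod("kernelList", "DiffusionKernelBank", function(x) x@kernels)
#' @rdname accessors
setMethod("stackedKernels", "DiffusionKernelBank", function(x) x@stacked)

#' @rdname accessors
setMethod("piList", "CoactivationStack", function(x) x@pis)
#' @rdname accessors
setMethod("stackedPi", "CoactivationStack", function(x) x@stacked)
#' @rdname accessors
setMethod("penaltyLambda", "CoactivationStack", function(x) x@lambda)
#' @rdname accessors
setMethod("piSparsity", "CoactivationStack", function(x) x@sparsity)

#' @rdname accessors
setMethod("perSubjectCorrelation", "EvaluationReport",
          function(x) x@perSubject)
#' @rdname accessors
setMethod("meanCorrelation", "EvaluationReport",
          function(x) x@meanCorrelation)

#' Number of subjects in a cohort
#' @param x an [SCFCCohort-class].
#' @return Integer subject count.
#' @export
setMethod("length", "SCFCCohort", function(x) length(x@banks))

#' Subset a cohort by subject index
#' @param x an [SCFCCohort-class].
#' @param i integer or logical index over subjects.
#' @param j,...,drop ignored.
#' @return The sub-cohort.
#' @export
setMethod("[", "SCFCCohort", function(x, i, j, ..., drop = FALSE) {
  new("SCFCCohort", scs = x@scs[i], specs = x@specs[i], banks = x@banks[i],
      fcs = x@fcs[i], scaleSet = x@scaleSet, subjectIDs = x@subjectIDs[i])
})

#' Extract one subject of a cohort as a plain list
#'
#' @param cohort an [SCFCCohort-class].
#' @param i subject index.
#' @return List with elements `sc`, `spec`, `bank`, `fc`, `id`.
#' @export
getSubject <- function(cohort, i) {
  list(sc = cohort@scs[[i]], spec = cohort@specs[[i]],
       bank = cohort@banks[[i]], fc = cohort@fcs[[i]],
       id = cohort@subjectIDs[[i]])
}

## show methods -------------------------------------------------------------

setMethod("show", "StructuralConnectome", function(object) {
  cat("StructuralConnectome", object@subjectID, ":", nrow(object@weights),
      "regions,", sum(object@weights[upper.tri(object@weights)] > 0),
      "edges\n")
  if (!is.null(object@metadata$isolatedNodes))
    cat("  isolated nodes:",
        paste(object@metadata$isolatedNodes, collapse = ", "), "\n")
})

setMethod("show", "FunctionalConnectome", function(object) {
  cat("FunctionalConnectome", object@subjectID, ":", nrow(object@values),
      "regions\n")
})

setMethod("show", "SpectralDecomposition", function(object) {
  lam <- object@eigenvalues
  cat("SpectralDecomposition (", object@normalization, "): ",
      length(lam), " modes, lambda in [", format(min(lam), digits = 4), ", ",
      format(max(lam), digits = 4), "]\n", sep = "")
})

setMethod("show", "ScaleSet", function(object) {
  cat("ScaleSet:", length(object@scales), "scales in [",
      format(min(object@scales), digits = 4), ",",
      format(max(object@scales), digits = 4), "]\n")
})

setMethod("show", "DiffusionKernelBank", function(object) {
  cat("DiffusionKernelBank", object@subjectID, ":",
      length(object@kernels), "kernels,",
      nrow(object@kernels[[1L]]), "regions\n")
})

setMethod("show", "CoactivationStack", function(object) {
  cat("CoactivationStack:", length(object@pis), "scales x",
      ncol(object@stacked), "regions; lambda =",
      format(object@lambda, digits = 4), "; sparsity =",
      format(object@sparsity, digits = 3), "\n")
})

setMethod("show", "SCFCCohort", function(object) {
  cat("SCFCCohort:", length(object@banks), "subjects,",
      nrow(object@fcs[[1L]]@values), "regions,",
      length(object@scaleSet@scales), "scales\n")
})

setMethod("show", "SDKModel", function(object) {
  cat("SDKModel: optimal scale", format(object@optimalScale, digits = 4),
      "over a grid of", length(object@scaleGrid), "scales\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@protocol, "): ",
      length(object@perSubject), " subjects, mean r = ",
      format(object@meanCorrelation, digits = 4), " (sd ",
      format(object@sdCorrelation, digits = 4), ")\n", sep = "")
})

setMethod("show", "DMFParameters", function(object) {
  cat("DMFParameters: G =", object@G, ", sigma =", object@sigmaNoise,
      ", tauS =", object@tauS, "s\n")
})

setMethod("show", "BOLDTimeseries", function(object) {
  cat("BOLDTimeseries:", nrow(object@samples), "samples x",
      ncol(object@samples), "regions at tr =", object@tr, "s\n")
})

setMethod("show", "SyntheticCohortSpec", function(object) {
  cat("SyntheticCohortSpec: n =", object@n, ", p =", object@p,
      ", m =", object@m, ", modules =", object@moduleCount,
      ", pi sparsity =", object@piSparsity,
      ", fc noise sd =", object@fcNoiseSD, "\n")
})
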