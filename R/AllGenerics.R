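#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname accessors
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @rdname accessors
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' @rdname accessors
#' @export
setGeneric("nScales", function(x) standardGeneric("nScales"))

#' @rdname accessors
#' @export
setGeneric("kernelList", function(x) standardGeneric("kernelList"))

#' @rdname accessors
#' @export
setGeneric("stackedKernels", function(x) standardGeneric("stackedKernels"))

#' @rdname accessors
#' @export
setGeneric("piList", function(x) standardGeneric("piList"))

#' @rdname accessors
#' @export
setGeneric("stackedPi", function(x) standardGeneric("stackedPi"))

#' @rdname accessors
#' @export
setGeneric("penaltyLambda", function(x) standardGeneric("penaltyLambda"))

#' @rdname accessors
#' @export
setGeneric("piSparsity", function(x) standardGeneric("piSparsity"))

#' @rdname accessors
#' @export
setGeneric("perSubjectCorrelation",
           function(x) standardGeneric("perSubjectCorrelation"))

#' @rdname accessors
#' @export
setGeneric("meanCorrelation", function(x) standardGeneric("meanCorrelation"))
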