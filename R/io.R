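#' Read a connectivity matrix from a delimited text file
#'
#' Parses a dense whitespace- or comma-delimited square matrix and validates
#' it as the requested type: structural matrices are symmetrized and checked
#' (nonnegative, zero diagonal, no isolated node unless `allowIsolated`);
#' functional matrices must be symmetric with unit diagonal and entries in
#' \[-1, 1\] (tolerance 1e-6). Format errors name the offending cell.
#'
#' @param path file path.
#' @param type `"sc"` or `"fc"`.
#' @param labels optional path to a sidecar file with one region label per
#'   line, or a character vector of labels.
#' @param subjectID identifier for the returned object (default: file name
#'   without extension).
#' @param allowIsolated forwarded to [StructuralConnectome()] for `"sc"`.
#' @return A [StructuralConnectome-class] or [FunctionalConnectome-class].
#' @export
readConnectome <- function(path, type = c("sc", "fc"), labels = NULL,
                           subjectID = NULL, allowIsolated = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("[,]", readLines(path, n = 1L))) "," else ""
  df <- read.table(path, header = FALSE, sep = sep,
                   colClasses = "numeric", comment.char = "#")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop("format error in ", path, ": matrix is ", nrow(m), " x ", ncol(m),
         ", expected square")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("format error in ", path, ": non-finite entry at row ",
         bad[1L, 1L], ", col ", bad[1L, 2L])
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- readLines(labels)
  if (!is.null(labels) && length(labels) != nrow(m))
    stop("label count (", length(labels), ") does not match matrix size (",
         nrow(m), ")")
  if (is.null(subjectID))
    subjectID <- sub("\\.[^.]*$", "", basename(path))
  if (type == "sc") {
    StructuralConnectome(m, regionLabels = labels, subjectID = subjectID,
                         allowIsolated = allowIsolated)
  } else {
    over <- which(abs(m) > 1 + 1e-6, arr.ind = TRUE)
    if (nrow(over))
      stop("format error in ", path, ": FC entry out of [-1, 1] at row ",
           over[1L, 1L], ", col ", over[1L, 2L], " (value ",
           format(m[over[1L, , drop = FALSE]], digits = 4), ")")
    if (max(abs(m - t(m))) > 1e-6)
      stop("format error in ", path, ": FC matrix is not symmetric")
    m <- symmetrizeMatrix(m)
    m[m > 1] <- 1; m[m < -1] <- -1
    if (max(abs(diag(m) - 1)) > 1e-6)
      stop("format error in ", path, ": FC diagonal must be 1")
    diag(m) <- 1
    FunctionalConnectome(m, subjectID = subjectID)
  }
}

#' Write a connectivity matrix as delimited text
#'
#' Values are written with 17 significant digits, so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param x a [StructuralConnectome-class], [FunctionalConnectome-class],
#'   [PredictedFC-class] or plain matrix.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(x, path, sep = "\t") {
  m <- if (is.matrix(x)) x else connMatrix(x)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a fitted model to a directory
#'
#' Writes `pi.tsv` (the stacked mn x n co-activation matrix at full
#' precision) and `meta.json` (scales, lambda, sparsity, n, m, optional
#' region labels and training-subject IDs).
#'
#' @param stack a [CoactivationStack-class].
#' @param dir output directory (created if missing).
#' @param regionLabels,trainingIDs optional metadata vectors.
#' @return `dir`, invisibly.
#' @export
writeMKLModel <- function(stack, dir, regionLabels = NULL,
                          trainingIDs = NULL) {
  stopifnot(is(stack, "CoactivationStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeConnectome(stack@stacked, file.path(dir, "pi.tsv"))
  meta <- list(scales = stack@scaleSet@scales, lambda = stack@lambda,
               sparsity = stack@sparsity, n = ncol(stack@stacked),
               m = length(stack@pis))
  if (!is.null(regionLabels)) meta$regionLabels <- regionLabels
  if (!is.null(trainingIDs)) meta$trainingIDs <- trainingIDs
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a serialized model directory
#'
#' @param dir directory written by [writeMKLModel()].
#' @return A [CoactivationStack-class]; region labels and training IDs, when
#'   present, are attached as attributes.
#' @export
readMKLModel <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  piPath <- file.path(dir, "pi.tsv")
  if (!file.exists(metaPath) || !file.exists(piPath))
    stop("not a model directory: ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  stacked <- as.matrix(read.table(piPath, header = FALSE))
  dimnames(stacked) <- NULL
  stack <- CoactivationStack(stacked, ScaleSet(meta$scales),
                             lambda = meta$lambda)
  if (!is.null(meta$regionLabels))
    attr(stack, "regionLabels") <- meta$regionLabels
  if (!is.null(meta$trainingIDs))
    attr(stack, "trainingIDs") <- meta$trainingIDs
  stack
}

#' Write an evaluation report as a delimited table
#'
#' One row per evaluated subject (subjectID, protocol, fold, correlation)
#' plus a summary row holding the mean and its standard deviation.
#'
#' @param report an [EvaluationReport-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  folds <- if (length(report@folds)) report@folds else
    rep(NA_integer_, length(report@perSubject))
  df <- data.frame(subjectID = names(report@perSubject),
                   protocol = report@protocol, fold = folds,
                   correlation = report@perSubject)
  df <- rbind(df, data.frame(subjectID = "MEAN", protocol = report@protocol,
                             fold = NA_integer_,
                             correlation = report@meanCorrelation))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
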