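#' Expression matrix accessor
#'
#' @param x a [MirExperiment-class] or a plain numeric matrix.
#' @return numeric matrix, miRNAs x samples.
#' @export
setGeneric("mirExprs", function(x) standardGeneric("mirExprs"))

#' @rdname mirExprs
setMethod("mirExprs", "MirExperiment",
          function(x) SummarizedExperiment::assay(x, "exprs"))
#' @rdname mirExprs
setMethod("mirExprs", "matrix", function(x) x)

#' Diagnostic group accessor
#'
#' @param x a [MirExperiment-class].
#' @return factor of group labels, one per sample, named by sample id.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
setMethod("sampleGroups", "MirExperiment", function(x) {
  g <- SummarizedExperiment::colData(x)$group
  g <- as.factor(g)
  names(g) <- colnames(x)
  g
})

#' Drug-class flag accessor
#'
#' @param x a [MirExperiment-class].
#' @return logical matrix, samples x available drug-class columns
#'   (\code{classA}..\code{classG}).
#' @export
setGeneric("drugFlags", function(x) standardGeneric("drugFlags"))

#' @rdname drugFlags
setMethod("drugFlags", "MirExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cols <- grep("^class[A-G]$", colnames(cd), value = TRUE)
  m <- as.matrix(as.data.frame(cd[, cols, drop = FALSE]))
  storage.mode(m) <- "logical"
  rownames(m) <- colnames(x)
  m
})

#' Mask of entries floored from negative raw readings
#'
#' @param x a [MirExperiment-class] processed by [floorNegatives()], or a
#'   matrix returned by it.
#' @return logical matrix marking entries that were below background.
#' @export
setGeneric("flooredMask", function(x) standardGeneric("flooredMask"))

#' @rdname flooredMask
setMethod("flooredMask", "MirExperiment", function(x) {
  if ("floored" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "floored")
  else
    matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
})
#' @rdname flooredMask
setMethod("flooredMask", "matrix", function(x) {
  fl <- attr(x, "floored")
  if (is.null(fl)) matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  else fl
})
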