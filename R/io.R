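#' Read a raw expression matrix from TSV
#'
#' The expected dialect is a tab-separated table whose first column holds
#' miRNA ids and whose header row holds sample ids. Negative entries are
#' permitted at this stage: bead-array software reports sub-background
#' signals as negative values, which are floored later by
#' [floorNegatives()].
#'
#' @param path path to a TSV file.
#' @return numeric matrix with miRNA rownames and sample colnames, in
#'   file order.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate miRNA id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  suppressWarnings(num <- vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop("non-numeric expression value at row '", ids[b[1L]],
         "', column '", colnames(body)[b[2L]], "'")
  }
  rownames(num) <- ids
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: first column \code{miRNA}, remaining
#' columns the samples.
#'
#' @param x numeric matrix or [MirExperiment-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(x, path) {
  m <- mirExprs(x)
  df <- data.frame(miRNA = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' CSV with columns \code{sample}, \code{group}, optionally
#' \code{classA}..\code{classG} (logical), \code{age}, \code{sex}.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
readSampleTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  for (cl in grep("^class[A-G]$", colnames(df), value = TRUE))
    df[[cl]] <- as.logical(df[[cl]])
  df
}

#' @rdname readSampleTable
#' @param x data.frame of sample metadata.
#' @export
writeSampleTable <- function(x, path) {
  write.csv(x, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Floor sub-background readings at zero
#'
#' Negative raw readings indicate expression below the assay background,
#' i.e. absence of signal; they are replaced by 0 and flagged so that
#' downstream normalization can exclude them from its statistics.
#' Idempotent: flooring an already-floored matrix changes nothing.
#'
#' @param x numeric matrix or [MirExperiment-class].
#' @return same shape as the input; for a matrix, the floored matrix with
#'   a logical \code{"floored"} attribute; for a MirExperiment, the
#'   object with assay \code{"exprs"} floored and a \code{"floored"}
#'   assay recording the mask.
#' @export
setGeneric("floorNegatives", function(x) standardGeneric("floorNegatives"))

#' @rdname floorNegatives
setMethod("floorNegatives", "matrix", function(x) {
  mask <- x < 0
  x[mask] <- 0
  prev <- attr(x, "floored")
  if (!is.null(prev)) mask <- mask | prev
  attr(x, "floored") <- mask
  x
})

#' @rdname floorNegatives
setMethod("floorNegatives", "MirExperiment", function(x) {
  m <- floorNegatives(mirExprs(x))
  mask <- attr(m, "floored")
  attr(m, "floored") <- NULL
  SummarizedExperiment::assay(x, "exprs") <- m
  SummarizedExperiment::assay(x, "floored") <- mask
  x
})

#' Drop uninformative miRNAs
#'
#' Retains miRNAs expressed (> 0) in at least \code{minExpressedSamples}
#' samples and with nonzero variance across samples, preserving row
#' order. The published 312-to-198 narrowing rule of the study this
#' mirrors was not disclosed, so the filter is an explicit parameterized
#' stand-in rather than a reconstruction.
#'
#' @param x numeric matrix or [MirExperiment-class] (floored).
#' @param minExpressedSamples minimum number of samples with positive
#'   expression; must not exceed the sample count.
#' @return filtered object of the same class; the number of removed rows
#'   is reported via \code{message()}.
#' @export
setGeneric("filterInformative",
           function(x, minExpressedSamples = 3L)
             standardGeneric("filterInformative"))

#' @rdname filterInformative
setMethod("filterInformative", "matrix", function(x, minExpressedSamples = 3L) {
  if (minExpressedSamples < 1L)
    stop("minExpressedSamples must be >= 1")
  if (minExpressedSamples > ncol(x))
    stop("minExpressedSamples (", minExpressedSamples,
         ") exceeds the sample count (", ncol(x), ")")
  nPos <- rowSums(x > 0)
  vr <- apply(x, 1L, var)
  keep <- nPos >= minExpressedSamples & vr > 0
  message(sum(!keep), " uninformative miRNA(s) removed, ",
          sum(keep), " retained")
  out <- x[keep, , drop = FALSE]
  fl <- attr(x, "floored")
  if (!is.null(fl)) attr(out, "floored") <- fl[keep, , drop = FALSE]
  out
})

#' @rdname filterInformative
setMethod("filterInformative", "MirExperiment",
          function(x, minExpressedSamples = 3L) {
  m <- mirExprs(x)
  if (minExpressedSamples > ncol(m))
    stop("minExpressedSamples (", minExpressedSamples,
         ") exceeds the sample count (", ncol(m), ")")
  nPos <- rowSums(m > 0)
  vr <- apply(m, 1L, var)
  keep <- nPos >= minExpressedSamples & vr > 0
  message(sum(!keep), " uninformative miRNA(s) removed, ",
          sum(keep), " retained")
  x[keep, ]
})

#' Median-of-positives sample normalization
#'
#' Each sample (column) is rescaled so that the median of its positive
#' entries equals the global median of per-sample positive medians.
#' Zeros encode "below background", not abundance, so they are excluded
#' from the statistics and stay exactly zero. The operation is
#' idempotent and removes per-sample scalar scale factors.
#'
#' @param x nonnegative numeric matrix or [MirExperiment-class].
#' @return normalized object of the same class.
#' @export
setGeneric("normalizeSamples", function(x) standardGeneric("normalizeSamples"))

#' @rdname normalizeSamples
setMethod("normalizeSamples", "matrix", function(x) {
  allZero <- colSums(x > 0) == 0
  if (any(allZero))
    stop("sample(s) with no positive expression: ",
         paste(colnames(x)[allZero], collapse = ", "))
  med <- apply(x, 2L, function(v) median(v[v > 0]))
  target <- median(med)
  out <- sweep(x, 2L, target / med, `*`)
  attr(out, "floored") <- attr(x, "floored")
  out
})

#' @rdname normalizeSamples
setMethod("normalizeSamples", "MirExperiment", function(x) {
  SummarizedExperiment::assay(x, "exprs") <-
    normalizeSamples(mirExprs(x))
  x
})

#' Cube-root transform
#'
#' Entrywise x^(1/3) of a nonnegative matrix; 0 maps to 0 and ordering is
#' preserved. This is the variance-taming transform used before
#' correlation clustering of sample profiles.
#'
#' @param x nonnegative numeric matrix or [MirExperiment-class].
#' @return transformed object of the same class as the input matrix.
#' @export
setGeneric("cubeRoot", function(x) standardGeneric("cubeRoot"))

#' @rdname cubeRoot
setMethod("cubeRoot", "matrix", function(x) {
  if (any(x < 0)) stop("cubeRoot expects a nonnegative (floored) matrix")
  x^(1 / 3)
})

#' @rdname cubeRoot
setMethod("cubeRoot", "MirExperiment", function(x) cubeRoot(mirExprs(x)))
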