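#' @import methods
#' @importFrom stats cor median sd quantile pnorm t.test var setNames
#' @importFrom stats rnorm runif aggregate
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay "assay<-" assayNames colData
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom utils combn read.delim write.table read.csv write.csv
NULL

#' MirExperiment: miRNA expression with sample metadata
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding a miRNA-by-sample expression matrix (assay \code{"exprs"}) with
#' per-sample clinical annotation in \code{colData}: the diagnostic group
#' and, optionally, the seven medication drug-class flags (\code{classA}
#' ... \code{classG}), age and sex. After background flooring a logical
#' assay \code{"floored"} marks entries that were reported below background
#' (negative raw readings) and set to zero.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso [MirExperiment()] for construction, [floorNegatives()],
#'   [normalizeSamples()], [filterInformative()].
#' @export
setClass("MirExperiment", contains = "SummarizedExperiment")

.validMirExperiment <- function(object) {
  msg <- NULL
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(cd$group))
    msg <- c(msg, "'group' may not contain NA")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "miRNA ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("MirExperiment", .validMirExperiment)

#' Construct a MirExperiment
#'
#' @param values numeric matrix, miRNAs in rows (unique rownames), samples
#'   in columns (unique colnames). Negative entries are allowed before
#'   [floorNegatives()] has been applied.
#' @param sampleData data.frame of per-sample metadata, one row per column
#'   of \code{values}; must contain \code{group} and may contain drug-class
#'   flags \code{classA}..\code{classG}, \code{age} and \code{sex}. Row
#'   order is matched to columns by the \code{sample} column if present,
#'   otherwise by rownames, otherwise by position.
#' @return a [MirExperiment-class] object.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("mir-", 1:3), paste0("S", 1:4)))
#' md <- data.frame(sample = paste0("S", 1:4),
#'                  group = c("C", "C", "SZ", "SZ"))
#' me <- MirExperiment(m, md)
#' @export
MirExperiment <- function(values, sampleData) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have miRNA rownames and sample colnames")
  sampleData <- as.data.frame(sampleData)
  if ("sample" %in% colnames(sampleData)) {
    rownames(sampleData) <- sampleData$sample
    sampleData$sample <- NULL
  }
  if (!is.null(rownames(sampleData)) &&
      all(colnames(values) %in% rownames(sampleData))) {
    sampleData <- sampleData[colnames(values), , drop = FALSE]
  } else if (nrow(sampleData) == ncol(values)) {
    rownames(sampleData) <- colnames(values)
  } else {
    stop("sampleData does not match the expression columns")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(sampleData))
  new("MirExperiment", se)
}

#' SamResult: moderated multiclass score table
#'
#' Per-miRNA output of the permutation score engine: one standardized
#' score per diagnostic group, the pooled per-miRNA scale, the shared
#' exchangeability constant s0, the scalar ranking statistic
#' D = max over groups of |z|, and (once a permutation null has been
#' attached) permutation q-values and windowed local false discovery
#' rates, both in percent.
#'
#' @slot z numeric matrix, miRNAs x groups, standardized group scores.
#' @slot s numeric, per-miRNA pooled scale.
#' @slot s0 numeric(1), exchangeability constant added to every scale.
#' @slot D numeric, ranking statistic max_k |z_ik|.
#' @slot groupSizes named integer, samples per group.
#' @slot qvalue numeric, permutation q-values in percent (NA before
#'   [samQvalues()]).
#' @slot localFdr numeric, windowed local FDR in percent (NA before
#'   [samLocalFdr()]).
#' @export
setClass("SamResult", representation(
  z = "matrix", s = "numeric", s0 = "numeric", D = "numeric",
  groupSizes = "integer", qvalue = "numeric", localFdr = "numeric"))

.validSamResult <- function(object) {
  msg <- NULL
  m <- nrow(object@z)
  if (length(object@s) != m || length(object@D) != m)
    msg <- c(msg, "score slots must have one entry per miRNA")
  if (length(object@s0) != 1L || object@s0 < 0)
    msg <- c(msg, "s0 must be a single nonnegative number")
  if (ncol(object@z) != length(object@groupSizes))
    msg <- c(msg, "one z column per group is required")
  if (is.null(msg)) TRUE else msg
}
setValidity("SamResult", .validSamResult)

#' PermutationNull: label-permutation reference distribution
#'
#' Holds the ranking statistic recomputed under B group-label
#' permutations that preserve the group sizes, with the s0 of the
#' observed fit. When the design admits no more than \code{enumerateMax}
#' distinct label assignments the permutations are enumerated completely
#' instead of sampled.
#'
#' @slot nullD numeric matrix, B x miRNAs, permuted ranking statistics.
#' @slot nullZ list of per-group permuted score matrices (B x miRNAs),
#'   one element per group, used for score-scale tail probabilities.
#' @slot B integer(1), number of permutations.
#' @slot seed integer(1), RNG seed used when sampling permutations.
#' @slot enumerated logical(1), TRUE when all distinct assignments were
#'   enumerated.
#' @export
setClass("PermutationNull", representation(
  nullD = "matrix", nullZ = "list", B = "integer", seed = "integer",
  enumerated = "logical"))

#' MirDendrogram: centroid-correlation sample dendrogram
#'
#' Binary merge tree over samples built by greedy agglomeration under the
#' distance 2*(1-cc), where cc is the Pearson correlation (clamped below
#' at zero) between cube-root expression profiles and cluster average
#' profiles; all merge heights therefore lie in [0, 2].
#'
#' @slot merge integer matrix, (n-1) x 2, hclust merge convention
#'   (negative entries are leaves, positive entries earlier merges).
#' @slot height numeric, merge heights, non-decreasing.
#' @slot labels character, leaf (sample) ids.
#' @slot order integer, leaf ordering for plotting.
#' @export
setClass("MirDendrogram", representation(
  merge = "matrix", height = "numeric", labels = "character",
  order = "integer"))

.validMirDendrogram <- function(object) {
  msg <- NULL
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "a dendrogram over n leaves must have exactly n-1 merges")
  if (is.unsorted(object@height))
    msg <- c(msg, "merge heights must be non-decreasing")
  if (any(object@height < 0 | object@height > 2 + 1e-12))
    msg <- c(msg, "merge heights must lie in [0, 2]")
  if (is.null(msg)) TRUE else msg
}
setValidity("MirDendrogram", .validMirDendrogram)

#' NscFit: nearest shrunken centroid model
#'
#' Class centroids standardized against the overall centroid,
#' soft-thresholded towards it over a grid of shrinkage thresholds.
#'
#' @slot overall numeric, overall centroid per miRNA.
#' @slot classCentroids numeric matrix, miRNAs x classes.
#' @slot s numeric, pooled within-class standard deviation per miRNA.
#' @slot s0 numeric(1), offset added to every scale (median of s).
#' @slot mk numeric, per-class factor sqrt(1/n_k - 1/N).
#' @slot dik numeric matrix, standardized centroid differences.
#' @slot deltaGrid numeric, shrinkage thresholds.
#' @slot classCounts named integer, training samples per class.
#' @slot priors named numeric, class priors used by the discriminant.
#' @export
setClass("NscFit", representation(
  overall = "numeric", classCentroids = "matrix", s = "numeric",
  s0 = "numeric", mk = "numeric", dik = "matrix", deltaGrid = "numeric",
  classCounts = "integer", priors = "numeric"))

#' DrugClassDesign: taker / non-taker partitions per drug class
#'
#' For each medication class, the case subjects (controls are never
#' takers) inside the analysis cohort split into takers and non-takers,
#' restricted to the diagnostic groups the class is prescribed in, and an
#' eligibility flag: a class can be used as a covariate only when both
#' arms contain at least \code{minPerArm} (default 3) case subjects.
#'
#' @slot takers named list of character vectors, sample ids per class.
#' @slot nonTakers named list of character vectors, sample ids per class.
#' @slot eligible named logical, one flag per class.
#' @slot minPerArm integer(1), arm-size threshold used.
#' @export
setClass("DrugClassDesign", representation(
  takers = "list", nonTakers = "list", eligible = "logical",
  minPerArm = "integer"))

setMethod("show", "SamResult", function(object) {
  cat("SamResult:", nrow(object@z), "miRNAs,",
      ncol(object@z), "groups (", paste(colnames(object@z), collapse = ", "),
      ")\n  s0 =", format(object@s0, digits = 4))
  if (!all(is.na(object@qvalue)))
    cat(";", sum(object@qvalue == 0), "miRNAs at q = 0%")
  cat("\n")
})

setMethod("show", "MirDendrogram", function(object) {
  cat("MirDendrogram over", length(object@labels), "samples; heights in [",
      format(min(object@height), digits = 3), ",",
      format(max(object@height), digits = 3), "]\n")
})

setMethod("show", "NscFit", function(object) {
  cat("NscFit:", nrow(object@classCentroids), "miRNAs,",
      ncol(object@classCentroids), "classes; s0 =",
      format(object@s0, digits = 4), "\n  delta grid of length",
      length(object@deltaGrid), "\n")
})

setMethod("show", "DrugClassDesign", function(object) {
  el <- names(object@eligible)[object@eligible]
  cat("DrugClassDesign:", length(object@eligible), "classes;",
      "eligible:", if (length(el)) paste(el, collapse = ", ") else "none",
      "\n")
})

setMethod("show", "PermutationNull", function(object) {
  cat("PermutationNull:", object@B, "permutations x",
      ncol(object@nullD), "miRNAs",
      if (object@enumerated) "(full enumeration)" else "(sampled)", "\n")
})
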