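# Accessors for the packaged study tables: the published ranked score
# tables, covariate-effect ledger, adjusted-score reports and the
# 20-sample bead-array cohort metadata, transcribed to plain text.

#' Path to a packaged data file
#'
#' @param file file name under the package's \code{extdata}.
#' @return absolute path.
#' @export
exomirData <- function(file) {
  p <- system.file("extdata", file, package = "exomiR", mustWork = TRUE)
  p
}

#' Packaged study tables
#'
#' Loaders for the published result tables shipped with the package:
#' \describe{
#'   \item{\code{samTableThreeGroup()}}{the 198-row three-group ranked
#'     score table (z-scores for C, BD, SZ; q-value and local FDR in
#'     percent).}
#'   \item{\code{samTableBdControl()}}{the 51-row BD-versus-control
#'     ranked table (q-value and local FDR only).}
#'   \item{\code{covariateEffectsTable()}}{per-miRNA covariate-effect
#'     scores for drug classes A, B, C (blanks are NA).}
#'   \item{\code{adjustedTableSz()}}{the top-21 SZ scores adjusted for
#'     classes A, B, C and B+C, with p-values.}
#'   \item{\code{adjustedTableBd()}}{the BD counterpart (transcribed
#'     verbatim; several of its printed columns are internally
#'     misaligned, so it is shipped for reference rather than
#'     arithmetic checks).}
#'   \item{\code{luminexCohort()}}{metadata of the 20 bead-array
#'     samples: group, drug-class flags A-G, age, sex.}
#' }
#'
#' @return data.frame (see each description).
#' @examples
#' nrow(samTableThreeGroup())   # 198
#' head(qZero(samTableThreeGroup()))
#' @name studyTables
NULL

#' @rdname studyTables
#' @export
samTableThreeGroup <- function() {
  readRankTable(exomirData("sam_scores_three_group.tsv"))
}

#' @rdname studyTables
#' @export
samTableBdControl <- function() {
  readRankTable(exomirData("sam_scores_bd_vs_control.tsv"))
}

#' @rdname studyTables
#' @export
covariateEffectsTable <- function() {
  readCovariateEffects(exomirData("covariate_effects_abc.tsv"))
}

#' @rdname studyTables
#' @export
adjustedTableSz <- function() {
  read.delim(exomirData("adjusted_scores_sz.tsv"), check.names = FALSE)
}

#' @rdname studyTables
#' @export
adjustedTableBd <- function() {
  read.delim(exomirData("adjusted_scores_bd.tsv"), check.names = FALSE)
}

#' @rdname studyTables
#' @export
luminexCohort <- function() {
  readSampleTable(exomirData("luminex_metadata.csv"))
}
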