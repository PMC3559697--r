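# Medication drug-class covariate procedure: eligibility, per-class
# covariate-effect scores, and adjustment of disease z-scores by
# subtraction.

#' Diagnostic groups each drug class is prescribed in
#'
#' Default scoping of the seven medication classes: A (antipsychotics
#' for SZ) applies to SZ only; B (neurotransmitter receptor-site
#' binders) and C (sedatives / hypnotics / anticonvulsants /
#' analgesics) apply to both BD and SZ; D (mood stabilizers for BD), E
#' (psycho-stimulants) and F (serotonin and adrenergic antagonists)
#' apply to BD only; G (serotonin antagonist) to SZ only. Eligibility
#' of a class as a covariate is judged among case subjects of these
#' groups only — a class prescribed only in BD cannot be evaluated
#' against SZ subjects who would never receive it.
#'
#' @return named list, class letter -> character vector of group labels.
#' @export
drugClassGroups <- function() {
  list(A = "SZ", B = c("BD", "SZ"), C = c("BD", "SZ"),
       D = "BD", E = "BD", F = "BD", G = "SZ")
}

#' Load a drug-class configuration from YAML
#'
#' The YAML maps class letters to a description and the diagnostic
#' groups the class is prescribed in; see
#' \code{system.file("extdata", "drug_classes.yaml", package = "exomiR")}
#' for the packaged default.
#'
#' @param path YAML file path.
#' @return named list, class letter -> list(description, groups).
#' @export
readDrugClasses <- function(path) {
  yaml::read_yaml(path)
}

#' Determine drug classes eligible as covariates
#'
#' Splits the case subjects (controls are never medication takers) of
#' the analysis cohort into takers and non-takers per drug class,
#' restricted to the diagnostic groups the class is prescribed in, and
#' flags a class eligible when both arms hold at least
#' \code{minPerArm} subjects — a standard error over fewer than three
#' subjects per arm is not usable.
#'
#' @param samples data.frame of sample metadata (columns \code{sample},
#'   \code{group}, \code{classA}..\code{classG}) or a
#'   [MirExperiment-class].
#' @param cohort sample ids actually analyzed (default: all samples in
#'   \code{samples}).
#' @param classes drug-class letters to evaluate (default A-G).
#' @param applicability named list, class letter -> group labels the
#'   class applies to; defaults to [drugClassGroups()]. A class letter
#'   missing from the list applies to all case groups.
#' @param minPerArm minimum subjects per arm (default 3).
#' @param controlGroup label of the control group (default \code{"C"}).
#' @return a [DrugClassDesign-class].
#' @examples
#' md <- readSampleTable(system.file("extdata", "luminex_metadata.csv",
#'                                   package = "exomiR"))
#' design <- eligibleClasses(md)
#' design
#' @export
eligibleClasses <- function(samples, cohort = NULL,
                            classes = LETTERS[1:7],
                            applicability = drugClassGroups(),
                            minPerArm = 3L, controlGroup = "C") {
  if (is(samples, "MirExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(samples))
    cd$sample <- colnames(samples)
    samples <- cd
  }
  if (is.null(cohort)) cohort <- samples$sample
  unknownCohort <- setdiff(cohort, samples$sample)
  if (length(unknownCohort))
    stop("cohort contains unknown sample(s): ",
         paste(unknownCohort, collapse = ", "))
  badClass <- setdiff(classes, LETTERS[1:7])
  if (length(badClass))
    stop("unknown drug class letter(s): ", paste(badClass, collapse = ", "))
  sub <- samples[samples$sample %in% cohort, , drop = FALSE]
  takers <- nonTakers <- setNames(vector("list", length(classes)), classes)
  eligible <- setNames(logical(length(classes)), classes)
  for (cl in classes) {
    col <- paste0("class", cl)
    if (!col %in% colnames(sub))
      stop("metadata lacks column ", col)
    appl <- applicability[[cl]]
    inScope <- sub$group != controlGroup &
      (if (is.null(appl)) TRUE else sub$group %in% appl)
    takers[[cl]] <- sub$sample[inScope & sub[[col]]]
    nonTakers[[cl]] <- sub$sample[inScope & !sub[[col]]]
    eligible[cl] <- length(takers[[cl]]) >= minPerArm &&
      length(nonTakers[[cl]]) >= minPerArm
  }
  new("DrugClassDesign", takers = takers, nonTakers = nonTakers,
      eligible = eligible, minPerArm = as.integer(minPerArm))
}

#' Per-miRNA covariate-effect scores for a drug class
#'
#' Reruns the moderated two-class score comparing case subjects taking a
#' drug-class medication against case subjects not taking it; the
#' returned effect is the taker-group score under the same s0 convention
#' as the disease analysis.
#'
#' @param x expression matrix or [MirExperiment-class] (floored).
#' @param design a [DrugClassDesign-class] from [eligibleClasses()].
#' @param classId drug-class letter; must be eligible.
#' @param s0 exchangeability constant; computed on the taker/non-taker
#'   design via [computeS0()] when NULL.
#' @return named numeric vector of effect scores, one per miRNA.
#' @export
covariateEffect <- function(x, design, classId, s0 = NULL) {
  stopifnot(is(design, "DrugClassDesign"))
  if (!classId %in% names(design@eligible))
    stop("unknown drug class: ", classId)
  if (!design@eligible[[classId]])
    stop("drug class ", classId, " is not eligible (needs at least ",
         design@minPerArm, " takers and ", design@minPerArm,
         " non-takers)")
  m <- mirExprs(x)
  tk <- design@takers[[classId]]
  nt <- design@nonTakers[[classId]]
  sub <- m[, c(tk, nt), drop = FALSE]
  lab <- factor(rep(c("taker", "nonTaker"), c(length(tk), length(nt))),
                levels = c("nonTaker", "taker"))
  if (is.null(s0)) s0 <- computeS0(sub, lab)
  sam <- groupZScores(sub, lab, s0 = s0)
  setNames(sam@z[, "taker"], rownames(sub))
}

#' Subtract covariate effects from disease z-scores
#'
#' Adjusted score = original score minus the sum of the requested
#' classes' effects, in exact arithmetic. A missing (blank) effect
#' contributes zero, so a miRNA with no computed effect keeps its
#' original score.
#'
#' @param z named numeric vector of original scores.
#' @param effects data.frame or matrix of per-class effect scores with
#'   miRNA ids as rownames (or a \code{miRNA} column) and one column per
#'   class; NA cells are blanks. A named list of vectors from
#'   [covariateEffect()] is also accepted.
#' @param classes character vector of class letters to adjust for.
#' @return named numeric vector of adjusted scores, same order as
#'   \code{z}.
#' @examples
#' adjustScores(c(`hsa-miR-33` = 3.10046),
#'              data.frame(row.names = "hsa-miR-33", A = 0.6342707),
#'              classes = "A")
#' @export
adjustScores <- function(z, effects, classes) {
  if (is.list(effects) && !is.data.frame(effects))
    effects <- as.data.frame(effects, optional = TRUE)
  effects <- as.data.frame(effects)
  if ("miRNA" %in% colnames(effects)) {
    rownames(effects) <- effects$miRNA
    effects$miRNA <- NULL
  }
  adj <- z
  for (cl in classes) {
    if (!cl %in% colnames(effects)) {
      message("no effects for class ", cl, "; treated as 0")
      next
    }
    e <- effects[names(z), cl]
    e[is.na(e)] <- 0
    adj <- adj - e
  }
  adj
}

#' Permutation tail probability of an adjusted score
#'
#' Two-sided tail probability of |z| under a permutation null of the
#' same statistic, with add-one smoothing so p is never below
#' 1/(B + 1).
#'
#' @param zAdj numeric vector of (adjusted) scores.
#' @param nullValues numeric vector or matrix of null statistics (e.g. a
#'   per-group slice of a [PermutationNull-class]'s \code{nullZ}).
#' @return numeric vector of p-values in [1/(B+1), 1].
#' @export
adjustedPvalue <- function(zAdj, nullValues) {
  nv <- abs(as.vector(as.matrix(nullValues)))
  B <- length(nv)
  vapply(abs(zAdj), function(a) (1 + sum(nv >= a)) / (B + 1), numeric(1L))
}

#' Assemble an adjusted-score report
#'
#' Produces the wide per-miRNA report used for the medication covariate
#' analysis: the original disease score with its permutation p-value,
#' then for each requested class (and for the combination of all
#' requested classes) the adjusted score and its p-value.
#'
#' @param z named numeric vector of original scores.
#' @param effects per-class effect table (see [adjustScores()]).
#' @param classes class letters adjusted for individually.
#' @param nullValues null statistics for [adjustedPvalue()]; when NULL
#'   no p-value columns are produced.
#' @param combine classes whose effects are additionally subtracted
#'   jointly (default: all of \code{classes} with more than one entry).
#' @return data.frame, one row per miRNA.
#' @export
adjustedTable <- function(z, effects, classes, nullValues = NULL,
                          combine = NULL) {
  out <- data.frame(miRNA = names(z), score = unname(z),
                    stringsAsFactors = FALSE)
  if (!is.null(nullValues)) out$p <- adjustedPvalue(z, nullValues)
  for (cl in classes) {
    a <- adjustScores(z, effects, cl)
    out[[paste0("adj", cl)]] <- unname(a)
    if (!is.null(nullValues))
      out[[paste0("p", cl)]] <- adjustedPvalue(a, nullValues)
  }
  if (is.null(combine) && length(classes) > 1L) combine <- classes
  if (!is.null(combine) && length(combine) > 1L) {
    a <- adjustScores(z, effects, combine)
    nm <- paste(combine, collapse = "")
    out[[paste0("adj", nm)]] <- unname(a)
    if (!is.null(nullValues))
      out[[paste0("p", nm)]] <- adjustedPvalue(a, nullValues)
  }
  out
}

#' Read a per-class covariate-effect table
#'
#' TSV with a \code{miRNA} column and one column per class
#' (\code{classA}, \code{classB}, ... or bare letters); empty cells are
#' blanks (NA), meaning "no effect computed".
#'
#' @param path TSV file path.
#' @return data.frame with miRNA rownames and one numeric column per
#'   class letter.
#' @export
readCovariateEffects <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   na.strings = c("NA", ""))
  rownames(df) <- df$miRNA
  df$miRNA <- NULL
  colnames(df) <- sub("^class", "", colnames(df))
  df
}
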