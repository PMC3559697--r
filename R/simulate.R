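# Synthetic bead-array study generator. A single global seed governs all
# sub-generators; each stage derives its own stream from the seed plus a
# fixed offset so adding a stage never perturbs the others.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' SimConfig: synthetic study configuration
#'
#' Defaults emulate the study design this package targets: three
#' diagnostic groups (6 controls, 6 bipolar disorder, 8 schizophrenia),
#' 312 miRNAs on a log2-normal baseline, a spiked differentially
#' expressed subset in the SZ group, and sub-background readings emitted
#' as negative raw values by subtracting a background constant.
#'
#' @slot nMirnas integer(1), number of miRNAs.
#' @slot groupSizes named integer, samples per group (names are labels).
#' @slot nSpikedPerGroup named integer, spiked miRNAs per affected group.
#' @slot effectSizeLog2 numeric(1), log2 shift applied to spiked miRNAs
#'   in their affected group.
#' @slot baselineLogMean,baselineLogSd numeric(1), log2-scale abundance
#'   distribution of the per-miRNA baselines.
#' @slot noiseSd numeric(1), log2-scale per-measurement noise.
#' @slot backgroundThreshold numeric(1), constant subtracted from linear
#'   intensities; intensities below it come out negative.
#' @slot covariateAssignment named list, drug-class letter -> sample ids
#'   of takers (case samples only).
#' @slot covariateEffectLog2 numeric(1), additive log2 effect in takers
#'   for covariate-affected miRNAs.
#' @slot nCovariateMirnas integer(1), number of miRNAs carrying the
#'   drug-class effect.
#' @slot qpcrNoiseSd numeric(1), CT noise (cycles) for [simulateQpcr()].
#' @slot seed integer(1), global seed.
#' @export
setClass("SimConfig", representation(
  nMirnas = "integer", groupSizes = "integer", nSpikedPerGroup = "integer",
  effectSizeLog2 = "numeric", baselineLogMean = "numeric",
  baselineLogSd = "numeric", noiseSd = "numeric",
  backgroundThreshold = "numeric", covariateAssignment = "list",
  covariateEffectLog2 = "numeric", nCovariateMirnas = "integer",
  qpcrNoiseSd = "numeric", seed = "integer"))

.validSimConfig <- function(object) {
  msg <- NULL
  if (object@nMirnas < 1L) msg <- c(msg, "nMirnas must be positive")
  if (length(object@groupSizes) < 1L || any(object@groupSizes < 1L))
    msg <- c(msg, "all group sizes must be positive")
  if (is.null(names(object@groupSizes)))
    msg <- c(msg, "groupSizes must be named by group label")
  if (any(object@nSpikedPerGroup < 0L))
    msg <- c(msg, "spike counts must be nonnegative")
  if (sum(object@nSpikedPerGroup) > object@nMirnas)
    msg <- c(msg, "cannot spike more miRNAs than exist")
  if (!all(names(object@nSpikedPerGroup) %in% names(object@groupSizes)))
    msg <- c(msg, "nSpikedPerGroup names must be group labels")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@effectSizeLog2 < 0) msg <- c(msg, "effectSizeLog2 must be >= 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("SimConfig", .validSimConfig)

#' Build a synthetic study configuration
#'
#' @param nMirnas number of miRNAs (default 312, the bead panel size).
#' @param groupSizes named samples-per-group vector
#'   (default \code{c(C = 6, BD = 6, SZ = 8)}).
#' @param nSpikedPerGroup named spiked-miRNA counts
#'   (default 20 spiked in SZ).
#' @param effectSizeLog2 log2 shift of spiked miRNAs (default 2).
#' @param baselineLogMean,baselineLogSd baseline abundance distribution
#'   on the log2 scale (defaults 6 and 1.5).
#' @param noiseSd log2-scale measurement noise (default 0.2).
#' @param backgroundThreshold background constant subtracted from linear
#'   intensities (default 30).
#' @param covariateAssignment named list mapping drug-class letters to
#'   taker sample ids; empty by default (no medication confound).
#' @param covariateEffectLog2 additive log2 taker effect (default 1).
#' @param nCovariateMirnas miRNAs carrying the taker effect (default 10).
#' @param qpcrNoiseSd CT noise in cycles (default 0.3).
#' @param seed integer seed (default 1).
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 7)
#' sim <- simulateExpression(cfg)
#' dim(sim$expression)
#' @export
simConfig <- function(nMirnas = 312L,
                      groupSizes = c(C = 6L, BD = 6L, SZ = 8L),
                      nSpikedPerGroup = c(C = 0L, BD = 0L, SZ = 20L),
                      effectSizeLog2 = 2,
                      baselineLogMean = 6, baselineLogSd = 1.5,
                      noiseSd = 0.2,
                      backgroundThreshold = 30,
                      covariateAssignment = list(),
                      covariateEffectLog2 = 1,
                      nCovariateMirnas = 10L,
                      qpcrNoiseSd = 0.3,
                      seed = 1L) {
  gs <- setNames(as.integer(groupSizes), names(groupSizes))
  sp <- setNames(as.integer(nSpikedPerGroup), names(nSpikedPerGroup))
  new("SimConfig", nMirnas = as.integer(nMirnas), groupSizes = gs,
      nSpikedPerGroup = sp, effectSizeLog2 = effectSizeLog2,
      baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
      noiseSd = noiseSd, backgroundThreshold = backgroundThreshold,
      covariateAssignment = covariateAssignment,
      covariateEffectLog2 = covariateEffectLog2,
      nCovariateMirnas = as.integer(nCovariateMirnas),
      qpcrNoiseSd = qpcrNoiseSd, seed = as.integer(seed))
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror the arguments of [simConfig()]; absent fields keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a [SimConfig-class].
#' @export
simConfigFromYaml <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (nm in c("groupSizes", "nSpikedPerGroup"))
    if (!is.null(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  do.call(simConfig, lst)
}

.simSampleIds <- function(config) {
  unlist(lapply(names(config@groupSizes), function(g)
    paste0(g, seq_len(config@groupSizes[[g]]))), use.names = FALSE)
}

.simGroupOf <- function(config) {
  rep(names(config@groupSizes), config@groupSizes)
}

#' Simulate a raw bead-array expression matrix with ground truth
#'
#' Per-miRNA log2 baselines are drawn once, spiked miRNAs receive an
#' additive log2 shift in their affected group, covariate-affected
#' miRNAs receive an additive log2 shift in medication takers, Gaussian
#' log2 noise is added, and the linear-scale intensity has a constant
#' background subtracted, so that low-abundance readings come out
#' negative exactly as instrument exports do. The companion truth table
#' records which miRNAs were spiked (and where) and which carry a
#' drug-class effect.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{expression} (numeric matrix, possibly
#'   negative, miRNAs x samples) and \code{truth} (list with
#'   \code{spiked_mirnas}: per-miRNA affected group and true log2
#'   effect; \code{covariate_affected}: per-miRNA drug classes with a
#'   nonzero effect).
#' @export
simulateExpression <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  ids <- sprintf("mir-%03d", seq_len(config@nMirnas))
  sampleIds <- .simSampleIds(config)
  grp <- .simGroupOf(config)
  badAssign <- setdiff(unlist(config@covariateAssignment), sampleIds)
  if (length(badAssign))
    stop("covariateAssignment names unknown sample(s): ",
         paste(badAssign, collapse = ", "))

  .withSeed(config@seed + 101L, {
    baseline <- rnorm(config@nMirnas, config@baselineLogMean,
                      config@baselineLogSd)
    # spiked subsets are disjoint across groups
    pool <- seq_len(config@nMirnas)
    spiked <- list()
    for (g in names(config@nSpikedPerGroup)) {
      k <- config@nSpikedPerGroup[[g]]
      if (k > 0L) {
        pick <- sample(pool, k)
        pool <- setdiff(pool, pick)
        spiked[[g]] <- pick
      }
    }
    covIdx <- integer(0)
    if (length(config@covariateAssignment) > 0 &&
        config@covariateEffectLog2 != 0 && config@nCovariateMirnas > 0L)
      covIdx <- sample(seq_len(config@nMirnas),
                       min(config@nCovariateMirnas, config@nMirnas))

    y <- matrix(baseline, config@nMirnas, length(sampleIds))
    dimnames(y) <- list(ids, sampleIds)
    for (g in names(spiked))
      y[spiked[[g]], grp == g] <- y[spiked[[g]], grp == g] +
        config@effectSizeLog2
    for (cl in names(config@covariateAssignment)) {
      takers <- config@covariateAssignment[[cl]]
      if (length(covIdx) && length(takers))
        y[covIdx, takers] <- y[covIdx, takers] + config@covariateEffectLog2
    }
    if (config@noiseSd > 0)
      y <- y + matrix(rnorm(length(y), 0, config@noiseSd), nrow(y))
    raw <- 2^y - config@backgroundThreshold

    spikedMap <- list()
    for (g in names(spiked))
      for (i in spiked[[g]])
        spikedMap[[ids[i]]] <- list(group = g,
                                    effect = config@effectSizeLog2)
    covMap <- list()
    if (length(covIdx))
      for (i in covIdx)
        covMap[[ids[i]]] <- names(config@covariateAssignment)

    list(expression = raw,
         truth = list(spiked_mirnas = spikedMap,
                      covariate_affected = covMap))
  })
}

#' Simulate sample metadata
#'
#' One row per sample: diagnostic group, seven logical drug-class flags
#' A-G (controls never take a listed medication, so all their flags are
#' FALSE), age and sex. Flags echo the configured covariate assignment.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{classA}..\code{classG}, \code{age}, \code{sex}.
#' @export
simulateMetadata <- function(config) {
  stopifnot(is(config, "SimConfig"))
  sampleIds <- .simSampleIds(config)
  grp <- .simGroupOf(config)
  ctrl <- sampleIds[grp == "C"]
  badC <- intersect(unlist(config@covariateAssignment), ctrl)
  if (length(badC))
    stop("control sample(s) cannot be medication takers: ",
         paste(badC, collapse = ", "))
  flags <- sapply(LETTERS[1:7], function(cl)
    sampleIds %in% config@covariateAssignment[[cl]])
  colnames(flags) <- paste0("class", LETTERS[1:7])
  .withSeed(config@seed + 202L, {
    age <- round(runif(length(sampleIds), 35, 95))
    sex <- sample(c("M", "F"), length(sampleIds), replace = TRUE,
                  prob = c(0.85, 0.15))
    data.frame(sample = sampleIds, group = grp, flags, age = age,
               sex = sex, stringsAsFactors = FALSE)
  })
}

#' Simulate a long-format qPCR well table
#'
#' CT values follow the standard log-linear amplification model
#' CT = intercept - slope * log2(expression + 1) + noise, with an
#' optional per-plate offset (which cancels in delta-CT). The reference
#' target amplifies from a level held constant across samples (the
#' median of its expression row), emulating a stably expressed
#' normalizer.
#'
#' @param config a [SimConfig-class] (supplies \code{qpcrNoiseSd} and the
#'   seed).
#' @param expression nonnegative expression matrix containing all
#'   targets and the reference.
#' @param targets character, miRNA ids of interest.
#' @param reference id of the reference miRNA (constant normalizer).
#' @param nPlates,nReplicates plates and within-plate replicates per
#'   (sample, target); defaults 3 plates of duplicates.
#' @param intercept,slope amplification model parameters (defaults 35, 1).
#' @param plateSd standard deviation of the per-plate CT offset
#'   (default 0.5 cycles).
#' @return data.frame with columns \code{sample}, \code{target},
#'   \code{plate}, \code{replicate}, \code{ct}.
#' @export
simulateQpcr <- function(config, expression, targets, reference,
                         nPlates = 3L, nReplicates = 2L,
                         intercept = 35, slope = 1, plateSd = 0.5) {
  stopifnot(is(config, "SimConfig"), nPlates >= 1L, nReplicates >= 1L)
  expression <- mirExprs(expression)
  missing <- setdiff(c(targets, reference), rownames(expression))
  if (length(missing))
    stop("target id(s) not in expression matrix: ",
         paste(missing, collapse = ", "))
  samples <- colnames(expression)
  refLevel <- median(expression[reference, ])
  allTargets <- unique(c(targets, reference))
  wells <- expand.grid(replicate = seq_len(nReplicates),
                       plate = seq_len(nPlates),
                       target = allTargets, sample = samples,
                       stringsAsFactors = FALSE)
  wells <- wells[, c("sample", "target", "plate", "replicate")]
  .withSeed(config@seed + 303L, {
    plateOff <- if (plateSd > 0) rnorm(nPlates, 0, plateSd)
                else numeric(nPlates)
    level <- ifelse(wells$target == reference, refLevel,
                    expression[cbind(wells$target, wells$sample)])
    ct <- intercept - slope * log2(level + 1) + plateOff[wells$plate]
    if (config@qpcrNoiseSd > 0)
      ct <- ct + rnorm(nrow(wells), 0, config@qpcrNoiseSd)
    wells$ct <- ct
    rownames(wells) <- NULL
    wells
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulateExpression()] and
#' [simulateMetadata()] and assembling a floored [MirExperiment-class].
#'
#' @param config a [SimConfig-class].
#' @return list with \code{experiment} (floored MirExperiment),
#'   \code{raw} (matrix with negatives), \code{samples} (metadata
#'   data.frame) and \code{truth}.
#' @export
simulateStudy <- function(config) {
  sim <- simulateExpression(config)
  md <- simulateMetadata(config)
  me <- floorNegatives(MirExperiment(sim$expression, md))
  list(experiment = me, raw = sim$expression, samples = md,
       truth = sim$truth)
}

#' Write / read a simulation truth table as JSON
#'
#' @param truth the \code{truth} element returned by
#'   [simulateExpression()].
#' @param path JSON file path.
#' @return invisibly \code{path}; \code{readSimTruth} returns the list.
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
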