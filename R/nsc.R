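# Nearest shrunken centroid classification with cross-validated
# misclassification curves.

.nscScale <- function(x, groups) {
  M <- .groupIndicator(groups)
  n <- colSums(M)
  N <- sum(n)
  K <- length(n)
  gm <- x %*% sweep(M, 2L, n, `/`)
  ssw <- rowSums(x^2) - as.vector(gm^2 %*% n)
  ssw[ssw < 0] <- 0
  list(s = sqrt(ssw / (N - K)), groupMeans = gm, n = n, N = N)
}

#' Fit a nearest shrunken centroid model
#'
#' Standard construction: the standardized difference between class
#' centroid and overall centroid,
#' \deqn{d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))},
#' with \eqn{m_k = \sqrt{1/n_k - 1/N}}, \eqn{s_i} the pooled
#' within-class standard deviation and \eqn{s_0} its median, is
#' soft-thresholded by each \eqn{\Delta} in the grid:
#' \eqn{d'_{ik} = \mathrm{sign}(d_{ik}) \max(|d_{ik}| - \Delta, 0)}.
#' Shrunken class centroids are rebuilt from \eqn{d'_{ik}}; miRNAs whose
#' differences vanish for all classes drop out of the classifier.
#'
#' @inheritParams groupZScores
#' @param deltaGrid nonnegative shrinkage thresholds (default 30 values
#'   from 0 to the largest |d|).
#' @param s0 scale offset; defaults to the median of the pooled
#'   within-class standard deviations.
#' @param priors named class priors; uniform by default (the cohort
#'   sizes are near-equal).
#' @return an [NscFit-class].
#' @export
nscFit <- function(x, groups = NULL, deltaGrid = NULL, s0 = NULL,
                   priors = NULL) {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("at least two classes are required")
  if (any(table(groups) < 1L))
    stop("every class needs at least 1 sample")
  sc <- .nscScale(x, groups)
  if (is.null(s0)) s0 <- median(sc$s)
  mk <- sqrt(1 / sc$n - 1 / sc$N)
  overall <- rowMeans(x)
  dik <- sweep(sc$groupMeans - overall, 2L, mk, `/`) / (sc$s + s0)
  if (is.null(deltaGrid))
    deltaGrid <- seq(0, max(abs(dik)), length.out = 30L)
  if (any(deltaGrid < 0)) stop("deltaGrid must be nonnegative")
  if (length(deltaGrid) == 0L) stop("deltaGrid must be nonempty")
  lv <- levels(groups)
  if (is.null(priors)) priors <- setNames(rep(1 / length(lv), length(lv)), lv)
  new("NscFit", overall = overall, classCentroids = sc$groupMeans,
      s = sc$s, s0 = s0, mk = setNames(as.numeric(mk), lv), dik = dik,
      deltaGrid = as.numeric(deltaGrid),
      classCounts = setNames(as.integer(sc$n), lv),
      priors = priors[lv])
}

.softThreshold <- function(d, delta) {
  sign(d) * pmax(abs(d) - delta, 0)
}

#' Shrunken centroids at a threshold
#'
#' @param fit an [NscFit-class].
#' @param delta shrinkage threshold.
#' @return list with \code{centroids} (miRNAs x classes),
#'   \code{dShrunk}, and \code{surviving} (ids of miRNAs with a nonzero
#'   shrunken difference in some class).
#' @export
nscShrink <- function(fit, delta) {
  dp <- .softThreshold(fit@dik, delta)
  cent <- fit@overall +
    sweep(dp, 2L, fit@mk, `*`) * (fit@s + fit@s0)
  surviving <- rownames(dp)[rowSums(dp != 0) > 0]
  list(centroids = cent, dShrunk = dp, surviving = surviving)
}

#' Classify samples with a shrunken-centroid model
#'
#' Discriminant score
#' \eqn{\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2 / (s_i + s_0)^2 -
#' 2 \log \pi_k}; the smallest score wins. Ties (e.g. under full
#' shrinkage with uniform priors) go to the class with the largest
#' training count, then to class order.
#'
#' @param fit an [NscFit-class].
#' @param newX numeric matrix (same miRNAs as the fit) or vector.
#' @param delta shrinkage threshold (default 0).
#' @return factor of predicted class labels.
#' @export
nscPredict <- function(fit, newX, delta = 0) {
  if (is.null(dim(newX))) newX <- matrix(newX, ncol = 1L)
  sh <- nscShrink(fit, delta)
  lv <- colnames(fit@classCentroids)
  denom <- (fit@s + fit@s0)^2
  scores <- vapply(lv, function(k) {
    colSums((newX - sh$centroids[, k])^2 / denom) - 2 * log(fit@priors[k])
  }, numeric(ncol(newX)))
  scores <- matrix(scores, ncol = length(lv), dimnames = list(NULL, lv))
  pred <- apply(scores, 1L, function(sc) {
    cand <- which(sc <= min(sc) + 1e-9)
    if (length(cand) > 1L)
      cand <- cand[order(-fit@classCounts[cand])][1L]
    lv[cand[1L]]
  })
  factor(pred, levels = lv)
}

#' Cross-validated misclassification curves
#'
#' Refits the shrunken-centroid model on each training split and scores
#' the held-out samples over the whole threshold grid, reporting the
#' overall and per-class misclassification rate and the number of
#' surviving miRNAs per threshold. Leave-one-out is the default, suited
#' to cohorts of a few dozen samples; k-fold splits are available.
#'
#' @inheritParams nscFit
#' @param deltaGrid shrinkage thresholds (default: grid of the full-data
#'   fit).
#' @param folds \code{"loo"} (default) or an integer number of folds.
#' @param seed seed for k-fold assignment (ignored for LOO).
#' @return data.frame with columns \code{delta}, \code{nSurviving},
#'   \code{errOverall} and one \code{err<class>} column per class.
#' @examples
#' sim <- simulateStudy(simConfig(nMirnas = 40L, effectSizeLog2 = 4,
#'                                noiseSd = 0.1, seed = 5))
#' cv <- cvMisclassification(sim$experiment)
#' cv[1, ]
#' @export
cvMisclassification <- function(x, groups = NULL, deltaGrid = NULL,
                                folds = "loo", seed = 1L, priors = NULL) {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  groups <- droplevels(as.factor(groups))
  N <- ncol(x)
  lv <- levels(groups)
  if (is.null(deltaGrid))
    deltaGrid <- nscFit(x, groups, priors = priors)@deltaGrid
  foldId <- if (identical(folds, "loo")) seq_len(N)
            else .withSeed(seed, sample(rep_len(seq_len(folds), N)))
  for (f in unique(foldId)) {
    tr <- table(groups[foldId != f])
    if (any(tr < 1L))
      stop("fold leaves class(es) empty: ",
           paste(names(which(tr < 1L)), collapse = ", "))
  }
  pred <- matrix(NA_character_, N, length(deltaGrid))
  nSurv <- numeric(length(deltaGrid))
  fullFit <- nscFit(x, groups, deltaGrid = deltaGrid, priors = priors)
  for (d in seq_along(deltaGrid))
    nSurv[d] <- length(nscShrink(fullFit, deltaGrid[d])$surviving)
  for (f in unique(foldId)) {
    test <- which(foldId == f)
    fit <- nscFit(x[, -test, drop = FALSE], groups[-test],
                  deltaGrid = deltaGrid, priors = priors)
    for (d in seq_along(deltaGrid))
      pred[test, d] <- as.character(
        nscPredict(fit, x[, test, drop = FALSE], deltaGrid[d]))
  }
  out <- data.frame(delta = deltaGrid, nSurviving = nSurv,
                    errOverall = colMeans(pred != as.character(groups)))
  for (g in lv)
    out[[paste0("err", g)]] <-
      colMeans(pred[groups == g, , drop = FALSE] != g)
  out
}

#' Write misclassification curves as TSV
#'
#' @param x data.frame from [cvMisclassification()].
#' @param path output path.
#' @return invisibly \code{path}.
#' @export
writeMisclassification <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
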