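# Moderated multiclass score engine: per-group standardized scores with an
# exchangeability constant s0, permutation q-values and windowed local FDR.

.groupIndicator <- function(groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  M <- vapply(lv, function(g) as.numeric(groups == g),
              numeric(length(groups)))
  colnames(M) <- lv
  M
}

# pooled per-miRNA scale: sqrt( SSW / (N - K) * (1 / N) ), where SSW is the
# within-group sum of squares. The 1/N factor puts the scale on a
# standard-error footing so the scores come out on the published z range.
.samScale <- function(x, groups) {
  M <- .groupIndicator(groups)
  n <- colSums(M)
  N <- sum(n)
  K <- length(n)
  gm <- x %*% sweep(M, 2L, n, `/`)       # group means, m x K
  ssw <- rowSums(x^2) - as.vector(gm^2 %*% n)
  ssw[ssw < 0] <- 0                      # numerical guard
  list(s = sqrt(ssw / (N - K) / N), groupMeans = gm, n = n)
}

#' Per-group moderated z-scores
#'
#' For miRNA i and group k the score is
#' \deqn{z_{ik} = (\bar x_{ik} - \bar x_i) / (s_i + s_0)}
#' with \eqn{\bar x_{ik}} the group mean, \eqn{\bar x_i} the grand mean,
#' \eqn{s_i} the pooled per-miRNA scale and \eqn{s_0} the shared
#' exchangeability constant that keeps low-scale miRNAs from dominating
#' the ranking. By construction the group-size-weighted scores sum to
#' zero for every miRNA: \eqn{\sum_k n_k z_{ik} = 0}.
#'
#' @param x numeric matrix (miRNAs x samples) or [MirExperiment-class].
#' @param groups factor of group labels per sample; taken from the
#'   object's metadata when \code{x} is a MirExperiment.
#' @param s0 nonnegative exchangeability constant; see [computeS0()].
#' @return a [SamResult-class] with scores, scales and the ranking
#'   statistic D = max_k |z_ik| filled in (q-values and local FDR still
#'   NA).
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 6, 7), 1)
#' colnames(m) <- paste0("s", 1:6); rownames(m) <- "mir-1"
#' groupZScores(m, factor(rep(c("a", "b"), each = 3)), s0 = 0)
#' @export
groupZScores <- function(x, groups = NULL, s0 = 0) {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L)
    stop("at least two groups are required")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 samples: ",
         paste(names(which(table(groups) < 2L)), collapse = ", "))
  if (s0 < 0) stop("s0 must be nonnegative")
  sc <- .samScale(x, groups)
  grand <- rowMeans(x)
  z <- (sc$groupMeans - grand) / (sc$s + s0)
  z[!is.finite(z)] <- 0                  # constant miRNA with s0 = 0
  m <- nrow(x)
  new("SamResult", z = z, s = sc$s, s0 = s0,
      D = apply(abs(z), 1L, max),
      groupSizes = setNames(as.integer(sc$n), names(sc$n)),
      qvalue = rep(NA_real_, m), localFdr = rep(NA_real_, m))
}

#' Choose the exchangeability constant s0
#'
#' Scans the percentiles 0, 5, ..., 100 of the per-miRNA scales
#' \eqn{s_i} and returns the candidate minimizing the coefficient of
#' variation of the median ranking statistic across scale bins, i.e. the
#' constant that makes the scores exchangeable across the scale range.
#'
#' @inheritParams groupZScores
#' @param percentiles candidate percentiles of the scale distribution.
#' @param nBins number of quantile bins of \eqn{s_i} used to measure the
#'   coefficient of variation (default 10).
#' @return the chosen s0 (a value of the scale distribution, strictly
#'   positive whenever any \eqn{s_i > 0}).
#' @export
computeS0 <- function(x, groups = NULL, percentiles = seq(0, 100, by = 5),
                      nBins = 10L) {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  groups <- as.factor(groups)
  sc <- .samScale(x, groups)
  s <- sc$s
  if (all(s == 0))
    stop("degenerate data: every miRNA has zero within-group scale")
  cand <- unique(unname(quantile(s, percentiles / 100)))
  cand <- cand[cand > 0]
  grand <- rowMeans(x)
  r <- sc$groupMeans - grand             # numerators, reused per candidate
  breaks <- unique(quantile(s, seq(0, 1, length.out = nBins + 1L)))
  bins <- if (length(breaks) > 2L)
    cut(s, breaks, include.lowest = TRUE) else factor(rep(1L, length(s)))
  cv <- vapply(cand, function(s0) {
    D <- apply(abs(r / (s + s0)), 1L, max)
    med <- tapply(D, bins, median)
    med <- med[!is.na(med)]
    if (mean(med) == 0) Inf else sd(med) / mean(med)
  }, numeric(1L))
  cand[which.min(cv)]
}

.countDistinctAssignments <- function(n) {
  exp(lgamma(sum(n) + 1) - sum(lgamma(n + 1)))
}

# all distinct assignments of N samples into groups of the given sizes;
# returns a list of integer label vectors (values index the group)
.enumerateAssignments <- function(n) {
  N <- sum(n)
  rec2 <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    out <- list()
    for (p in combn(avail, sizes[1L], simplify = FALSE)) {
      for (r in rec2(setdiff(avail, p), sizes[-1L]))
        out[[length(out) + 1L]] <- c(list(p), r)
    }
    out
  }
  parts <- rec2(seq_len(N), n)
  lapply(parts, function(pp) {
    lab <- integer(N)
    for (k in seq_along(pp)) lab[pp[[k]]] <- k
    lab
  })
}

#' Permutation null distribution of the ranking statistic
#'
#' Recomputes the per-group scores and the ranking statistic
#' D = max_k |z_ik| under group-label permutations that preserve the
#' group sizes, holding s0 at its observed value. When the design admits
#' at most \code{enumerateMax} distinct assignments, all of them are
#' used instead of random sampling.
#'
#' @inheritParams groupZScores
#' @param B number of permutations (at least 100 when sampling).
#' @param seed integer seed for the permutation stream.
#' @param s0 exchangeability constant of the observed fit.
#' @param enumerateMax enumeration threshold (default 500). Under
#'   enumeration the identity assignment is excluded, so B is one less
#'   than the number of distinct assignments.
#' @return a [PermutationNull-class].
#' @export
samPermutationNull <- function(x, groups = NULL, B = 1000L, seed = 1L,
                               s0 = 0, enumerateMax = 500L) {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  groups <- as.factor(groups)
  n <- table(groups)
  lv <- levels(groups)
  nDistinct <- .countDistinctAssignments(as.integer(n))
  enumerated <- nDistinct <= enumerateMax
  if (!enumerated && B < 100L)
    stop("B must be at least 100 for a usable null resolution")
  if (enumerated) {
    labSets <- .enumerateAssignments(as.integer(n))
    perms <- lapply(labSets, function(lab) factor(lv[lab], levels = lv))
    # drop the identity assignment: the null holds genuine rearrangements
    obs <- as.character(groups)
    perms <- perms[!vapply(perms, function(p)
      identical(as.character(p), obs), logical(1L))]
    B <- length(perms)
  } else {
    perms <- .withSeed(seed, replicate(B, sample(groups), simplify = FALSE))
  }
  m <- nrow(x)
  nullD <- matrix(NA_real_, B, m, dimnames = list(NULL, rownames(x)))
  nullZ <- lapply(lv, function(g) nullD)
  names(nullZ) <- lv
  for (b in seq_len(B)) {
    sc <- .samScale(x, perms[[b]])
    z <- (sc$groupMeans - rowMeans(x)) / (sc$s + s0)
    z[!is.finite(z)] <- 0
    nullD[b, ] <- apply(abs(z), 1L, max)
    for (g in lv) nullZ[[g]][b, ] <- z[, g]
  }
  new("PermutationNull", nullD = nullD, nullZ = nullZ, B = as.integer(B),
      seed = as.integer(seed), enumerated = enumerated)
}

.rankOrder <- function(sam) {
  order(-sam@D, rownames(sam@z))
}

#' Permutation q-values
#'
#' For the miRNA of rank r (descending ranking statistic D), the
#' q-value is 100 times the expected number of null statistics at or
#' above \eqn{D_{(r)}} per permutation, divided by r (the observed
#' count at that threshold), made non-decreasing in rank by a running
#' maximum and clipped to [0, 100]. The expected null count is the mean
#' per-permutation exceedance count; \code{center = "median"} switches
#' to the per-permutation median.
#'
#' @param sam a [SamResult-class] from [groupZScores()].
#' @param null a [PermutationNull-class] on the same miRNA set.
#' @param center how per-permutation null counts are aggregated.
#' @return the SamResult with the \code{qvalue} slot filled (percent).
#' @export
samQvalues <- function(sam, null, center = c("mean", "median")) {
  center <- match.arg(center)
  if (ncol(null@nullD) != nrow(sam@z))
    stop("null was computed on a different miRNA set")
  ord <- .rankOrder(sam)
  Ds <- sam@D[ord]
  B <- null@B
  if (center == "mean") {
    nullv <- sort(as.vector(null@nullD))
    total <- length(nullv)
    cnt <- (total - findInterval(Ds, nullv, left.open = TRUE)) / B
  } else {
    rows <- apply(null@nullD, 1L, sort, simplify = FALSE)
    m <- ncol(null@nullD)
    perRank <- vapply(rows, function(rw)
      m - findInterval(Ds, rw, left.open = TRUE), numeric(length(Ds)))
    cnt <- apply(matrix(perRank, nrow = length(Ds)), 1L, median)
  }
  q <- 100 * cnt / seq_along(Ds)
  q <- cummax(pmin(pmax(q, 0), 100))
  out <- sam
  out@qvalue[ord] <- q
  out
}

#' Windowed local false discovery rate
#'
#' The q-value judges a miRNA by everything ranked above it; the local
#' FDR instead judges it together with its neighbors in the ranking.
#' For rank r, the window spans ranks [r - w/2, r + w/2] (clipped at the
#' list ends); the local FDR is 100 times the mean per-permutation null
#' count inside the D-interval spanned by that window, divided by the
#' observed count in the interval, clipped to [0, 100].
#'
#' @inheritParams samQvalues
#' @param window neighborhood size in ranks (at least 10, at most the
#'   number of miRNAs).
#' @return the SamResult with the \code{localFdr} slot filled (percent).
#' @export
samLocalFdr <- function(sam, null, window = 50L) {
  m <- nrow(sam@z)
  if (window < 10L) stop("window must be at least 10")
  if (window > m) stop("window (", window, ") exceeds the miRNA count (",
                       m, ")")
  if (ncol(null@nullD) != m)
    stop("null was computed on a different miRNA set")
  ord <- .rankOrder(sam)
  Ds <- sam@D[ord]
  nullv <- sort(as.vector(null@nullD))
  total <- length(nullv)
  w2 <- window %/% 2L
  lfdr <- vapply(seq_len(m), function(r) {
    lo <- max(1L, r - w2)
    hi <- min(m, r + w2)
    dHigh <- Ds[lo]                      # largest D in the window
    dLow <- Ds[hi]                       # smallest D in the window
    obs <- hi - lo + 1L
    nullCnt <- (findInterval(dHigh, nullv) -
                  findInterval(dLow, nullv, left.open = TRUE)) / null@B
    min(max(100 * nullCnt / obs, 0), 100)
  }, numeric(1L))
  out <- sam
  out@localFdr[ord] <- lfdr
  out
}

#' Ranked score report
#'
#' Rows sorted by descending ranking statistic (ties broken by miRNA id)
#' with one z-score column per group, the q-value and the local FDR,
#' both in percent.
#'
#' @param sam a completed [SamResult-class].
#' @return data.frame with columns \code{miRNA},
#'   \code{z-score:<group>} per group, \code{q-value(\%)},
#'   \code{local FDR(\%)}.
#' @export
rankTable <- function(sam) {
  ord <- .rankOrder(sam)
  df <- data.frame(miRNA = rownames(sam@z)[ord],
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (g in colnames(sam@z))
    df[[paste0("z-score:", g)]] <- sam@z[ord, g]
  df[["q-value(%)"]] <- sam@qvalue[ord]
  df[["local FDR(%)"]] <- sam@localFdr[ord]
  rownames(df) <- NULL
  df
}

#' Write / read a ranked report TSV
#'
#' The dialect matches the packaged study tables: tab-separated,
#' columns \code{miRNA}, one \code{z-score:<group>} per group (absent
#' for two-class reports that only carry q-values), \code{q-value(\%)},
#' \code{local FDR(\%)}.
#'
#' @param x data.frame from [rankTable()].
#' @param path file path.
#' @return invisibly \code{path}; \code{readRankTable} returns the
#'   data.frame.
#' @export
writeRankTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankTable
#' @export
readRankTable <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' One-call moderated score analysis
#'
#' Computes s0, the observed scores, the permutation null, q-values and
#' local FDR in one step.
#'
#' @inheritParams groupZScores
#' @param B permutations (default 1000).
#' @param seed permutation seed.
#' @param window local FDR window (default 50, reduced to the miRNA
#'   count when the panel is smaller).
#' @param center q-value aggregation, see [samQvalues()].
#' @return list with \code{scores} (completed [SamResult-class]) and
#'   \code{null} (the [PermutationNull-class]).
#' @examples
#' sim <- simulateStudy(simConfig(nMirnas = 40L, seed = 3))
#' res <- samAnalysis(sim$experiment, B = 100, seed = 3)
#' head(rankTable(res$scores), 3)
#' @export
samAnalysis <- function(x, groups = NULL, B = 1000L, seed = 1L,
                        window = 50L, center = "mean") {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  s0 <- computeS0(x, groups)
  sam <- groupZScores(x, groups, s0 = s0)
  null <- samPermutationNull(x, groups, B = B, seed = seed, s0 = s0)
  sam <- samQvalues(sam, null, center = center)
  sam <- samLocalFdr(sam, null, window = min(window, nrow(x)))
  list(scores = sam, null = null)
}

#' miRNAs at q-value zero
#'
#' @param x a completed [SamResult-class], or a ranked report data.frame
#'   with a \code{q-value(\%)} column (e.g. a packaged study table).
#' @return character vector of miRNA ids whose q-value is exactly 0.
#' @export
qZero <- function(x) {
  if (is(x, "SamResult"))
    return(rownames(x@z)[!is.na(x@qvalue) & x@qvalue == 0])
  q <- x[["q-value(%)"]]
  as.character(x$miRNA[q == 0])
}

#' Holm step-down multiple-testing correction
#'
#' Sorts p-values ascending and rejects while
#' \eqn{p_{(r)} \le \alpha / (m_{total} - (r - 1))}, stopping at the
#' first failure. \code{mTotal} defaults to the number of p-values but
#' can be larger when the tested set is a subset of the panel (e.g. 312
#' assayed miRNAs).
#'
#' @param pvalues named numeric vector of p-values in [0, 1].
#' @param alpha family-wise error level (default 0.05).
#' @param mTotal total number of comparisons corrected for.
#' @return character vector of rejected names, with the per-rank
#'   thresholds attached as attribute \code{"thresholds"}.
#' @examples
#' holmStepdown(c(a = 1e-6, b = 0.04, c = 0.05), alpha = 0.05, mTotal = 3)
#' @export
holmStepdown <- function(pvalues, alpha = 0.05, mTotal = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues)))
    stop("p-values must lie in [0, 1]")
  if (mTotal < length(pvalues))
    stop("mTotal must be at least the number of p-values")
  if (is.null(names(pvalues)))
    names(pvalues) <- seq_along(pvalues)
  ord <- order(pvalues, names(pvalues))
  ps <- pvalues[ord]
  thr <- alpha / (mTotal - (seq_along(ps) - 1L))
  ok <- ps <= thr
  firstFail <- which(!ok)[1L]
  rejected <- if (is.na(firstFail)) names(ps) else names(ps)[seq_len(firstFail - 1L)]
  structure(rejected, thresholds = setNames(thr, names(ps)))
}

#' Exact two-class Wilcoxon rank-sum test per miRNA
#'
#' Rank-sum test with mid-ranks for ties and an exact permutation
#' distribution obtained by enumerating all assignments of the samples
#' to the two groups (feasible for the small cohorts this package
#' targets; a normal approximation with tie correction is used beyond
#' \code{enumerateMax} assignments). P-values are two-sided,
#' \eqn{\min(1, 2 \min(P(W \le w), P(W \ge w)))}.
#'
#' @inheritParams groupZScores
#' @param g1,g2 the two group labels to compare; W is the rank sum of
#'   \code{g1}.
#' @param enumerateMax largest number of assignments enumerated exactly.
#' @return data.frame with columns \code{miRNA}, \code{W}, \code{p}.
#' @export
wilcoxonTwoClass <- function(x, groups = NULL, g1, g2,
                             enumerateMax = 2e5) {
  if (is(x, "MirExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- mirExprs(x)
  }
  groups <- as.character(groups)
  i1 <- which(groups == g1)
  i2 <- which(groups == g2)
  if (length(i1) == 0L || length(i2) == 0L)
    stop("both groups must be nonempty")
  sub <- x[, c(i1, i2), drop = FALSE]
  n1 <- length(i1)
  n <- n1 + length(i2)
  exact <- choose(n, n1) <= enumerateMax
  assigns <- if (exact) combn(n, n1) else NULL
  res <- t(apply(sub, 1L, function(v) {
    rk <- rank(v)                        # mid-ranks under ties
    w <- sum(rk[seq_len(n1)])
    if (exact) {
      wp <- colSums(matrix(rk[assigns], nrow = n1))
      p <- min(1, 2 * min(mean(wp <= w), mean(wp >= w)))
    } else {
      mu <- n1 * (n + 1) / 2
      tie <- table(rk)
      sig2 <- n1 * (n - n1) / 12 *
        ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
      p <- if (sig2 == 0) 1 else
        min(1, 2 * pnorm(-abs(w - mu) / sqrt(sig2)))
    }
    c(W = w, p = p)
  }))
  data.frame(miRNA = rownames(sub), W = res[, "W"], p = res[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}
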