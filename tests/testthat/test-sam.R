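# Independent oracle: spreadsheet-style evaluation of the score formula
# on a single miRNA, kept deliberately separate from the package code.
bruteZ <- function(values, groups, s0) {
  groups <- as.factor(groups)
  grand <- mean(values)
  N <- length(values)
  K <- nlevels(groups)
  ssw <- sum(unlist(lapply(levels(groups), function(g) {
    v <- values[groups == g]
    (v - mean(v))^2
  })))
  s <- sqrt(ssw / (N - K) / N)
  vapply(levels(groups), function(g)
    (mean(values[groups == g]) - grand) / (s + s0), numeric(1L))
}

test_that("group z-scores match brute-force formula evaluation", {
  g <- factor(rep(c("g1", "g2"), each = 3))
  m <- toyMatrix(c(1, 2, 3, 5, 6, 7), 1)
  sam <- groupZScores(m, g, s0 = 0)
  expect_equal(unname(sam@z[1, ]), unname(bruteZ(m[1, ], g, 0)))
  # a handful of random 3-group instances, s0 > 0
  set.seed(21)
  for (i in 1:5) {
    g3 <- factor(rep(c("C", "BD", "SZ"), c(3, 3, 4)))
    m3 <- toyMatrix(rnorm(30, 10, 2), 3)
    sam3 <- groupZScores(m3, g3, s0 = 0.3)
    for (r in 1:3)
      expect_equal(unname(sam3@z[r, levels(g3)]),
                   unname(bruteZ(m3[r, ], g3, 0.3)))
  }
})

test_that("a constant miRNA scores zero in every group", {
  m <- toyMatrix(rep(4, 8), 1)
  sam <- groupZScores(m, factor(rep(c("a", "b"), each = 4)), s0 = 0.5)
  expect_true(all(sam@z == 0))
})

test_that("group-size-weighted scores sum to zero on generated data", {
  for (s in 1:5) {
    sim <- quietStudy(simConfig(nMirnas = 60L, seed = 100L + s))
    sam <- groupZScores(sim$experiment, s0 = 0.1)
    n <- sam@groupSizes[colnames(sam@z)]
    ws <- abs(sam@z %*% n)
    expect_lt(max(ws), 1e-6 * sum(n))
  }
})

test_that("degenerate designs are rejected", {
  m <- toyMatrix(rnorm(12), 3)
  expect_error(groupZScores(m, factor(c("a", "a", "a", "b"))), "2 samples")
  expect_error(groupZScores(m, factor(rep("a", 4))), "two groups")
  expect_error(groupZScores(m, factor(rep(c("a", "b"), 2)), s0 = -1),
               "nonnegative")
})

test_that("computeS0 lands in the scale range and handles flat scales", {
  set.seed(31)
  m <- toyMatrix(rnorm(200 * 8, sd = rep(runif(200, 0.5, 5), each = 8)), 200)
  g <- factor(rep(c("a", "b"), each = 4))
  s0 <- computeS0(m, g)
  sc <- groupZScores(m, g, s0 = 0)@s
  expect_gte(s0, min(sc))
  expect_lte(s0, max(sc))
  # equal scales: every percentile is the common value
  flat <- matrix(rep(c(0, 1, 2, 3, 0, 1, 2, 3), times = 10), 10, 8,
                 byrow = TRUE,
                 dimnames = list(sprintf("mir-%02d", 1:10),
                                 sprintf("s%02d", 1:8)))
  s0f <- computeS0(flat, factor(rep(c("a", "b"), each = 4)))
  expect_equal(s0f,
               unname(groupZScores(flat, factor(rep(c("a", "b"), each = 4)),
                                   s0 = 0)@s[1]))
  expect_error(computeS0(toyMatrix(rep(1, 80), 10),
                         factor(rep(c("a", "b"), each = 4))), "degenerate")
})

test_that("the exchangeability constant tames low-scale outliers", {
  set.seed(32)
  nd <- nullTwoGroup(m = 500, n1 = 5, n2 = 5, seed = 32)
  s0 <- computeS0(nd$x, nd$groups)
  expect_gt(s0, 0)
  tails0 <- sum(abs(groupZScores(nd$x, nd$groups, s0 = 0)@z) > 3)
  tailsS0 <- sum(abs(groupZScores(nd$x, nd$groups, s0 = s0)@z) > 3)
  expect_lt(tailsS0, tails0)
})

test_that("permutation null: shape, determinism, enumeration", {
  nd <- nullTwoGroup(m = 10, n1 = 6, n2 = 6, seed = 41)
  n1 <- samPermutationNull(nd$x, nd$groups, B = 100L, seed = 9L, s0 = 0.1)
  n2 <- samPermutationNull(nd$x, nd$groups, B = 100L, seed = 9L, s0 = 0.1)
  expect_identical(n1@nullD, n2@nullD)
  expect_identical(dim(n1@nullD), c(100L, 10L))
  expect_error(samPermutationNull(nd$x, nd$groups, B = 50L, s0 = 0.1),
               "at least 100")
  # 3 vs 3 admits 20 distinct assignments; the identity is excluded
  sm <- nullTwoGroup(m = 5, n1 = 3, n2 = 3, seed = 42)
  ne <- samPermutationNull(sm$x, sm$groups, B = 1000L, s0 = 0.1)
  expect_true(ne@enumerated)
  expect_identical(ne@B, 19L)
})

test_that("observed and permuted statistics agree on null data", {
  ok <- vapply(1:10, function(s) {
    nd <- nullTwoGroup(m = 80, n1 = 5, n2 = 5, seed = 300 + s)
    s0 <- computeS0(nd$x, nd$groups)
    sam <- groupZScores(nd$x, nd$groups, s0 = s0)
    nl <- samPermutationNull(nd$x, nd$groups, B = 200L, seed = 300 + s,
                             s0 = s0)
    suppressWarnings(stats::ks.test(sam@D, as.vector(nl@nullD))$p.value) >
      0.01
  }, logical(1L))
  expect_gte(sum(ok), 9L)
})

test_that("q-values: zero only above the whole null, monotone, calibrated", {
  # spiked miRNA exceeding every null value gets q = 0 (unequal group
  # sizes: no label rearrangement can reproduce the observed split)
  set.seed(51)
  m <- toyMatrix(rnorm(30 * 10), 30)
  m[1, 7:10] <- m[1, 7:10] + 50
  g <- factor(rep(c("a", "b"), c(6, 4)))
  sam <- groupZScores(m, g, s0 = computeS0(m, g))
  nl <- samPermutationNull(m, g, B = 200L, seed = 51L, s0 = sam@s0)
  sam <- samQvalues(sam, nl)
  expect_equal(sam@qvalue[1], 0)
  rt <- rankTable(sam)
  expect_false(is.unsorted(rt[["q-value(%)"]]))
  expect_true(all(rt[["q-value(%)"]] >= 0 & rt[["q-value(%)"]] <= 100))
  # pure-null panel: q-values concentrate high
  nd <- nullTwoGroup(m = 100, n1 = 5, n2 = 5, seed = 52)
  s0 <- computeS0(nd$x, nd$groups)
  samN <- groupZScores(nd$x, nd$groups, s0 = s0)
  nlN <- samPermutationNull(nd$x, nd$groups, B = 200L, seed = 52L, s0 = s0)
  samN <- samQvalues(samN, nlN)
  expect_gte(median(samN@qvalue), 50)
})

test_that("local FDR: bounded, high under the null, low on a spiked top", {
  nd <- nullTwoGroup(m = 120, n1 = 5, n2 = 5, seed = 61)
  s0 <- computeS0(nd$x, nd$groups)
  sam <- groupZScores(nd$x, nd$groups, s0 = s0)
  nl <- samPermutationNull(nd$x, nd$groups, B = 200L, seed = 61L, s0 = s0)
  sam <- samLocalFdr(sam, nl, window = 50L)
  expect_true(all(sam@localFdr >= 0 & sam@localFdr <= 100))
  mid <- rankTable(sam)[["local FDR(%)"]][48:72]
  expect_true(all(mid >= 70))
  expect_error(samLocalFdr(sam, nl, window = 5L), "at least 10")
  expect_error(samLocalFdr(sam, nl, window = 500L), "exceeds")
  # strongly spiked block at effect 3: the top rank is clean
  sim <- quietStudy(simConfig(nSpikedPerGroup = c(C = 0L, BD = 0L,
                                                  SZ = 30L),
                              effectSizeLog2 = 3, seed = 62L))
  res <- samAnalysis(sim$experiment, B = 300L, seed = 62L)
  expect_lt(rankTable(res$scores)[["local FDR(%)"]][1], 10)
})

test_that("rankTable orders by statistic with lexicographic ties", {
  sam <- new("SamResult",
             z = matrix(c(2, -2, 1, -1), 2, 2,
                        dimnames = list(c("mir-b", "mir-a"), c("g1", "g2"))),
             s = c(1, 1), s0 = 0.1, D = c(2, 2),
             groupSizes = c(g1 = 3L, g2 = 3L),
             qvalue = c(0, 0), localFdr = c(1, 1))
  rt <- rankTable(sam)
  expect_identical(rt$miRNA, c("mir-a", "mir-b"))
  expect_identical(nrow(rt), 2L)
})

test_that("the top-ranked miRNA of a single-spike panel is the spike", {
  set.seed(71)
  m <- toyMatrix(rnorm(50 * 12, 10), 50)
  m[7, 1:4] <- m[7, 1:4] + 30
  g <- factor(rep(c("C", "BD", "SZ"), c(4, 4, 4)))
  res <- samAnalysis(m, g, B = 200L, seed = 71L, window = 20L)
  expect_identical(rankTable(res$scores)$miRNA[1], rownames(m)[7])
})

test_that("ranked report TSV round-trips bit-exact on the study table", {
  t2 <- samTableThreeGroup()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRankTable(t2, path)
  expect_identical(readLines(path),
                   readLines(exomirData("sam_scores_three_group.tsv")))
})

test_that("Holm step-down matches its closed form and a brute oracle", {
  thr <- attr(holmStepdown(c(a = 0.5), alpha = 0.05, mTotal = 312L),
              "thresholds")
  expect_equal(unname(thr[1]), 0.05 / 312)
  expect_length(holmStepdown(setNames(rep(1, 4), letters[1:4])), 0L)
  r <- holmStepdown(c(a = 1e-6, b = 0.04, c = 0.05), mTotal = 3L)
  expect_identical(as.character(r), "a")
  # exhaustive oracle: largest k such that all sorted p up to k pass
  bruteHolm <- function(p, alpha, mTot) {
    ps <- sort(p)
    pass <- vapply(seq_along(ps), function(k)
      all(ps[1:k] <= alpha / (mTot - (1:k) + 1)), logical(1L))
    k <- if (any(!pass)) which(!pass)[1L] - 1L else length(ps)
    names(ps)[seq_len(k)]
  }
  set.seed(81)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    p <- setNames(round(runif(n), 3), paste0("m", seq_len(n)))
    mt <- n + sample(0:300, 1)
    expect_setequal(as.character(holmStepdown(p, 0.05, mt)),
                    bruteHolm(p, 0.05, mt))
  }
  expect_error(holmStepdown(c(a = -0.1)), "0, 1")
})

test_that("exact Wilcoxon: enumeration, ties, rank invariance", {
  g <- factor(rep(c("a", "b"), each = 3))
  m <- toyMatrix(c(1, 2, 3, 10, 11, 12), 1)
  w <- wilcoxonTwoClass(m, g, "a", "b")
  expect_equal(w$W, 6)
  expect_equal(w$p, 0.1)      # 2/20 assignments as extreme
  # identical values: p = 1 after mid-ranking
  expect_equal(wilcoxonTwoClass(toyMatrix(rep(2, 6), 1), g, "a", "b")$p, 1)
  # invariant under monotone transforms
  set.seed(91)
  v <- toyMatrix(rexp(8), 1)
  g8 <- factor(rep(c("a", "b"), each = 4))
  expect_equal(wilcoxonTwoClass(v, g8, "a", "b")$p,
               wilcoxonTwoClass(log1p(v), g8, "a", "b")$p)
  # agreement with the exact distribution in wilcox.test on tie-free data
  for (i in 1:5) {
    x <- toyMatrix(sample(1:100, 9), 1)
    g9 <- factor(rep(c("a", "b"), c(4, 5)))
    ours <- wilcoxonTwoClass(x, g9, "a", "b")$p
    ref <- stats::wilcox.test(x[1, 1:4], x[1, 5:9], exact = TRUE)$p.value
    expect_equal(ours, ref)
  }
  expect_error(wilcoxonTwoClass(v, g8, "a", "zzz"), "nonempty")
})
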