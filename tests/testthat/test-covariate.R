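test_that("the study cohort yields exactly classes A, B, C as covariates", {
  md <- luminexCohort()
  des <- eligibleClasses(md)
  expect_identical(des@eligible,
                   c(A = TRUE, B = TRUE, C = TRUE, D = FALSE, E = FALSE,
                     F = FALSE, G = FALSE))
  # class D is judged among the BD bead-array cases: 4 takers, 2 non-takers
  expect_setequal(des@takers$D, c("BD1", "BD2", "BD5", "BD6"))
  expect_setequal(des@nonTakers$D, c("BD3", "BD4"))
  # class A among SZ cases only
  expect_setequal(des@takers$A, c("SZ1", "SZ3", "SZ7"))
  expect_length(des@nonTakers$A, 5L)
  # arms are disjoint and exclude controls
  for (cl in LETTERS[1:7]) {
    expect_length(intersect(des@takers[[cl]], des@nonTakers[[cl]]), 0L)
    expect_false(any(grepl("^C", c(des@takers[[cl]], des@nonTakers[[cl]]))))
  }
})

test_that("a control-only cohort has no eligible class", {
  md <- luminexCohort()
  des <- eligibleClasses(md, cohort = md$sample[md$group == "C"])
  expect_false(any(des@eligible))
  expect_true(all(lengths(des@takers) == 0L))
  expect_error(eligibleClasses(md, classes = "Z"), "unknown drug class")
  expect_error(eligibleClasses(md, cohort = "nope"), "unknown sample")
})

test_that("covariate effects: zero for identical arms, sign and rank for a
           spiked taker effect, calm under the null", {
  # identical taker / non-taker values give effect exactly 0
  md <- data.frame(sample = paste0("SZ", 1:8), group = "SZ",
                   classA = rep(c(TRUE, FALSE), each = 4))
  for (cl in LETTERS[2:7]) md[[paste0("class", cl)]] <- FALSE
  x <- toyMatrix(rep(c(3, 7, 1), times = 8), 3, samples = md$sample)
  des <- eligibleClasses(md)
  e0 <- covariateEffect(x, des, "A", s0 = 0.5)
  expect_equal(unname(e0), c(0, 0, 0))
  expect_error(covariateEffect(x, des, "D"), "not eligible")
  # +2 log2 taker effect: positive effect, among the top |e|
  set.seed(31)
  takers <- paste0("SZ", 1:4)
  y <- matrix(rnorm(50 * 8, 8, 0.2), 50, 8,
              dimnames = list(sprintf("mir-%02d", 1:50), md$sample))
  y["mir-07", takers] <- y["mir-07", takers] + 2
  e <- covariateEffect(2^y, des, "A")
  expect_gt(e["mir-07"], 0)
  expect_lte(match("mir-07", names(sort(-abs(e)))), 5L)
  # null generator: effects stay small for nearly all miRNAs
  sim <- quietStudy(nullConfig(710L))
  mdn <- sim$samples
  mdn$classB <- mdn$sample %in% c(paste0("SZ", 1:4), paste0("BD", 1:3))
  en <- covariateEffect(sim$experiment, eligibleClasses(mdn), "B")
  expect_gte(mean(abs(en) < 2), 0.95)
})

test_that("score adjustment reproduces the published worked arithmetic", {
  t2 <- samTableThreeGroup()
  eff <- covariateEffectsTable()
  z <- setNames(t2[["z-score:SZ"]], t2$miRNA)
  a <- adjustScores(z["hsa-miR-33"], eff, "A")
  expect_equal(unname(a), 2.46619, tolerance = 5e-5)
  b <- adjustScores(z["hsa-miR-96"], eff, "B")
  expect_equal(unname(b), 2.42693, tolerance = 5e-5)
  bc <- adjustScores(z["hsa-miR-33"], eff, c("B", "C"))
  expect_equal(unname(bc), 2.4480, tolerance = 5e-5)
  # blank effect means "nothing computed": score unchanged
  expect_equal(unname(adjustScores(z["hsa-miR-30e-5p"], eff, "B")),
               unname(z["hsa-miR-30e-5p"]))
  # empty class set is the identity
  expect_identical(adjustScores(z, eff, character(0)), z)
  expect_message(adjustScores(z[1], eff, "Z"), "treated as 0")
})

test_that("adjustment removes an aligned medication confound", {
  drops <- vapply(1:20, function(s) {
    cfg <- nullConfig(700L + s,
                      covariateAssignment = list(B = paste0("SZ", 1:8)),
                      covariateEffectLog2 = 1, nCovariateMirnas = 10L)
    sim <- quietStudy(cfg)
    aff <- names(sim$truth$covariate_affected)
    sam <- groupZScores(sim$experiment, s0 = computeS0(sim$experiment))
    e <- covariateEffect(sim$experiment, eligibleClasses(sim$samples), "B")
    z <- sam@z[, "SZ"]
    zadj <- adjustScores(z, data.frame(B = e, row.names = names(e)), "B")
    mean(abs(zadj[aff])) / mean(abs(z[aff]))
  }, numeric(1L))
  expect_true(all(drops <= 0.5))
})

test_that("permutation p-values of adjusted scores are sane and uniform", {
  nullv <- seq(-3, 3, length.out = 999)
  expect_equal(adjustedPvalue(0, nullv), 1)
  expect_equal(adjustedPvalue(10, nullv), 1 / 1000)
  ok <- vapply(1:10, function(s) {
    nd <- nullTwoGroup(m = 100, n1 = 5, n2 = 5, seed = 800 + s)
    s0 <- computeS0(nd$x, nd$groups)
    sam <- groupZScores(nd$x, nd$groups, s0 = s0)
    nl <- samPermutationNull(nd$x, nd$groups, B = 200L, seed = 800 + s,
                             s0 = s0)
    p <- adjustedPvalue(sam@z[, "a"], nl@nullZ[["a"]])
    suppressWarnings(stats::ks.test(p, "punif")$p.value) > 0.01
  }, logical(1L))
  expect_gte(sum(ok), 9L)
})

test_that("the drug-class YAML mirrors the default applicability map", {
  yml <- readDrugClasses(exomirData("drug_classes.yaml"))
  expect_setequal(names(yml), LETTERS[1:7])
  fromYaml <- lapply(yml, `[[`, "groups")
  expect_identical(fromYaml[order(names(fromYaml))],
                   drugClassGroups()[order(names(drugClassGroups()))])
})
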