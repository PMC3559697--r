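test_that("null design with zero noise is flat across samples", {
  cfg <- simConfig(nMirnas = 25L,
                   nSpikedPerGroup = c(C = 0L, BD = 0L, SZ = 0L),
                   noiseSd = 0)
  sim <- simulateExpression(cfg)
  expect_equal(dim(sim$expression), c(25L, 20L))
  expect_true(all(apply(sim$expression, 1L, function(r)
    max(r) - min(r)) == 0))
  expect_length(sim$truth$spiked_mirnas, 0L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- simConfig(seed = 1L)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(a, b)
  expect_identical(simulateMetadata(cfg), simulateMetadata(cfg))
  w1 <- simulateQpcr(cfg, floorNegatives(a$expression), "mir-001", "mir-002")
  w2 <- simulateQpcr(cfg, floorNegatives(b$expression), "mir-001", "mir-002")
  expect_identical(w1, w2)
  # a different seed actually changes the draw
  expect_false(identical(a$expression,
                         simulateExpression(simConfig(seed = 2L))$expression))
})

test_that("default config emits sub-background (negative) readings", {
  sim <- simulateExpression(simConfig(seed = 3L))
  expect_gt(sum(sim$expression < 0), 0L)
})

test_that("spiked group-mean shift is recovered from the output", {
  cfg <- simConfig(nSpikedPerGroup = c(C = 0L, BD = 0L, SZ = 20L),
                   effectSizeLog2 = 2, noiseSd = 0.2, seed = 4L)
  sim <- simulateExpression(cfg)
  md <- simulateMetadata(cfg)
  spiked <- names(sim$truth$spiked_mirnas)
  # undo the background shift to estimate on the generating (log2) scale
  y <- log2(sim$expression + cfg@backgroundThreshold)
  sz <- md$group == "SZ"
  diffs <- rowMeans(y[spiked, sz]) - rowMeans(y[spiked, !sz])
  sePerRow <- 0.2 * sqrt(1 / sum(sz) + 1 / sum(!sz))
  seMean <- sePerRow / sqrt(length(spiked))
  expect_lt(abs(mean(diffs) - 2), 3 * seMean)
})

test_that("spiked miRNAs dominate the affected group's |z| ranking", {
  # background censoring off: recovery is a property of the uncensored
  # generator + score pipeline; flooring is exercised elsewhere
  hits <- vapply(1:10, function(s) {
    sim <- quietStudy(simConfig(seed = 40L + s, backgroundThreshold = 0))
    sam <- groupZScores(sim$experiment, s0 = computeS0(sim$experiment))
    top <- names(sort(-abs(sam@z[, "SZ"])))[1:25]
    all(names(sim$truth$spiked_mirnas) %in% top)
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("metadata: controls carry no drug flags; assignment echoes", {
  md <- simulateMetadata(simConfig())
  flags <- as.matrix(md[md$group == "C", paste0("class", LETTERS[1:7])])
  expect_false(any(flags))
  cfg <- simConfig(covariateAssignment = list(A = paste0("SZ", 1:3)))
  md2 <- simulateMetadata(cfg)
  expect_identical(sum(md2$classA), 3L)
  expect_setequal(md2$sample[md2$classA], paste0("SZ", 1:3))
  # assigning a control is a configuration error
  expect_error(simulateMetadata(
    simConfig(covariateAssignment = list(A = "C1"))), "control")
})

test_that("config invariants are enforced", {
  expect_error(simConfig(groupSizes = c(C = 0L, SZ = 3L)), "positive")
  expect_error(simConfig(nMirnas = 5L,
                         nSpikedPerGroup = c(SZ = 9L)), "spike")
  expect_error(simConfig(noiseSd = -1), "noiseSd")
})

test_that("YAML config round-trips into simConfig", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nMirnas: 50", "seed: 9",
               "groupSizes: {C: 4, BD: 4, SZ: 5}",
               "nSpikedPerGroup: {SZ: 5}"), path)
  cfg <- simConfigFromYaml(path)
  expect_identical(cfg@nMirnas, 50L)
  expect_identical(cfg@groupSizes, c(C = 4L, BD = 4L, SZ = 5L))
  expect_error(simConfigFromYaml({
    p2 <- withr::local_tempfile(fileext = ".yaml")
    writeLines("bogusField: 1", p2); p2
  }), "unknown")
})

test_that("qPCR wells follow the amplification model", {
  cfg <- simConfig(qpcrNoiseSd = 0, seed = 5L)
  ex <- rbind(t = c(400, 200), ref = c(500, 500))
  colnames(ex) <- c("sA", "sB")
  w <- simulateQpcr(cfg, ex, targets = "t", reference = "ref",
                    nPlates = 3L, nReplicates = 2L, slope = 1,
                    plateSd = 0)
  # 3 plates x 2 replicates per (sample, target)
  expect_identical(nrow(w[w$sample == "sA" & w$target == "t", ]), 6L)
  # 2-fold expression ratio at slope 1: CT differs by -1 cycle
  ctA <- unique(w$ct[w$sample == "sA" & w$target == "t"])
  ctB <- unique(w$ct[w$sample == "sB" & w$target == "t"])
  expect_equal(ctA - ctB, -log2(401 / 201), tolerance = 1e-12)
  # reference CT is identical in all samples when noise-free
  expect_length(unique(w$ct[w$target == "ref"]), 1L)
  expect_error(simulateQpcr(cfg, ex, targets = "nope", reference = "ref"),
               "not in expression")
})

test_that("truth table round-trips through JSON", {
  sim <- simulateExpression(simConfig(seed = 6L))
  path <- withr::local_tempfile(fileext = ".json")
  writeSimTruth(sim$truth, path)
  back <- readSimTruth(path)
  expect_setequal(names(back$spiked_mirnas), names(sim$truth$spiked_mirnas))
  expect_identical(back$spiked_mirnas[[1]]$group,
                   sim$truth$spiked_mirnas[[1]]$group)
})
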