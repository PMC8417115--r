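test_that("generated design covers 2 groups x 7 timepoints x n reps", {
  sim <- simulateProteome(nProteins = 40, seed = 1)
  pe <- sim$experiment
  expect_s4_class(pe, "ProteomeExperiment")
  expect_equal(dim(pe), c(40L, 56L))
  cd <- colData(pe)
  expect_equal(as.vector(table(cd$group)), c(28L, 28L))
  expect_true(all(table(cd$group, cd$timepoint) == 4))
  expect_true(all(assay(pe, "intensity") >= 0, na.rm = TRUE))
})

test_that("generation is deterministic and truth is self-consistent", {
  a <- simulateProteome(nProteins = 60, seed = 5)
  b <- simulateProteome(nProteins = 60, seed = 5)
  expect_identical(a, b)
  # every planted DE protein carries exactly one module label
  expect_setequal(names(a$truth$moduleLabel), a$truth$deProteins)
  expect_true(all(a$truth$moduleLabel %in% 1:6))
  # non-DE proteins have an all-zero planted profile
  nonDE <- setdiff(rownames(a$experiment), a$truth$deProteins)
  expect_true(all(a$truth$trueLog2FC[nonDE, ] == 0))
})

test_that("no planted effects means no systematic group difference", {
  sim <- simulateProteome(nProteins = 400, deFraction = 0, seed = 2,
                          censorQuantile = 0.01)
  x <- log2(assay(sim$experiment, "intensity"))
  cd <- colData(sim$experiment)
  d <- rowMeans(x[, cd$group == "YB1"], na.rm = TRUE) -
       rowMeans(x[, cd$group == "PBS"], na.rm = TRUE)
  # mean diff ~ N(0, ~noiseSd^2 * 2/28 / 400) -> tight Monte-Carlo band
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.05)
})

test_that("a flat planted effect shifts uncensored values by its size", {
  flat <- matrix(1, 6, 7)
  sim <- simulateProteome(nProteins = 500, deFraction = 1,
                          effectLog2FC = 2, moduleShapes = flat,
                          censorQuantile = 0.01, seed = 3)
  x <- log2(assay(sim$experiment, "intensity"))
  cd <- colData(sim$experiment)
  d <- rowMeans(x[, cd$group == "YB1"], na.rm = TRUE) -
       rowMeans(x[, cd$group == "PBS"], na.rm = TRUE)
  expect_lt(abs(mean(d, na.rm = TRUE) - 2), 0.05)
})

test_that("missingness is 1/2 at the censor point and monotone in intensity", {
  sim <- simulateProteome(nProteins = 3000, deFraction = 0, seed = 4)
  x <- sim$truth$logIntensity
  cen <- sim$truth$censoredMask
  cq <- sim$truth$censorPoint
  # cells whose underlying value sits at the censor point go missing
  # with probability 1/2 (logistic(0)); 3-binomial-SD Monte-Carlo band
  near <- abs(x - cq) < 0.05
  n <- sum(near)
  expect_gt(n, 1000)
  expect_lt(abs(mean(cen[near]) - 0.5), 3 * sqrt(0.25 / n))
  # empirical missing rate is non-increasing across intensity quintiles
  bins <- cut(x, breaks = quantile(x, 0:5 / 5), include.lowest = TRUE)
  rate <- tapply(as.vector(cen), bins, mean)
  expect_true(all(diff(rate) <= 1e-3))
})

test_that("degenerate replicate counts are rejected", {
  expect_error(simulateProteome(nReps = 1), "presence filter")
  expect_error(simulateProteome(moduleShapes = matrix(1, 2, 2)), "6 x 7")
})

test_that("module shape library peaks where documented", {
  sh <- defaultModuleShapes()
  expect_equal(unname(apply(sh[3:6, ], 1, which.max)), c(3, 4, 6, 7))
  expect_equal(unname(apply(sh[1:2, ], 1, which.min)), c(3, 4))
  expect_equal(unname(apply(abs(sh), 1, max)), rep(1, 6))
})
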