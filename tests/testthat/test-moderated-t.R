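randomMatrix <- function(n, seed, mu = 20, sd = 0.5) {
  set.seed(seed)
  matrix(rnorm(n * 8, mu, sd), n, 8,
         dimnames = list(sprintf("p%04d", seq_len(n)), paste0("s", 1:8)))
}

test_that("a degenerate variance spread yields an infinite prior", {
  pr <- fitModerationPrior(rep(4, 50), df = 6)
  expect_identical(dfPrior(pr), Inf)
  expect_equal(varPrior(pr), 4)
})

test_that("proteins without residual df are excluded from the fit", {
  s2 <- c(1.2, 0.9, 5)
  prAll <- fitModerationPrior(s2, df = c(6, 6, 0))
  prTwo <- fitModerationPrior(s2[1:2], df = 6)
  expect_equal(dfPrior(prAll), dfPrior(prTwo))
  expect_equal(varPrior(prAll), varPrior(prTwo))
  expect_error(fitModerationPrior(c(1, 1), df = c(0, 0)), ">= 2 proteins")
})

test_that("the moment fit matches the independent limma fit", {
  skip_if_not_installed("limma")
  set.seed(11)
  sg2 <- 1.5 * (rchisq(5000, 6) / 6) / (rchisq(5000, 5) / 5)
  pr <- fitModerationPrior(sg2, df = 6)
  fl <- limma::fitFDist(sg2, df1 = rep(6, length(sg2)))
  expect_equal(dfPrior(pr), fl$df2, tolerance = 1e-8)
  expect_equal(varPrior(pr), fl$scale, tolerance = 1e-8)
})

test_that("d0 = 0 reduces the moderated t to the pooled two-sample t", {
  x <- randomMatrix(30, seed = 21)
  prior0 <- new("ModerationPrior", dfPrior = 0, varPrior = 1)
  r <- moderatedTTest(x, "2d", prior = prior0, design = nullDesign())
  for (i in c(1, 7, 30)) {
    o <- pooledTOracle(x[i, 1:4], x[i, 5:8])
    expect_equal(r$t[i], o$t, tolerance = 1e-12)
    expect_equal(r$p[i], o$p, tolerance = 1e-12)
  }
})

test_that("identical groups give zero fold change and p = 1", {
  x <- matrix(rep(c(10, 12, 11, 13), 4), 2, 8, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:8)))
  x[2, ] <- x[2, ] + c(0.3, -0.1, 0.2, 0, 0.25, 0.05, 0.1, 0)
  r <- moderatedTTest(x, "2d", design = nullDesign())
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$p[1], 1, tolerance = 1e-12)
})

test_that("the moderated statistic matches a hand-coded evaluation", {
  x <- randomMatrix(20, seed = 31)
  prior <- new("ModerationPrior", dfPrior = 4, varPrior = 1)
  r <- moderatedTTest(x, "2d", prior = prior, design = nullDesign())
  for (i in c(2, 9, 20)) {
    a <- x[i, 1:4]; b <- x[i, 5:8]
    sg2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 6
    spost <- (4 * 1 + 6 * sg2) / (4 + 6)
    tmod <- (mean(a) - mean(b)) / sqrt(spost * (1 / 4 + 1 / 4))
    expect_equal(r$t[i], tmod, tolerance = 1e-12)
    expect_equal(r$p[i], 2 * pt(-abs(tmod), 10), tolerance = 1e-12)
  }
})

test_that("moderated t agrees with the limma implementation end to end", {
  skip_if_not_installed("limma")
  # heterogeneous true variances give a finite prior d0, away from
  # limma's total-df cap, so the two routes must agree numerically
  set.seed(41)
  sd <- sqrt(1 / rgamma(400, shape = 3, rate = 1))
  x <- randomMatrix(400, seed = 41) * 0 +
    matrix(rnorm(400 * 8, 0, sd), 400, 8)
  dimnames(x) <- list(sprintf("p%04d", 1:400), paste0("s", 1:8))
  r <- moderatedTTest(x, "2d", design = nullDesign())
  design <- cbind(PBS = 1, YB1vsPBS = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(r$t, fit$t[, "YB1vsPBS"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r$p, fit$p.value[, "YB1vsPBS"], tolerance = 1e-8,
               ignore_attr = TRUE)
  pr <- attr(r, "prior")
  expect_equal(dfPrior(pr), fit$df.prior, tolerance = 1e-6)
  expect_equal(varPrior(pr), fit$s2.prior, tolerance = 1e-6)
})

test_that("moderated t is monotone in |log2fc| at fixed variance", {
  prior <- new("ModerationPrior", dfPrior = 4, varPrior = 1)
  base <- c(10, 11, 9, 10)
  ts <- sapply(c(0.5, 1, 2, 4), function(d) {
    x <- rbind(p1 = c(base + d, base))
    colnames(x) <- paste0("s", 1:8)
    abs(moderatedTTest(x, "2d", prior = prior, design = nullDesign())$t)
  })
  expect_true(all(diff(ts) > 0))
})

test_that("proteins with under two values per group are skipped", {
  x <- randomMatrix(3, seed = 51)
  x[2, 1:3] <- NA
  r <- moderatedTTest(x, "2d", design = nullDesign())
  expect_equal(nrow(r), 2)
  sk <- attr(r, "skipped")
  expect_equal(sk$protein, "p0002")
  expect_match(sk$reason, "n1=1")
})

test_that("DE calling applies the boundary conventions", {
  r <- data.frame(protein = c("a", "b", "c", "d"), timepoint = "2d",
                  log2fc = c(1.0, 0.99, -1.2, 3),
                  t = 1, df = 6,
                  p = c(0.05, 0.001, 0.04, 0.2), n1 = 4, n2 = 4)
  out <- callDE(r)
  expect_identical(out$results$de, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$unionCount, 2)
  expect_equal(unname(out$countsByTimepoint["2d"]), 2)
  # the literal natural-scale reading is one-sided with strict cutoffs
  nat <- callDE(r, scale = "natural")
  expect_identical(nat$results$de, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$results$p_adj, p.adjust(r$p, method = "BH"))
})

test_that("the full cascade flags planted effects over null proteins", {
  sim <- simulateProteome(nProteins = 300, seed = 61)
  de <- runDEPipeline(sim$experiment, seed = 61)
  flagged <- unique(de$results$protein[de$results$de])
  planted <- sim$truth$deProteins
  sens <- length(intersect(flagged, planted)) / length(planted)
  expect_gt(sens, 0.6)
  expect_true(all(c("p_adj", "de") %in% colnames(de$results)))
  expect_equal(sum(de$countsByTimepoint),
               sum(de$results$de))
})
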