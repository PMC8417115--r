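test_that("profiles carry log2fc at tested timepoints and 0 elsewhere", {
  r <- data.frame(protein = "P1", timepoint = "2d", log2fc = 2.9,
                  t = 9, df = 6, p = 1e-4, n1 = 4, n2 = 4,
                  p_adj = 1e-4, de = TRUE)
  b <- buildProfiles(r)
  expect_equal(unname(b$profiles["P1", ]), c(0, 0, 0, 2.9, 0, 0, 0))
  expect_equal(unname(b$filled["P1", ]), c(T, T, T, F, T, T, T))
  expect_error(buildProfiles(transform(r, de = FALSE)), "no differentially")
})

test_that("profile matrix has one row per DE protein", {
  sim <- simulateProteome(nProteins = 300, seed = 71)
  de <- runDEPipeline(sim$experiment, seed = 71)
  b <- buildProfiles(de$results)
  expect_equal(nrow(b$profiles), de$unionCount)
  expect_equal(colnames(b$profiles), timepointLevels())
  # profiled log2fc tracks the planted effect for strong DE proteins
  planted <- intersect(rownames(b$profiles), sim$truth$deProteins)
  err <- b$profiles[planted, ] - sim$truth$trueLog2FC[planted, ]
  err <- err[!b$filled[planted, ]]
  expect_lt(median(abs(err)), 0.5)
})

test_that("k = 1 returns the column-mean centroid", {
  set.seed(1)
  x <- matrix(rnorm(70), 10, 7)
  km <- kmeansModules(x, k = 1, nInit = 3, seed = 1)
  expect_equal(as.numeric(km$centers), colMeans(x))
  expect_equal(km$withinSS, sum(sweep(x, 2, colMeans(x))^2))
})

test_that("six exactly repeated rows partition perfectly at k = 6", {
  arch <- matrix(rnorm(42, sd = 5), 6, 7)
  x <- arch[rep(1:6, each = 10), ]
  km <- kmeansModules(x, k = 6, nInit = 10, seed = 2)
  expect_equal(km$withinSS, 0)
  expect_equal(sort(km$sizes), rep(10L, 6))
  expect_equal(length(unique(km$labels[1:10])), 1)
})

test_that("clustering is deterministic given the seed", {
  set.seed(3)
  x <- matrix(rnorm(350), 50, 7)
  a <- kmeansModules(x, k = 4, nInit = 10, seed = 9)
  b <- kmeansModules(x, k = 4, nInit = 10, seed = 9)
  expect_identical(a, b)
  expect_error(kmeansModules(x[1:3, ], k = 6), "exceeds")
})

test_that("the final assignment is a fixed point of Lloyd's update", {
  set.seed(4)
  x <- matrix(rnorm(420), 60, 7)
  km <- kmeansModules(x, k = 5, nInit = 20, seed = 5)
  d2 <- outer(rowSums(x^2), rowSums(km$centers^2), "+") -
    2 * x %*% t(km$centers)
  expect_equal(unname(max.col(-d2, ties.method = "first")),
               unname(km$labels))
  # centroids are the means of their members
  for (j in seq_len(5)) {
    mem <- x[km$labels == j, , drop = FALSE]
    expect_equal(unname(km$centers[j, ]), colMeans(mem), tolerance = 1e-12)
  }
})

test_that("within-SS never beats the stats::kmeans optimum on easy data", {
  set.seed(6)
  x <- rbind(matrix(rnorm(140, 0), 20, 7),
             matrix(rnorm(140, 8), 20, 7))
  mine <- kmeansModules(x, k = 2, nInit = 10, seed = 7)
  ref <- stats::kmeans(x, centers = 2, nstart = 10,
                       algorithm = "Lloyd")
  expect_equal(mine$withinSS, ref$tot.withinss, tolerance = 1e-8)
})

test_that("well-separated archetypes are recovered almost perfectly", {
  skip_if_not_installed("mclust")
  set.seed(8)
  arch <- defaultModuleShapes() * 10
  labels <- rep(1:6, each = 20)
  x <- arch[labels, ] + matrix(rnorm(120 * 7, sd = 0.3), 120, 7)
  km <- kmeansModules(x, k = 6, nInit = 30, seed = 10)
  ari <- mclust::adjustedRandIndex(km$labels, labels)
  expect_gte(ari, 0.95)
  # label permutation leaves the ARI unchanged
  perm <- c(3, 1, 2, 6, 4, 5)[km$labels]
  expect_equal(mclust::adjustedRandIndex(perm, labels), ari)
})

test_that("two points merge at half their squared distance", {
  x <- rbind(c(0, 0, 0, 0, 0, 0, 0), c(2, 0, 0, 0, 1, 0, 0))
  w <- wardHclust(x)
  expect_equal(w$tree$height, sum((x[1, ] - x[2, ])^2) / 2)
})

test_that("far pairs are isolated by cutting the Ward tree", {
  x <- rbind(c(0, 0), c(0, 1), c(50, 50), c(50, 51), c(-40, 0), c(-40, 1))
  w <- wardHclust(x, k = 3)
  expect_equal(length(unique(w$labels)), 3)
  expect_equal(w$labels[1], w$labels[2])
  expect_equal(w$labels[3], w$labels[4])
  expect_equal(w$labels[5], w$labels[6])
  expect_true(all(diff(w$tree$height) >= 0))  # monotone merge heights
  expect_error(wardHclust(x[1, , drop = FALSE]), "at least 2")
})

test_that("the merge sequence equals brute-force Ward agglomeration", {
  set.seed(12)
  x <- matrix(rnorm(16), 8, 2)
  w <- wardHclust(x)
  bf <- wardBruteForce(x)
  expect_equal(hclustMemberSets(w$tree), bf$members)
  expect_equal(w$tree$height, bf$heights, tolerance = 1e-10)
})

test_that("module summaries report peak timepoints and counts", {
  prof <- rbind(a = c(0, 1, 3, 1, 0, 0, 0),
                b = c(0, 1, 2.6, 1, 0, 0, 0),
                c = c(0, 0, 0, 0, 0, 1, 2))
  colnames(prof) <- timepointLevels()
  labels <- c(a = 1, b = 1, c = 2)
  s <- moduleSummary(labels, prof)
  expect_equal(s$peakTimepoint, c("24h", "14d"))
  expect_equal(sum(s$n), 3)
  # a single-member module's centroid is that row
  expect_equal(unlist(s[2, timepointLevels()]), prof["c", ],
               ignore_attr = TRUE)
})
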