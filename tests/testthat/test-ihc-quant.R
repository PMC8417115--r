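test_that("optical density transform matches its defining formula", {
  expect_equal(as.numeric(rgbToOD(array(255, c(1, 1, 3)))), c(0, 0, 0))
  od <- rgbToOD(array(26, c(1, 1, 3)))
  expect_equal(as.numeric(od), rep(-log10(26 / 255), 3), tolerance = 1e-12)
  expect_equal(round(as.numeric(od), 4), rep(0.9916, 3))
  # zero intensity clamps to 1 before the log
  od0 <- rgbToOD(array(c(0, 255, 255), c(1, 1, 3)))
  expect_equal(as.numeric(od0), c(-log10(1 / 255), 0, 0), tolerance = 1e-12)
  expect_error(rgbToOD(matrix(1, 2, 2)), "RGB")
})

test_that("deconvolution solves the 3x3 unmixing exactly", {
  sm <- hdabStainMatrix()
  m <- stainBasis(sm)
  # a pure stain OD unmixes to a unit concentration
  od <- array(m["hematoxylin", ], c(1, 1, 3))
  expect_equal(as.numeric(deconvolveStains(od, sm)), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(deconvolveStains(array(0, c(1, 1, 3)), sm)),
               c(0, 0, 0))
  # random non-negative concentrations round-trip through the forward map
  set.seed(1)
  conc <- matrix(runif(300, 0, 2), 100, 3)
  od <- array(conc %*% m, c(10, 10, 3))
  back <- matrix(deconvolveStains(od, sm), ncol = 3)
  expect_lt(max(abs(back - conc)), 1e-9)
})

test_that("vectorized unmixing equals a per-pixel linear solve", {
  set.seed(42)
  m <- stainBasis(hdabStainMatrix())
  od <- array(runif(3000, 0, 2), c(50, 20, 3))
  fast <- matrix(deconvolveStains(od, hdabStainMatrix()), ncol = 3)
  slow <- t(apply(matrix(od, ncol = 3), 1, function(v)
    solve(t(m), v)))
  expect_lt(max(abs(fast - slow)), 1e-9)
})

test_that("signal channel maps concentration monotonically onto 0-255", {
  expect_equal(stainSignal(matrix(0)), matrix(0))
  expect_equal(stainSignal(matrix(-3)), matrix(0))  # clipped negatives
  expect_equal(stainSignal(matrix(1)), matrix(230)) # 255 * 0.9
  expect_equal(stainSignal(matrix(50)), matrix(255))
  s <- stainSignal(matrix(seq(0, 3, by = 0.01), nrow = 1))
  expect_true(all(diff(as.numeric(s)) >= 0))
})

test_that("binarization counts pixels at or above the threshold", {
  sig <- matrix(c(0, 10, 70, 69, 230, 255), 2)
  expect_equal(binarizeSignal(sig, 70)$count, 3)
  expect_equal(binarizeSignal(sig, 0)$count, 6)
  expect_equal(binarizeSignal(matrix(0, 5, 5), 1)$count, 0)
  # exhaustive per-pixel comparison oracle at the iNOS threshold
  set.seed(2)
  sig <- matrix(sample(0:255, 400, TRUE), 20)
  thr <- markerThresholds()[["iNOS"]]
  expect_equal(binarizeSignal(sig, thr)$count, sum(sig >= thr))
  expect_error(binarizeSignal(sig, 300), "0, 255")
})

test_that("default thresholds carry the published per-marker values", {
  expect_equal(markerThresholds(),
               c(C3 = 70, CD3 = 10, CD11c = 30, CD68 = 20, `F4/80` = 70,
                 iNOS = 70, Ly6G = 25, CD19 = 10))
})

test_that("grid ROIs tile the frame and random ROIs are seeded", {
  g <- extractROIs(240, 144, nRois = 9)
  expect_equal(nrow(g), 9)
  expect_equal(sort(unique(g$x0)), c(1, 81, 161))
  expect_equal(sort(unique(g$y0)), c(1, 49, 97))
  expect_true(all(g$x0 + g$w - 1 <= 240 & g$y0 + g$h - 1 <= 144))
  one <- extractROIs(80, 48, nRois = 1, roiWidthPx = 80, roiHeightPx = 48)
  expect_equal(unlist(one), c(roi = 1, x0 = 1, y0 = 1, w = 80, h = 48))
  r1 <- extractROIs(240, 144, nRois = 4, mode = "random", seed = 5)
  r2 <- extractROIs(240, 144, nRois = 4, mode = "random", seed = 5)
  expect_identical(r1, r2)
  expect_warning(extractROIs(240, 144, nRois = 9, mode = "random"),
                 "allowing overlap")
  expect_error(extractROIs(50, 50, roiWidthPx = 60, roiHeightPx = 10),
               "smaller than one ROI")
})

test_that("S/N arithmetic and the undefined-ROI contract hold", {
  n <- matrix(FALSE, 50, 100); n[1:50, 1:40] <- TRUE   # 2000 px
  s <- matrix(FALSE, 50, 100); s[1:20, 1:50] <- TRUE   # 1000 px
  r <- computeSN(s, n)
  expect_equal(r$ratio, 0.5)
  expect_true(r$defined)
  empty <- computeSN(s, matrix(FALSE, 50, 100))
  expect_false(empty$defined)
  expect_true(is.na(empty$ratio))
  zero <- computeSN(matrix(FALSE, 50, 100), n)
  expect_equal(zero$ratio, 0)
  expect_error(computeSN(s, matrix(FALSE, 2, 2)), "identical dimensions")
})

test_that("quantifyMarker preserves ROI order and trivial cases", {
  sim <- simulateIHCImage(seed = 5, nMarkerBlobs = 0)
  rois <- extractROIs(240, 144, nRois = 9)
  q <- quantifyMarker(sim$image, "iNOS", rois = rois)
  expect_equal(nrow(q), 9)
  expect_equal(q$roi, 1:9)
  expect_true(all(q$ratio[q$defined] == 0))  # no marker stain anywhere
  expect_error(quantifyMarker(sim$image, "nope"), "no threshold")
})

test_that("planted cohort differences order the mean ratios", {
  hi <- simulateIHCCohort(nImages = 1, nMarkerBlobs = 12, seed = 21)
  lo <- simulateIHCCohort(nImages = 1, nMarkerBlobs = 3, seed = 22)
  expect_gt(mean(hi$ratio[hi$defined]), mean(lo$ratio[lo$defined]))
})
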