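#' Simulate a two-stain brightfield IHC image with known ground truth
#'
#' Composites an 8-bit RGB tumor-section-like image in optical-density
#' space under the Beer-Lambert model: elliptical hematoxylin-stained
#' nuclei and DAB-like marker-positive blobs are painted as per-pixel
#' stain amounts `a`, and each channel is rendered as
#' `I_c = round(255 * 10^-(a %*% M)_c)` with `M` the stain basis
#' ([hdabStainMatrix()] by default). Optional Gaussian read noise is
#' added in intensity space after quantization, then clipped to
#' \[0, 255\]. The exact painted masks and their area ratio S/N are
#' returned as ground truth.
#'
#' Nuclei are ellipses with uniform random centers, semi-axes and
#' orientation. With `allowOverlap = FALSE` (default) nuclei are placed
#' by rejection sampling with a 2 px separation margin so that planted
#' nuclei stay disjoint connected components; placement gives up with an
#' error after `maxAttempts` rejected draws per nucleus. Marker blobs
#' are ellipses that may overlap anything.
#'
#' @param widthPx,heightPx image size in pixels.
#' @param nNuclei number of hematoxylin nuclei to paint.
#' @param nucleusAxesPx length-2 range of nucleus semi-axes in px.
#' @param hematoxylinAmount stain amount (OD units) inside nuclei.
#' @param nMarkerBlobs number of marker-positive blobs.
#' @param markerAxesPx length-2 range of marker blob semi-axes in px.
#' @param markerAmount stain amount (OD units) inside marker blobs.
#' @param noiseSd Gaussian noise SD in 8-bit intensity units (0 = none).
#' @param allowOverlap allow nuclei to overlap each other.
#' @param micronsPerPx physical pixel size, metadata only (default
#'   0.25 um/px, a typical 40x scan).
#' @param stainMatrix the compositing [StainMatrix][StainMatrix-class].
#' @param maxAttempts rejection-sampling cap per nucleus.
#' @param seed integer seed; identical seed and parameters give a
#'   bit-identical image.
#' @return list with elements
#'   \describe{
#'     \item{image}{`heightPx x widthPx x 3` array of 8-bit intensities.}
#'     \item{truth}{list: `nucleiMask`, `markerMask` (logical matrices),
#'       `trueSN` (marker px / nuclei px; `NA` when no nuclei),
#'       `nNuclei`, `micronsPerPx`.}
#'   }
#' @examples
#' sim <- simulateIHCImage(widthPx = 80, heightPx = 60, nNuclei = 4,
#'                         nMarkerBlobs = 2, seed = 1)
#' sim$truth$trueSN
#' @export
simulateIHCImage <- function(widthPx = 240, heightPx = 144,
                             nNuclei = 12, nucleusAxesPx = c(5, 9),
                             hematoxylinAmount = 0.6,
                             nMarkerBlobs = 6, markerAxesPx = c(4, 8),
                             markerAmount = 0.8,
                             noiseSd = 0, allowOverlap = FALSE,
                             micronsPerPx = 0.25,
                             stainMatrix = hdabStainMatrix(),
                             maxAttempts = 500L, seed = 1L) {
    stopifnot(widthPx >= 1, heightPx >= 1, nNuclei >= 0, nMarkerBlobs >= 0,
              noiseSd >= 0, micronsPerPx > 0)
    if (hematoxylinAmount < 0 || markerAmount < 0)
        stop("stain amounts must be non-negative")
    if (any(nucleusAxesPx <= 0) || any(markerAxesPx <= 0))
        stop("ellipse semi-axes must be positive")
    if (2 * max(nucleusAxesPx) > min(widthPx, heightPx))
        stop("nucleus axes larger than the image")
    set.seed(seed)

    nucMask <- matrix(FALSE, heightPx, widthPx)
    for (i in seq_len(nNuclei)) {
        placed <- FALSE
        for (att in seq_len(maxAttempts)) {
            e <- randomEllipse(widthPx, heightPx, nucleusAxesPx)
            m <- ellipseMask(widthPx, heightPx, e)
            if (allowOverlap) {
                nucMask <- nucMask | m; placed <- TRUE; break
            }
            # 2 px separation margin keeps components disjoint after labelling
            pad <- ellipseMask(widthPx, heightPx,
                               modifyList(e, list(a = e$a + 2, b = e$b + 2)))
            if (!any(pad & nucMask)) {
                nucMask <- nucMask | m; placed <- TRUE; break
            }
        }
        if (!placed)
            stop(sprintf(
                "could not place nucleus %d without overlap in %d attempts",
                i, maxAttempts))
    }

    mrkMask <- matrix(FALSE, heightPx, widthPx)
    for (i in seq_len(nMarkerBlobs)) {
        e <- randomEllipse(widthPx, heightPx, markerAxesPx)
        mrkMask <- mrkMask | ellipseMask(widthPx, heightPx, e)
    }

    amounts <- cbind(hematoxylin = as.numeric(nucMask) * hematoxylinAmount,
                     marker = as.numeric(mrkMask) * markerAmount,
                     residual = 0)
    od <- amounts %*% stainBasis(stainMatrix)
    img <- round(255 * 10^(-od))
    if (noiseSd > 0) {
        img <- img + stats::rnorm(length(img), sd = noiseSd)
        img <- round(pmin(pmax(img, 0), 255))
    }
    img <- array(img, dim = c(heightPx, widthPx, 3))

    trueSN <- if (any(nucMask)) sum(mrkMask) / sum(nucMask) else NA_real_
    list(image = img,
         truth = list(nucleiMask = nucMask, markerMask = mrkMask,
                      trueSN = trueSN, nNuclei = nNuclei,
                      micronsPerPx = micronsPerPx))
}

randomEllipse <- function(widthPx, heightPx, axesRange) {
    a <- stats::runif(1, min(axesRange), max(axesRange))
    b <- stats::runif(1, min(axesRange), max(axesRange))
    amax <- max(a, b)
    list(cx = stats::runif(1, amax + 1, widthPx - amax),
         cy = stats::runif(1, amax + 1, heightPx - amax),
         a = a, b = b, theta = stats::runif(1, 0, pi))
}

ellipseMask <- function(widthPx, heightPx, e) {
    x <- matrix(seq_len(widthPx), heightPx, widthPx, byrow = TRUE) - e$cx
    y <- matrix(seq_len(heightPx), heightPx, widthPx) - e$cy
    u <- x * cos(e$theta) + y * sin(e$theta)
    v <- -x * sin(e$theta) + y * cos(e$theta)
    (u / e$a)^2 + (v / e$b)^2 <= 1
}

#' Simulate and quantify an imaging cohort
#'
#' Generates `nImages` replicate IHC images for one experimental group
#' and quantifies a marker on each over a 3 x 3 ROI grid, pooling
#' per-ROI S/N ratios across images — the standard scheme of 3
#' replicate sections x 9 views. The marker-positive area is controlled
#' by `nMarkerBlobs`, so a treated vs control contrast is planted by
#' passing different blob counts to two calls.
#'
#' @param nImages replicate images (default 3).
#' @param nRois ROIs per image laid out as a grid (default 9).
#' @param marker marker name for thresholding (default `"iNOS"`).
#' @param seed integer seed; image i uses `seed * 1000 + i` so cohorts
#'   with different base seeds are independent.
#' @param nNuclei,nMarkerBlobs,noiseSd,... forwarded to
#'   [simulateIHCImage()].
#' @return data.frame of pooled [quantifyMarker()] rows with an added
#'   `image` column.
#' @examples
#' ctrl <- simulateIHCCohort(nImages = 1, nMarkerBlobs = 3, seed = 1)
#' nrow(ctrl)
#' @export
simulateIHCCohort <- function(nImages = 3L, nRois = 9L, marker = "iNOS",
                              seed = 1L, nNuclei = 36L, nMarkerBlobs = 4L,
                              noiseSd = 0, ...) {
    out <- lapply(seq_len(nImages), function(i) {
        sim <- simulateIHCImage(nNuclei = nNuclei,
                                nMarkerBlobs = nMarkerBlobs,
                                noiseSd = noiseSd,
                                seed = seed * 1000L + i, ...)
        rois <- extractROIs(ncol(sim$truth$nucleiMask),
                            nrow(sim$truth$nucleiMask), nRois)
        cbind(image = i, quantifyMarker(sim$image, marker, rois = rois))
    })
    do.call(rbind, out)
}
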