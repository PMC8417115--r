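#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert transform `OD_c = -log10(max(I_c, 1) / 255)`
#' per channel. Intensities are clamped to at least 1 before the log so a
#' fully absorbed pixel maps to the finite maximum OD `log10(255)`;
#' a blank (255) pixel maps to OD 0 exactly.
#'
#' @param rgb numeric `h x w x 3` array of 8-bit intensities (0-255).
#' @return `h x w x 3` array of optical densities (>= 0).
#' @examples
#' rgbToOD(array(255, c(1, 1, 3)))  # blank field -> 0 OD
#' @export
rgbToOD <- function(rgb) {
    if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
        stop("expected an h x w x 3 RGB array")
    -log10(pmax(rgb, 1) / 255)
}

#' Unmix an OD image into per-stain concentration maps
#'
#' Per-pixel linear color deconvolution: with stain basis `M` (rows =
#' stains, unit OD vectors) and pixel OD row-vector `od`, the stain
#' amounts are `c = od %*% solve(M)`. Small negative amounts can arise
#' from noise and are retained here for diagnostics; [stainSignal()]
#' clips them when building the 0-255 signal channel.
#'
#' @param od `h x w x 3` OD array from [rgbToOD()].
#' @param stainMatrix a [StainMatrix][StainMatrix-class].
#' @return `h x w x 3` array of stain amounts; third dimension named by
#'   stain.
#' @examples
#' img <- simulateIHCImage(widthPx = 40, heightPx = 30, seed = 1)$image
#' conc <- deconvolveStains(rgbToOD(img), hdabStainMatrix())
#' dimnames(conc)[[3]]
#' @export
deconvolveStains <- function(od, stainMatrix = hdabStainMatrix()) {
    if (length(dim(od)) != 3L || dim(od)[3] != 3L)
        stop("expected an h x w x 3 OD array")
    m <- stainBasis(stainMatrix)
    conc <- matrix(od, ncol = 3L) %*% solve(m)
    array(conc, dim = dim(od),
          dimnames = list(NULL, NULL, rownames(m)))
}

#' Map a stain concentration map to an 8-bit signal channel
#'
#' `s = round(255 * (1 - 10^-max(c, 0)))`: the intensity a pure stain of
#' amount `c` would absorb, a monotone map of concentration onto the
#' 0-255 scale on which the marker thresholds are defined.
#'
#' @param concMap numeric matrix (one stain's concentration map).
#' @return integer-valued matrix in \[0, 255\].
#' @examples
#' stainSignal(matrix(c(0, 1), 1))  # 0 and round(255 * 0.9) = 230
#' @export
stainSignal <- function(concMap) {
    if (any(!is.finite(concMap)))
        stop("concentration map contains non-finite values")
    round(255 * (1 - 10^(-pmax(concMap, 0))))
}

#' Default marker binarization thresholds
#'
#' Per-marker thresholds on the 0-255 stain-signal scale used to extract
#' stained area: C3 70, CD3 10, CD11c 30, CD68 20, F4/80 70, iNOS 70,
#' Ly6G 25, CD19 10.
#'
#' @return named numeric vector of thresholds.
#' @examples markerThresholds()["iNOS"]
#' @export
markerThresholds <- function() {
    c(C3 = 70, CD3 = 10, CD11c = 30, CD68 = 20,
      `F4/80` = 70, iNOS = 70, Ly6G = 25, CD19 = 10)
}

#' Binarize a stain signal channel
#'
#' A pixel is called stained iff `signal >= threshold`.
#'
#' @param signal matrix from [stainSignal()].
#' @param threshold numeric threshold in \[0, 255\].
#' @return list with `mask` (logical matrix) and `count` (stained px).
#' @examples
#' binarizeSignal(matrix(c(0, 80, 230), 1), 70)$count
#' @export
binarizeSignal <- function(signal, threshold) {
    if (length(threshold) != 1L || threshold < 0 || threshold > 255)
        stop("threshold must be a single value in [0, 255]")
    mask <- signal >= threshold
    list(mask = mask, count = sum(mask))
}

#' Lay out regions of interest over an image
#'
#' Automated counterpart of manual ROI selection: either a deterministic
#' grid tiling (default) or seeded random placement of non-overlapping
#' rectangles (falling back to overlapping placement with a warning when
#' rejection sampling cannot fit them).
#'
#' @param widthPx,heightPx image size in pixels.
#' @param nRois number of ROIs (default 9, the standard scheme).
#' @param roiWidthPx,roiHeightPx ROI size; defaults tile the image into
#'   an approximately square grid in grid mode.
#' @param mode `"grid"` or `"random"`.
#' @param seed seed for random mode (ignored for grid).
#' @param maxAttempts rejection cap in random mode.
#' @return data.frame with columns `roi`, `x0`, `y0`, `w`, `h`
#'   (1-based top-left corner).
#' @examples
#' extractROIs(240, 144, nRois = 9)
#' @export
extractROIs <- function(widthPx, heightPx, nRois = 9L,
                        roiWidthPx = NULL, roiHeightPx = NULL,
                        mode = c("grid", "random"), seed = 1L,
                        maxAttempts = 1000L) {
    mode <- match.arg(mode)
    if (mode == "grid") {
        nc <- ceiling(sqrt(nRois))
        nr <- ceiling(nRois / nc)
        if (is.null(roiWidthPx)) roiWidthPx <- widthPx %/% nc
        if (is.null(roiHeightPx)) roiHeightPx <- heightPx %/% nr
    } else {
        if (is.null(roiWidthPx)) roiWidthPx <- widthPx %/% 3
        if (is.null(roiHeightPx)) roiHeightPx <- heightPx %/% 3
    }
    if (roiWidthPx > widthPx || roiHeightPx > heightPx)
        stop("image smaller than one ROI")
    if (mode == "grid") {
        nc <- ceiling(sqrt(nRois))
        nr <- ceiling(nRois / nc)
        xs <- round(seq(1, widthPx - roiWidthPx + 1, length.out = nc))
        ys <- round(seq(1, heightPx - roiHeightPx + 1, length.out = nr))
        g <- expand.grid(x0 = xs, y0 = ys)[seq_len(nRois), ]
        return(data.frame(roi = seq_len(nRois), x0 = g$x0, y0 = g$y0,
                          w = roiWidthPx, h = roiHeightPx))
    }
    set.seed(seed)
    picked <- matrix(numeric(0), ncol = 2)
    att <- 0L
    overlapOK <- FALSE
    while (nrow(picked) < nRois) {
        att <- att + 1L
        if (att > maxAttempts && !overlapOK) {
            warning("could not place non-overlapping ROIs; allowing overlap")
            overlapOK <- TRUE
        }
        x0 <- sample.int(widthPx - roiWidthPx + 1L, 1L)
        y0 <- sample.int(heightPx - roiHeightPx + 1L, 1L)
        clash <- nrow(picked) > 0 && any(
            abs(picked[, 1] - x0) < roiWidthPx &
            abs(picked[, 2] - y0) < roiHeightPx)
        if (!clash || overlapOK)
            picked <- rbind(picked, c(x0, y0))
    }
    data.frame(roi = seq_len(nRois), x0 = picked[, 1], y0 = picked[, 2],
               w = roiWidthPx, h = roiHeightPx)
}

cropROI <- function(m, roi) {
    m[roi$y0:(roi$y0 + roi$h - 1L), roi$x0:(roi$x0 + roi$w - 1L)]
}

#' Stained-area to nucleus-area ratio within an ROI
#'
#' Counts stained pixels (S) and nucleus pixels (N) inside one ROI and
#' forms the expression statistic S/N. An ROI without any segmented
#' nucleus yields an undefined ratio (`defined = FALSE`); such ROIs are
#' excluded from group statistics downstream.
#'
#' @param stainedMask logical matrix of stained pixels (whole image).
#' @param nucleusMask logical matrix of nucleus pixels, same shape.
#' @param roi one row of [extractROIs()] output (default: whole frame).
#' @return data.frame with `S_px`, `N_px`, `ratio`, `defined`.
#' @examples
#' s <- matrix(FALSE, 4, 4); s[1, 1:2] <- TRUE
#' n <- matrix(TRUE, 4, 4)
#' computeSN(s, n)$ratio  # 2/16
#' @export
computeSN <- function(stainedMask, nucleusMask, roi = NULL) {
    if (!identical(dim(stainedMask), dim(nucleusMask)))
        stop("masks must have identical dimensions")
    if (!is.null(roi)) {
        stainedMask <- cropROI(stainedMask, roi)
        nucleusMask <- cropROI(nucleusMask, roi)
    }
    S <- sum(stainedMask)
    N <- sum(nucleusMask)
    data.frame(S_px = S, N_px = N,
               ratio = if (N > 0) S / N else NA_real_,
               defined = N > 0)
}

#' Quantify one marker on an IHC image
#'
#' The full brightfield quantification chain per ROI: RGB -> OD ->
#' color deconvolution -> marker signal channel -> threshold
#' binarization (stained area S), in parallel with level-set nucleus
#' segmentation of the hematoxylin channel (nucleus area N), combined
#' as S/N per ROI.
#'
#' @param rgb `h x w x 3` 8-bit RGB array.
#' @param marker marker name; must be present in `thresholds`.
#' @param stainMatrix a [StainMatrix][StainMatrix-class].
#' @param thresholds named thresholds as from [markerThresholds()].
#' @param rois data.frame from [extractROIs()]; default one whole-frame
#'   ROI.
#' @param minAreaPx minimum nucleus component area (px) kept by the
#'   segmentation.
#' @param levelSetParams list of Chan-Vese controls passed to
#'   [segmentNuclei()] (`mu`, `maxIter`, `tol`).
#' @return data.frame, one row per ROI in input order, with columns
#'   `marker`, `roi`, `S_px`, `N_px`, `ratio`, `defined`.
#' @examples
#' sim <- simulateIHCImage(widthPx = 90, heightPx = 60, nNuclei = 5,
#'                         nMarkerBlobs = 2, seed = 3)
#' quantifyMarker(sim$image, "iNOS")
#' @export
quantifyMarker <- function(rgb, marker,
                           stainMatrix = hdabStainMatrix(),
                           thresholds = markerThresholds(),
                           rois = NULL, minAreaPx = 40L,
                           levelSetParams = list()) {
    if (!marker %in% names(thresholds))
        stop(sprintf("no threshold for marker '%s'", marker))
    conc <- deconvolveStains(rgbToOD(rgb), stainMatrix)
    signal <- stainSignal(conc[, , "marker"])
    stained <- binarizeSignal(signal, thresholds[[marker]])$mask
    hema <- conc[, , "hematoxylin"]
    if (is.null(rois))
        rois <- data.frame(roi = 1L, x0 = 1L, y0 = 1L,
                           w = ncol(hema), h = nrow(hema))
    out <- lapply(seq_len(nrow(rois)), function(i) {
        roi <- rois[i, ]
        seg <- do.call(segmentNuclei,
                       c(list(cropROI(hema, roi), minAreaPx = minAreaPx),
                         levelSetParams))
        sn <- computeSN(cropROI(stained, roi), seg$labels > 0)
        cbind(marker = marker, roi = roi$roi, sn,
              nNuclei = seg$count)
    })
    do.call(rbind, out)
}
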