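#' Segment nuclei from a hematoxylin concentration map
#'
#' Region-based (piecewise-constant, Chan-Vese) level-set segmentation.
#' The map is rescaled to \[0, 1\], the contour is initialized from an
#' Otsu threshold, and the level-set function is evolved by explicit
#' gradient descent on the Chan-Vese energy (curvature weight `mu`,
#' regularized delta) for at most `maxIter` iterations, stopping early
#' when the foreground stops changing. The final foreground is split
#' into connected components; components smaller than `minAreaPx` are
#' discarded and the rest relabelled 1..count.
#'
#' The evolution has no random element: the result is a deterministic
#' function of the map and the parameters.
#'
#' @param map numeric matrix, non-negative stain amounts.
#' @param minAreaPx drop components smaller than this (px).
#' @param mu curvature (boundary-length) weight on the \[0,1\]-scaled
#'   data term; default 0.1.
#' @param maxIter iteration budget; default 100.
#' @param tol stop when fewer than `tol` pixels change sign in an
#'   iteration; default 0.
#' @param dt explicit time step.
#' @return list with `labels` (integer matrix, 0 = background),
#'   `count` (number of nuclei) and `areaPx` (total nucleus area N).
#' @examples
#' sim <- simulateIHCImage(widthPx = 90, heightPx = 60, nNuclei = 5,
#'                         nMarkerBlobs = 0, seed = 2)
#' conc <- deconvolveStains(rgbToOD(sim$image))
#' segmentNuclei(conc[, , "hematoxylin"])$count
#' @export
segmentNuclei <- function(map, minAreaPx = 40L, mu = 0.1,
                          maxIter = 100L, tol = 0L, dt = 0.5) {
    if (length(dim(map)) != 2L)
        stop("expected a single-channel matrix")
    if (any(!is.finite(map)))
        stop("map contains non-finite values")
    mx <- max(map)
    empty <- list(labels = matrix(0L, nrow(map), ncol(map)),
                  count = 0L, areaPx = 0L)
    if (mx <= 0) return(empty)
    img <- pmax(map, 0) / mx

    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    phi <- img - thr
    fg <- phi > 0
    if (!any(fg) || all(fg)) return(empty)

    eps <- 1
    for (it in seq_len(maxIter)) {
        c1 <- mean(img[fg])
        c2 <- mean(img[!fg])
        force <- mu * curvature2d(phi) - (img - c1)^2 + (img - c2)^2
        delta <- eps / (pi * (eps^2 + phi^2))
        phi <- phi + dt * delta * force
        fgNew <- phi > 0
        changed <- sum(fg != fgNew)
        fg <- fgNew
        if (!any(fg) || all(fg)) break
        if (changed <= tol) break
    }

    lab <- matrix(as.integer(EBImage::bwlabel(fg * 1)),
                  nrow(map), ncol(map))
    if (max(lab) > 0L) {
        areas <- tabulate(lab, nbins = max(lab))
        keep <- which(areas >= minAreaPx)
        relab <- integer(max(lab))
        relab[keep] <- seq_along(keep)
        lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
    list(labels = lab, count = max(lab),
         areaPx = sum(lab > 0L))
}

# mean-curvature of a level-set function via central differences
# with replicated borders
curvature2d <- function(phi) {
    sh <- function(m, dr, dc) {
        nr <- nrow(m); nc <- ncol(m)
        ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
        ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
        m[ri, ci, drop = FALSE]
    }
    px <- (sh(phi, 0, 1) - sh(phi, 0, -1)) / 2
    py <- (sh(phi, 1, 0) - sh(phi, -1, 0)) / 2
    pxx <- sh(phi, 0, 1) - 2 * phi + sh(phi, 0, -1)
    pyy <- sh(phi, 1, 0) - 2 * phi + sh(phi, -1, 0)
    pxy <- (sh(phi, 1, 1) - sh(phi, 1, -1) -
            sh(phi, -1, 1) + sh(phi, -1, -1)) / 4
    (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
        ((px^2 + py^2)^1.5 + 1e-8)
}
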