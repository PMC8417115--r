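#' Variance-stabilizing normalization (median-ratio scaling + glog2)
#'
#' Two-step normalization of raw label-free intensities. First,
#' per-sample scale factors are estimated as the median ratio of each
#' sample to a geometric-mean pseudo-reference computed over proteins
#' observed in every sample (the standard size-factor construction);
#' each column is divided by its factor and the matrix is anchored to
#' the geometric mean of its reference-complete cells, so values are
#' expressed relative to the average reference level (log2-ratio-like,
#' centred near 0). Second, the anchored intensities are transformed
#' with the generalized log
#' `glog2(x) = log2((x + sqrt(x^2 + lambda^2)) / 2)`, with `lambda` a
#' low quantile (default the 1st percentile) of all scaled intensities,
#' which behaves like `log2(x)` for large `x` but stays finite and
#' stable near zero. Because the anchor removes the arbitrary global
#' scale, multiplying any sample by a positive constant leaves the
#' normalized values unchanged (complete-data case); group differences
#' (log2 fold changes) are unaffected by the anchoring.
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class], or a bare
#'   numeric matrix.
#' @param lambdaQuantile quantile of scaled intensities used for
#'   `lambda`.
#' @return for a `ProteomeExperiment`, the object with a `"glog2"`
#'   assay added and normalization parameters in
#'   `metadata(pe)$normalization` (`sizeFactors`, `lambda`, `anchor`);
#'   for a matrix, a list with `normalized`, `sizeFactors`, `lambda`,
#'   `anchor`.
#' @examples
#' m <- matrix(c(1, 10, 100, 3, 30, 300), ncol = 2,
#'             dimnames = list(paste0("p", 1:3), c("a", "b")))
#' vsnNormalize(m)$sizeFactors
#' @export
vsnNormalize <- function(pe, lambdaQuantile = 0.01) {
    x <- if (is(pe, "ProteomeExperiment")) assay(pe, "intensity")
         else as.matrix(pe)
    if (ncol(x) < 2) stop("need at least 2 samples to normalize")

    complete <- rowSums(is.na(x)) == 0 & rowSums(x == 0, na.rm = TRUE) == 0
    if (any(complete)) {
        logRef <- rowMeans(log(x[complete, , drop = FALSE]))
        sf <- apply(x[complete, , drop = FALSE], 2, function(col)
            exp(stats::median(log(col) - logRef)))
    } else {
        warning("no protein observed in all samples; ",
                "falling back to overall-median scaling")
        med <- apply(x, 2, stats::median, na.rm = TRUE)
        sf <- med / exp(mean(log(med)))
    }
    scaled <- sweep(x, 2, sf, "/")
    # anchor the common scale to the geometric mean of the
    # reference-complete cells so the output is invariant to rescaling
    # any single sample (the absolute scale carries no information in a
    # relative-quantification experiment)
    anchorCells <- if (any(complete)) scaled[complete, , drop = FALSE]
                   else scaled
    anchor <- exp(mean(log(anchorCells[anchorCells > 0 &
                                       !is.na(anchorCells)])))
    scaled <- scaled / anchor
    lambda <- stats::quantile(scaled, lambdaQuantile, na.rm = TRUE,
                              names = FALSE)
    lambda <- max(lambda, .Machine$double.eps)
    norm <- glog2(scaled, lambda)

    if (is(pe, "ProteomeExperiment")) {
        assay(pe, "glog2") <- norm
        metadata(pe)$normalization <- list(sizeFactors = sf, lambda = lambda,
                                           anchor = anchor)
        pe
    } else {
        list(normalized = norm, sizeFactors = sf, lambda = lambda,
             anchor = anchor)
    }
}

#' Generalized log2 transform
#'
#' `glog2(x) = log2((x + sqrt(x^2 + lambda^2)) / 2)`; equals `log2(x)`
#' asymptotically for `x >> lambda` and is defined and smooth at 0.
#'
#' @param x numeric.
#' @param lambda positive stabilization constant.
#' @return numeric of the same shape.
#' @examples
#' glog2(8, lambda = 1e-6)  # ~ 3
#' @export
glog2 <- function(x, lambda) {
    stopifnot(lambda > 0)
    log2((x + sqrt(x^2 + lambda^2)) / 2)
}
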