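#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two samples of S/N ratios (or any continuous statistic) by
#' the two-sample KS test: `D = sup |F1 - F2|` over the pooled sample.
#' In `"auto"` mode the exact conditional (permutation) p-value is
#' computed when `n1 * n2 <= 10000` and the data have no ties,
#' otherwise the asymptotic Kolmogorov distribution is used. Ties make
#' the exact method unavailable; a warning is emitted and the
#' asymptotic p returned.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return data.frame with `n1`, `n2`, `D`, `p`, `tier`
#'   (see [significanceTier()]) and `method`.
#' @examples
#' ksCompare(1:3, 1:3)$D  # identical samples: D = 0
#' @export
ksCompare <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y))
        stop("empty sample")
    hasTies <- anyDuplicated(c(x, y)) > 0
    if (hasTies && mode != "asymptotic")
        warning("ties present; exact KS p-value unavailable, ",
                "using asymptotic approximation")
    exact <- switch(mode,
        exact = TRUE,
        asymptotic = FALSE,
        auto = length(x) * length(y) <= 1e4)
    exact <- exact && !hasTies
    kt <- suppressWarnings(
        stats::ks.test(x, y, exact = exact))
    p <- min(max(kt$p.value, .Machine$double.xmin), 1)
    data.frame(n1 = length(x), n2 = length(y),
               D = unname(kt$statistic), p = p,
               tier = significanceTier(p),
               method = if (exact) "exact" else "asymptotic")
}

#' Significance tier label for a p-value
#'
#' Maps a p-value to the printed tier convention:
#' `"****"` for p < 0.0001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `"ns"` otherwise (the most extreme applicable tier wins; no `"***"`
#' tier exists in this convention).
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of tier labels.
#' @examples
#' significanceTier(c(0.2, 0.04, 5e-5))
#' @export
significanceTier <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    ifelse(p < 1e-4, "****",
    ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

#' Ordering of significance tiers
#'
#' Helper for "tier at least ..." checks: ns < * < ** < ****.
#'
#' @param tier character tier label(s).
#' @return integer rank (0 = ns).
#' @examples
#' tierRank("*") >= tierRank("*")
#' @export
tierRank <- function(tier) {
    match(tier, c("ns", "*", "**", "****")) - 1L
}

#' Compare a marker's S/N ratios between two groups
#'
#' Pools per-ROI S/N ratios across replicate images within each group
#' (the default scheme: 3 replicates x 9 ROIs = 27 ratios per group)
#' and runs the KS comparison per marker. Undefined ratios (ROIs
#' without nuclei) are excluded and counted.
#'
#' @param treated,control data.frames of [quantifyMarker()] results
#'   (columns `marker`, `ratio`, `defined`), rows possibly pooled over
#'   several images.
#' @param mode KS mode, see [ksCompare()].
#' @return data.frame, one row per marker: `marker`, `n1`, `n2`,
#'   `excluded1`, `excluded2`, `D`, `p`, `tier`, `method`.
#' @examples
#' a <- data.frame(marker = "iNOS", ratio = runif(27), defined = TRUE)
#' b <- data.frame(marker = "iNOS", ratio = runif(27) + 1, defined = TRUE)
#' compareMarkers(a, b)$tier
#' @export
compareMarkers <- function(treated, control, mode = "auto") {
    markers <- union(unique(treated$marker), unique(control$marker))
    out <- lapply(markers, function(mk) {
        tr <- treated[treated$marker == mk & treated$defined, ]
        ct <- control[control$marker == mk & control$defined, ]
        if (!nrow(tr) || !nrow(ct))
            stop(sprintf(
                "marker '%s' has no defined ratios in %s group",
                mk, if (!nrow(tr)) "the treated" else "the control"))
        ks <- ksCompare(tr$ratio, ct$ratio, mode = mode)
        cbind(marker = mk,
              ks[, c("n1", "n2")],
              excluded1 = sum(treated$marker == mk) - nrow(tr),
              excluded2 = sum(control$marker == mk) - nrow(ct),
              ks[, c("D", "p", "tier", "method")])
    })
    do.call(rbind, out)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' `volume = length * width^2 / 2` in mm^3 — the standard caliper
#' formula; e.g. 10 x 6.32 mm is ~200 mm^3, a typical enrollment size.
#'
#' @param lengthMm,widthMm caliper length and width in mm (vectorized).
#' @return volume(s) in mm^3.
#' @examples
#' tumorVolume(10, 6.32)
#' @export
tumorVolume <- function(lengthMm, widthMm) {
    if (any(lengthMm < 0) || any(widthMm < 0))
        stop("measurements must be non-negative")
    if (any(widthMm > lengthMm))
        warning("width exceeds length; measurements may be swapped")
    lengthMm * widthMm^2 / 2
}
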