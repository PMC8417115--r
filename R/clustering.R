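#' Build temporal log2FC profiles of DE proteins
#'
#' One row per protein flagged DE at >= 1 timepoint; entries are that
#' protein's log2 fold change at each of the seven timepoints.
#' Timepoints at which a protein was not testable (or not tested)
#' contribute 0 — "no evidence of change" — and are flagged.
#'
#' @param results flagged DE table from [callDE()] (the `results`
#'   element) or [runDEPipeline()].
#' @return list with `profiles` (DE proteins x 7 matrix) and `filled`
#'   (logical matrix marking zero-filled cells).
#' @examples
#' r <- data.frame(protein = "a", timepoint = "2d", log2fc = 2.9,
#'                 t = 9, df = 6, p = 1e-4, n1 = 4, n2 = 4,
#'                 p_adj = 1e-4, de = TRUE)
#' buildProfiles(r)$profiles
#' @export
buildProfiles <- function(results) {
    deIds <- unique(results$protein[results$de])
    if (!length(deIds))
        stop("no differentially expressed proteins to profile")
    tps <- timepointLevels()
    prof <- matrix(0, length(deIds), length(tps),
                   dimnames = list(deIds, tps))
    filled <- matrix(TRUE, length(deIds), length(tps),
                     dimnames = list(deIds, tps))
    sub <- results[results$protein %in% deIds, ]
    idx <- cbind(match(sub$protein, deIds), match(sub$timepoint, tps))
    prof[idx] <- sub$log2fc
    filled[idx] <- FALSE
    list(profiles = prof, filled = filled)
}

#' Temporal module discovery by k-means
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ seeding,
#' run `nInit` times from different seedings; the restart with the
#' smallest within-cluster sum of squares wins. An empty cluster is
#' repaired by re-seeding its centroid at the point farthest from its
#' current centroid. Deterministic given `seed`.
#'
#' @param profiles numeric matrix (e.g. from [buildProfiles()]).
#' @param k number of modules (default 6).
#' @param nInit number of restarts (default 50).
#' @param maxIter Lloyd iteration cap per restart.
#' @param seed integer seed.
#' @param standardize z-score rows before clustering (default FALSE:
#'   log2FC values are already commensurate across timepoints).
#' @return list with `labels` (named module assignment 1..k),
#'   `centers` (k x timepoints), `withinSS` (total), `sizes`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 5), 10))
#' kmeansModules(x, k = 2, nInit = 5, seed = 1)$sizes
#' @export
kmeansModules <- function(profiles, k = 6L, nInit = 50L, maxIter = 300L,
                          seed = 1L, standardize = FALSE) {
    x <- as.matrix(profiles)
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
    if (k > nrow(x))
        stop(sprintf("k = %d exceeds the %d profiles", k, nrow(x)))
    if (standardize)
        x <- t(scale(t(x)))
    set.seed(seed)

    best <- NULL
    for (i in seq_len(nInit)) {
        fit <- lloydOnce(x, k, maxIter)
        if (is.null(best) || fit$withinSS < best$withinSS)
            best <- fit
    }
    labels <- stats::setNames(best$labels, rownames(x))
    rownames(best$centers) <- seq_len(k)
    colnames(best$centers) <- colnames(x)
    list(labels = labels, centers = best$centers,
         withinSS = best$withinSS,
         sizes = tabulate(best$labels, nbins = k))
}

# one k-means++-seeded Lloyd run; consumes RNG state sequentially
lloydOnce <- function(x, k, maxIter) {
    n <- nrow(x)
    # k-means++ seeding
    centers <- x[sample.int(n, 1L), , drop = FALSE]
    d2 <- rowSums((x - centers[rep(1L, n), , drop = FALSE])^2)
    while (nrow(centers) < k) {
        pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
                else sample.int(n, 1L)
        centers <- rbind(centers, x[pick, , drop = FALSE])
        d2 <- pmin(d2, rowSums((x - centers[rep(nrow(centers), n),
                                            , drop = FALSE])^2))
    }
    labels <- integer(n)
    for (it in seq_len(maxIter)) {
        dist2 <- crossDist2(x, centers)
        newLabels <- max.col(-dist2, ties.method = "first")
        # empty-cluster repair: re-seed from the farthest point
        for (j in which(tabulate(newLabels, nbins = k) == 0L)) {
            far <- which.max(dist2[cbind(seq_len(n), newLabels)])
            centers[j, ] <- x[far, ]
            newLabels[far] <- j
            dist2 <- crossDist2(x, centers)
        }
        if (identical(newLabels, labels)) break
        labels <- newLabels
        centers <- rowsumMeans(x, labels, k)
    }
    dist2 <- crossDist2(x, centers)
    list(labels = labels, centers = centers,
         withinSS = sum(dist2[cbind(seq_len(n), labels)]))
}

crossDist2 <- function(x, centers) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
        2 * x %*% t(centers)
    pmax(d2, 0)
}

rowsumMeans <- function(x, labels, k) {
    sums <- rowsum(x, labels, reorder = FALSE)
    counts <- tabulate(labels, nbins = k)
    present <- sort(unique(labels))
    out <- matrix(0, k, ncol(x))
    out[present, ] <- sums / counts[present]
    out
}

#' Ward hierarchical clustering of DE profiles
#'
#' Agglomerative clustering with Ward's minimum-variance linkage
#' (Lance-Williams recurrence). Merge heights equal the increase in
#' total within-cluster sum of squares at each merge, so two points
#' merge at half their squared Euclidean distance.
#'
#' @param profiles numeric matrix of profiles (rows = proteins).
#' @param k optional number of clusters to cut at.
#' @return list with `tree` (an [stats::hclust] object) and `labels`
#'   (cut assignment, `NULL` when `k` is missing).
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' wardHclust(x, k = 2)$labels
#' @export
wardHclust <- function(profiles, k = NULL) {
    x <- as.matrix(profiles)
    if (nrow(x) < 2) stop("need at least 2 profiles")
    d2 <- stats::dist(x)^2 / 2    # ward.D on d^2/2 gives delta-SS heights
    tree <- stats::hclust(d2, method = "ward.D")
    labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
    list(tree = tree, labels = labels)
}

#' Summarize temporal modules
#'
#' Per module: the centroid curve (mean profile of members), the peak
#' timepoint (argmax of |centroid| reported with its sign via the
#' centroid value, and argmax of the centroid itself), and the member
#' count.
#'
#' @param labels module assignment (named by protein), e.g. from
#'   [kmeansModules()].
#' @param profiles profile matrix the assignment refers to.
#' @return data.frame with one row per module: `module`, `n`,
#'   `peakTimepoint` (argmax of centroid), `troughTimepoint` (argmin),
#'   plus the centroid in columns named by timepoint.
#' @examples
#' x <- matrix(c(0, 1, 0, 0, 0, 2, 0, 0), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("t1", "t2", "t3", "t4")))
#' moduleSummary(c(a = 1, b = 1), x)$peakTimepoint
#' @export
moduleSummary <- function(labels, profiles) {
    x <- as.matrix(profiles)
    stopifnot(all(names(labels) %in% rownames(x)))
    mods <- sort(unique(labels))
    rows <- lapply(mods, function(m) {
        members <- x[names(labels)[labels == m], , drop = FALSE]
        centroid <- colMeans(members)
        data.frame(module = m, n = nrow(members),
                   peakTimepoint = colnames(x)[which.max(centroid)],
                   troughTimepoint = colnames(x)[which.min(centroid)],
                   t(centroid), check.names = FALSE)
    })
    do.call(rbind, rows)
}
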