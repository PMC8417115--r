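#' Identification-quality filter on unique peptides
#'
#' Retains proteins measured with at least `minUnique` unique peptides,
#' preserving row order.
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class], or a
#'   numeric matrix (then `uniquePeptides` must be supplied).
#' @param minUnique minimum unique-peptide count (default 1).
#' @param uniquePeptides named counts when `pe` is a bare matrix; every
#'   protein must have an entry.
#' @return object of the same type as `pe`, subset to retained proteins.
#' @examples
#' m <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' rownames(filterUniquePeptides(m, uniquePeptides = c(A = 0, B = 1, C = 3)))
#' @export
filterUniquePeptides <- function(pe, minUnique = 1L, uniquePeptides = NULL) {
    if (is(pe, "ProteomeExperiment")) {
        keep <- rowData(pe)$uniquePeptides >= minUnique
        return(pe[keep, ])
    }
    m <- as.matrix(pe)
    if (is.null(uniquePeptides))
        stop("uniquePeptides required for a bare matrix")
    miss <- setdiff(rownames(m), names(uniquePeptides))
    if (length(miss))
        stop("no unique-peptide count for protein(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    m[uniquePeptides[rownames(m)] >= minUnique, , drop = FALSE]
}

#' Per-timepoint presence filter
#'
#' A protein is testable at a timepoint iff it has at least
#' `minPerGroup` non-missing intensities in the treated (YB1) samples
#' of that timepoint AND at least `minPerGroup` in the control (PBS)
#' samples. The analysis set is the union of testable proteins across
#' timepoints.
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class].
#' @param minPerGroup minimum observed samples per group (default 2).
#' @param assayName assay to count non-missing values in.
#' @return list with
#'   `testable` (proteins x timepoints logical matrix) and
#'   `analysisSet` (protein ids testable at >= 1 timepoint).
#' @examples
#' sim <- simulateProteome(nProteins = 100, seed = 1)
#' f <- filterPresence(sim$experiment)
#' head(f$analysisSet)
#' @export
filterPresence <- function(pe, minPerGroup = 2L, assayName = "intensity") {
    x <- assay(pe, assayName)
    cd <- colData(pe)
    tps <- timepointLevels()
    testable <- matrix(FALSE, nrow(x), length(tps),
                       dimnames = list(rownames(x), tps))
    for (tp in tps) {
        for (g in groupLevels()) {
            n <- sum(cd$group == g & cd$timepoint == tp)
            if (n < minPerGroup)
                stop(sprintf(
                    "design has only %d %s sample(s) at %s (< %d)",
                    n, g, tp, minPerGroup))
        }
        nY <- rowSums(!is.na(x[, cellSamples(pe, "YB1", tp), drop = FALSE]))
        nP <- rowSums(!is.na(x[, cellSamples(pe, "PBS", tp), drop = FALSE]))
        testable[, tp] <- nY >= minPerGroup & nP >= minPerGroup
    }
    list(testable = testable,
         analysisSet = rownames(x)[rowSums(testable) > 0])
}
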