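#' Construct a ProteomeExperiment
#'
#' Bundles a protein x sample intensity matrix with its sample design and
#' per-protein unique-peptide counts into a
#' [ProteomeExperiment][ProteomeExperiment-class].
#'
#' @param intensity numeric matrix, proteins x samples, non-negative,
#'   `NA` = missing. Must have row and column names.
#' @param design data.frame (or DataFrame) with one row per sample and
#'   columns `group` (YB1/PBS), `timepoint` (6h..14d) and `replicate`;
#'   rownames or a `sample_id` column must match `colnames(intensity)`.
#' @param uniquePeptides integer vector of unique-peptide counts, one per
#'   protein, in matrix row order (or named by protein id).
#' @return A [ProteomeExperiment][ProteomeExperiment-class].
#' @examples
#' sim <- simulateProteome(nProteins = 50, seed = 1)
#' pe <- sim$experiment
#' table(colData(pe)$group, colData(pe)$timepoint)
#' @export
ProteomeExperiment <- function(intensity, design, uniquePeptides) {
    intensity <- as.matrix(intensity)
    if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
        stop("intensity matrix must have protein rownames and sample colnames")
    design <- as.data.frame(design)
    if ("sample_id" %in% colnames(design)) {
        rownames(design) <- design$sample_id
        design$sample_id <- NULL
    }
    if (!setequal(rownames(design), colnames(intensity)))
        stop("design rows must match intensity matrix columns")
    design <- design[colnames(intensity), , drop = FALSE]
    design$group <- factor(as.character(design$group), levels = groupLevels())
    design$timepoint <- factor(as.character(design$timepoint),
                               levels = timepointLevels())
    design$replicate <- as.integer(design$replicate)
    if (!is.null(names(uniquePeptides))) {
        miss <- setdiff(rownames(intensity), names(uniquePeptides))
        if (length(miss))
            stop("no unique-peptide count for protein(s): ",
                 paste(utils::head(miss, 5), collapse = ", "))
        uniquePeptides <- uniquePeptides[rownames(intensity)]
    }
    if (length(uniquePeptides) != nrow(intensity))
        stop("uniquePeptides must have one entry per protein")
    se <- SummarizedExperiment(
        assays = list(intensity = intensity),
        colData = DataFrame(design),
        rowData = DataFrame(uniquePeptides = as.integer(uniquePeptides)))
    new("ProteomeExperiment", se)
}

setMethod("show", "ProteomeExperiment", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat(sprintf("design: %d group(s) x %d timepoint(s), replicates %s\n",
        length(unique(cd$group)), length(unique(droplevels(cd$timepoint))),
        paste(range(cd$replicate), collapse = "-")))
    x <- assay(object, "intensity")
    cat(sprintf("missing values: %.1f%%\n", 100 * mean(is.na(x))))
    invisible(NULL)
})

#' Samples belonging to one group x timepoint cell
#'
#' @param pe a [ProteomeExperiment][ProteomeExperiment-class].
#' @param group `"YB1"` or `"PBS"`.
#' @param timepoint one of [timepointLevels()].
#' @return character vector of sample ids.
#' @keywords internal
cellSamples <- function(pe, group, timepoint) {
    cd <- colData(pe)
    colnames(pe)[cd$group == group & cd$timepoint == timepoint]
}
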