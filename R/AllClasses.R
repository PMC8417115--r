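#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData
NULL

#' Stain basis matrix for color deconvolution
#'
#' A 3 x 3 matrix of optical-density stain vectors (rows = stains,
#' columns = RGB channels). Rows are renormalized to unit Euclidean norm
#' on construction; the matrix must be invertible so per-pixel unmixing
#' is well defined.
#'
#' @slot basis numeric 3 x 3 matrix, unit-norm rows, rownames = stain names.
#'
#' @seealso [StainMatrix()], [hdabStainMatrix()], [deconvolveStains()]
#' @name StainMatrix-class
#' @rdname StainMatrix-class
#' @exportClass StainMatrix
setClass("StainMatrix", representation(basis = "matrix"))

setValidity("StainMatrix", function(object) {
    m <- object@basis
    if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
        return("stain basis must be a numeric 3 x 3 matrix")
    if (any(!is.finite(m)))
        return("stain basis contains non-finite values")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("stain basis rows must carry unique stain names")
    nrm <- sqrt(rowSums(m^2))
    if (any(abs(nrm - 1) > 1e-9))
        return("stain vectors must have unit Euclidean norm")
    if (abs(det(m)) < 1e-12) {
        dep <- paste(rownames(m), collapse = ", ")
        return(sprintf("stain matrix is singular (rows: %s)", dep))
    }
    TRUE
})

#' Empirical-Bayes moderation prior for per-protein variances
#'
#' Holds the prior degrees of freedom d0 (possibly `Inf`) and the prior
#' variance s0^2 towards which per-protein sample variances are shrunk in
#' the moderated t-test.
#'
#' @slot dfPrior numeric(1), prior degrees of freedom d0 >= 0, may be `Inf`.
#' @slot varPrior numeric(1), prior variance s0^2 > 0.
#'
#' @seealso [fitModerationPrior()], [moderatedTTest()]
#' @name ModerationPrior-class
#' @rdname ModerationPrior-class
#' @exportClass ModerationPrior
setClass("ModerationPrior",
    representation(dfPrior = "numeric", varPrior = "numeric"))

setValidity("ModerationPrior", function(object) {
    if (length(object@dfPrior) != 1L || is.na(object@dfPrior) ||
        object@dfPrior < 0)
        return("dfPrior must be a single non-negative number (may be Inf)")
    if (length(object@varPrior) != 1L || !is.finite(object@varPrior) ||
        object@varPrior <= 0)
        return("varPrior must be a single positive finite number")
    TRUE
})

#' Container for a label-free proteome experiment
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the fixed
#' design used throughout the package: samples annotated by `group`
#' (YB1 = treated, PBS = control), `timepoint` (one of 6h, 12h, 24h, 2d,
#' 3d, 7d, 14d) and `replicate`, and proteins annotated with a
#' `uniquePeptides` count used by the identification-quality filter.
#' The `"intensity"` assay holds raw (non-negative) intensities with
#' `NA` for missing values; normalization and imputation add further
#' assays (`"glog2"`, `"imputed"`).
#'
#' @seealso [ProteomeExperiment()], [simulateProteome()], [vsnNormalize()]
#' @name ProteomeExperiment-class
#' @rdname ProteomeExperiment-class
#' @exportClass ProteomeExperiment
setClass("ProteomeExperiment", contains = "SummarizedExperiment")

#' Timepoint labels of the sampling design
#'
#' The seven post-injection sampling times, in temporal order.
#' @return character(7)
#' @examples timepointLevels()
#' @export
timepointLevels <- function() c("6h", "12h", "24h", "2d", "3d", "7d", "14d")

#' Group labels of the sampling design
#'
#' @return character(2): `"YB1"` (treated) and `"PBS"` (control).
#' @examples groupLevels()
#' @export
groupLevels <- function() c("YB1", "PBS")

setValidity("ProteomeExperiment", function(object) {
    cd <- colData(object)
    need <- c("group", "timepoint", "replicate")
    if (!all(need %in% colnames(cd)))
        return(sprintf("colData must contain columns: %s",
            paste(need, collapse = ", ")))
    if (!all(as.character(cd$group) %in% groupLevels()))
        return("group must be one of YB1, PBS")
    if (!all(as.character(cd$timepoint) %in% timepointLevels()))
        return(sprintf("timepoint must be one of: %s",
            paste(timepointLevels(), collapse = ", ")))
    if (!"uniquePeptides" %in% colnames(rowData(object)))
        return("rowData must contain a uniquePeptides column")
    up <- rowData(object)$uniquePeptides
    if (any(is.na(up)) || any(up < 0) || any(up != round(up)))
        return("uniquePeptides must be non-negative integers")
    if (anyDuplicated(colnames(object)))
        return("sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        return("protein ids must be unique")
    if (!"intensity" %in% names(assays(object)))
        return("an 'intensity' assay is required")
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
        return("intensities must be non-negative")
    TRUE
})
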