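#' Re-exported generics from SummarizedExperiment / S4Vectors
#'
#' `assay`, `assays`, `rowData`, `colData` and `metadata` are
#' re-exported so ProteomeExperiment objects can be inspected without
#' attaching SummarizedExperiment.
#'
#' @name reexports
#' @keywords internal
NULL

#' @rdname reexports
#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @rdname reexports
#' @importFrom SummarizedExperiment assays
#' @export
SummarizedExperiment::assays

#' @rdname reexports
#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @rdname reexports
#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @rdname reexports
#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata
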