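#' Construct a stain matrix
#'
#' Builds a [StainMatrix][StainMatrix-class] from a numeric 3 x 3 matrix of
#' optical-density stain vectors (rows = stains, columns = RGB). Rows are
#' normalized to unit Euclidean norm; an all-zero row or a (near-)singular
#' matrix is rejected with an error naming the offending rows.
#'
#' @param basis numeric 3 x 3 matrix; rows are stain OD vectors.
#' @param stains character(3) stain names; defaults to rownames of
#'   `basis` or `c("hematoxylin", "marker", "residual")`.
#' @return A [StainMatrix][StainMatrix-class] object.
#' @examples
#' StainMatrix(diag(3), c("a", "b", "c"))
#' hdabStainMatrix()
#' @export
StainMatrix <- function(basis,
                        stains = rownames(basis)) {
    basis <- as.matrix(basis)
    if (!identical(dim(basis), c(3L, 3L)))
        stop("stain basis must be 3 x 3 (rows = stains, columns = RGB)")
    if (is.null(stains))
        stains <- c("hematoxylin", "marker", "residual")
    nrm <- sqrt(rowSums(basis^2))
    if (any(nrm <= 0))
        stop("zero-length stain vector in row(s): ",
             paste(which(nrm <= 0), collapse = ", "))
    basis <- basis / nrm
    dimnames(basis) <- list(stains, c("R", "G", "B"))
    if (abs(det(basis)) < 1e-12)
        stop("stain matrix is singular; linearly dependent rows among: ",
             paste(stains, collapse = ", "))
    new("StainMatrix", basis = basis)
}

#' Default hematoxylin / DAB deconvolution matrix
#'
#' The fixed stain basis used for brightfield IHC quantification:
#' row 1 the hematoxylin (nuclear counterstain) vector, row 2 the
#' DAB-like marker chromogen, row 3 the residual channel. Values are the
#' standard H-DAB optical-density vectors
#' `(0.650, 0.704, 0.286)`, `(0.268, 0.570, 0.776)`,
#' `(0.711, 0.423, 0.561)`; rows are renormalized to unit norm.
#'
#' @return A [StainMatrix][StainMatrix-class].
#' @examples
#' stainBasis(hdabStainMatrix())
#' @export
hdabStainMatrix <- function() {
    StainMatrix(matrix(c(
        0.650, 0.704, 0.286,
        0.268, 0.570, 0.776,
        0.711, 0.423, 0.561), nrow = 3, byrow = TRUE),
        stains = c("hematoxylin", "marker", "residual"))
}

#' @describeIn StainMatrix-class the unit-row-norm 3 x 3 basis matrix.
#' @param object,x a `StainMatrix`.
#' @export
stainBasis <- function(x) x@basis

#' @describeIn StainMatrix-class the stain names (row labels).
#' @export
stainNames <- function(x) rownames(x@basis)

setMethod("show", "StainMatrix", function(object) {
    cat("StainMatrix (rows = stains, unit OD vectors)\n")
    print(round(object@basis, 4))
    invisible(NULL)
})

setMethod("show", "ModerationPrior", function(object) {
    cat(sprintf("ModerationPrior: d0 = %s, s0^2 = %.6g\n",
        format(object@dfPrior), object@varPrior))
    invisible(NULL)
})

#' @describeIn ModerationPrior-class prior degrees of freedom d0.
#' @param x a `ModerationPrior`.
#' @export
dfPrior <- function(x) x@dfPrior

#' @describeIn ModerationPrior-class prior variance s0^2.
#' @export
varPrior <- function(x) x@varPrior
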