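#' Read / write the package's plain-text interchange formats
#'
#' Intensity matrices are TSV with proteins as rows, samples as
#' columns, an empty cell meaning missing; the design table is TSV with
#' columns `sample_id`, `group`, `timepoint`, `replicate`; protein meta
#' is TSV with columns `protein`, `unique_peptides`; a stain matrix is
#' a whitespace-separated 3 x 3 text file (rows = stains).
#'
#' @param path file path.
#' @return `readIntensityMatrix`: numeric matrix with `NA` for missing;
#'   `readSampleDesign` / `readProteinMeta`: data.frame;
#'   `readStainMatrixFile`: a [StainMatrix][StainMatrix-class].
#' @name tiquant-io
NULL

#' @rdname tiquant-io
#' @export
readIntensityMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                            na.strings = c("", "NA", "NaN"))
    as.matrix(df)
}

#' @rdname tiquant-io
#' @param x object to write (matrix, data.frame, or StainMatrix).
#' @export
writeIntensityMatrix <- function(x, path) {
    df <- data.frame(protein = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname tiquant-io
#' @export
readSampleDesign <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname tiquant-io
#' @export
writeSampleDesign <- function(x, path) {
    df <- as.data.frame(x)
    if (!"sample_id" %in% colnames(df))
        df <- cbind(sample_id = rownames(df), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname tiquant-io
#' @export
readProteinMeta <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("protein", "unique_peptides") %in% colnames(df)))
    df
}

#' @rdname tiquant-io
#' @export
readStainMatrixFile <- function(path) {
    m <- as.matrix(utils::read.table(path))
    StainMatrix(m)
}

#' Read / write 8-bit RGB images and binary masks
#'
#' Images are PNG (or TIFF when the tiff package is installed) with
#' intensities on the 0-255 scale used throughout the package; masks
#' are written as single-channel 0/255 PNG.
#'
#' @param path file path; format chosen by extension (.png/.tif/.tiff).
#' @param img `h x w x 3` array of 8-bit intensities.
#' @param mask logical matrix.
#' @return `readIHCImage`: `h x w x 3` array in 0-255;
#'   `readMask`: logical matrix.
#' @name image-io
NULL

#' @rdname image-io
#' @export
readIHCImage <- function(path) {
    img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        requireTiff()
        tiff::readTIFF(path)
    } else png::readPNG(path)
    if (length(dim(img)) == 2L)
        img <- array(rep(img, 3), c(dim(img), 3))
    round(img[, , 1:3, drop = FALSE] * 255)
}

#' @rdname image-io
#' @export
writeIHCImage <- function(img, path) {
    arr <- pmin(pmax(img / 255, 0), 1)
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
        requireTiff()
        tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    } else png::writePNG(arr, path)
    invisible(path)
}

#' @rdname image-io
#' @export
writeMask <- function(mask, path) {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
    invisible(path)
}

#' @rdname image-io
#' @export
readMask <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m >= 0.5
}

requireTiff <- function() {
    if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required for TIFF files; ",
             "use PNG instead")
}

#' Write per-ROI quantification results
#'
#' TSV with columns `image`, `marker`, `roi`, `S_px`, `N_px`, `ratio`.
#'
#' @param results data.frame of [quantifyMarker()] output (an `image`
#'   column is added if absent).
#' @param path file path.
#' @export
#' @rdname tiquant-io
writeSNResults <- function(results, path) {
    if (!"image" %in% colnames(results))
        results <- cbind(image = NA_character_, results)
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
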