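# 10x-style on-disk exchange: MatrixMarket counts with features/barcodes
# TSVs, demultiplexing CSV, truth JSON.

#' Write / read 10x-style MTX count directories
#'
#' \code{writeCountsMTX} writes \code{matrix.mtx}, \code{features.tsv} and
#' \code{barcodes.tsv} into \code{dir}; \code{readCountsMTX} reads them back
#' into a sparse gene x cell matrix.
#'
#' @param x gene x cell count matrix or SingleCellExperiment.
#' @param dir directory (created if needed).
#' @return \code{writeCountsMTX}: \code{dir}, invisibly;
#'   \code{readCountsMTX}: a \code{dgCMatrix} with dimnames.
#' @export
writeCountsMTX <- function(x, dir) {
    counts <- .getCounts(x)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' @rdname writeCountsMTX
#' @export
readCountsMTX <- function(dir) {
    m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
    dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                        readLines(file.path(dir, "barcodes.tsv")))
    m
}

#' Write a demultiplexing result as CSV
#'
#' Columns: cell_id, status, label.
#'
#' @param demux a \code{\linkS4class{DemuxResult}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDemuxCSV <- function(demux, path) {
    df <- data.frame(cell_id = names(demux@label),
                     status = as.character(demux@status),
                     label = demux@label)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a gene-dynamics table as CSV
#'
#' @param dyn a \code{\linkS4class{GeneDynamics}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDynamicsCSV <- function(dyn, path) {
    utils::write.csv(as.data.frame(dynTable(dyn)), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}
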