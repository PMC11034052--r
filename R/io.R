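# Readers/writers for the matrix formats used in single-cell work:
# dense CSV/TSV (cells as rows, first column cell IDs) and MatrixMarket
# triplets (matrix.mtx + barcodes.tsv + features/genes.tsv), with
# genes x cells orientation auto-detected and transposed.

#' Read a cells x features matrix
#'
#' For \code{format = "mtx"}, \code{path} is a directory (or file prefix)
#' holding \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (or \code{genes.tsv}); orientation is normalized to cells x genes using
#' the barcode count. CSV/TSV files must have a header row of feature IDs
#' and cell IDs in the first column.
#'
#' @param path File (csv/tsv) or directory (mtx triplet).
#' @param format One of "auto", "csv", "tsv", "mtx".
#' @return Dense numeric matrix with cell IDs as row names.
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || file.exists(file.path(path, "matrix.mtx"))) "mtx"
      else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
      else if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv"
      else if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
      else stop("cannot guess format of ", path, call. = FALSE)
  }
  if (format == "mtx") return(read_mtx_triplet(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = if (format == "csv") "," else "\t",
                          row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric values in column '", colnames(df)[bad], "' of ", path, call. = FALSE)
  }
  m
}

read_mtx_triplet <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    if (!file.exists(ft)) ft <- file.path(path, "genes.tsv")
  } else {
    mtx <- paste0(path, "matrix.mtx"); bc <- paste0(path, "barcodes.tsv")
    ft <- paste0(path, "features.tsv")
    if (!file.exists(ft)) ft <- paste0(path, "genes.tsv")
  }
  for (f in c(mtx, bc, ft)) if (!file.exists(f))
    stop("MTX triplet incomplete: missing ", f, call. = FALSE)
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  features <- utils::read.table(ft, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (ncol(m) == length(barcodes) && nrow(m) == length(features)) {
    m <- t(m)  # genes x cells on disk -> cells x genes
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    stop(sprintf("MTX dimensions %d x %d do not match %d barcodes / %d features",
                 nrow(m), ncol(m), length(barcodes), length(features)), call. = FALSE)
  }
  rownames(m) <- barcodes
  colnames(m) <- features
  m
}

#' Write a cells x features matrix
#'
#' CSV/TSV with cell IDs in the first column, or an MTX triplet directory
#' (genes x cells orientation, 10x-style) for \code{format = "mtx"}.
#'
#' @param x Numeric matrix with cell IDs as row names.
#' @param path Output file (csv/tsv) or directory (mtx).
#' @param format One of "auto", "csv", "tsv", "mtx".
#' @return Invisibly, \code{path}.
#' @export
write_matrix <- function(x, path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  x <- as_cell_matrix(x)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
      else if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv"
      else "mtx"
  }
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(t(x), sparse = TRUE), file.path(path, "matrix.mtx"))
    writeLines(rownames(x), file.path(path, "barcodes.tsv"))
    writeLines(colnames(x), file.path(path, "features.tsv"))
  } else {
    df <- data.frame(cell_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
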