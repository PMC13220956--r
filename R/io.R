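# Readers and writers for the plain-text formats the pipeline touches:
# dense TSV matrices, MTX triplets, label TSVs, JSON sidecars.

#' Read and write dense expression matrices as TSV
#'
#' Matrices are stored genes-in-rows with a leading `gene` column (bulk,
#' region matrices transpose as needed by the caller).
#'
#' @param m Numeric matrix with row names.
#' @param path File path.
#' @return `read_matrix_tsv()` a numeric matrix; writers return the path
#'   invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[-1L])
  rownames(m) <- as.character(d[[1L]])
  m
}

#' Write / read a two-column sample-label TSV
#'
#' @param labels Named or unnamed vector of group/cluster labels.
#' @param ids Identifiers (samples or cells); defaults to `names(labels)`.
#' @param path File path.
#' @param id_col,label_col Column names.
#' @return `read_labels_tsv()` a named character vector.
#' @export
write_labels_tsv <- function(labels, path, ids = names(labels),
                             id_col = "id", label_col = "label") {
  if (is.null(ids)) ids <- paste0("s", seq_along(labels))
  d <- setNames(data.frame(ids, as.character(labels)), c(id_col, label_col))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(d[[2L]]), as.character(d[[1L]]))
}

#' Write / read a single-cell count matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`
#' (genes in MTX rows, the usual convention); `read_sc_mtx()` returns the
#' cell-by-gene orientation the caller consumes.
#'
#' @param counts Cell-by-gene matrix (rows = cells).
#' @param dir Output directory (created if missing).
#' @return `read_sc_mtx()` a sparse cell-by-gene dgCMatrix.
#' @export
write_sc_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sp), file.path(dir, "features.tsv"))
  writeLines(colnames(sp), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_sc_mtx
#' @export
read_sc_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  methods::as(Matrix::t(m), "CsparseMatrix")
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth A list (as produced by the simulators).
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
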